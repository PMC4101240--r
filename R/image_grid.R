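#' Load a grayscale image and normalize intensities to [0, 1]
#'
#' Reads a PNG or TIFF image (grayscale or RGB; 8- or 16-bit), converts RGB
#' to grayscale by the channel mean, and linearly rescales intensities to
#' the unit interval. A constant image maps to all zeros: the active contour
#' energy depends only on intensity contrasts, so the degenerate range is
#' resolved in favor of a well-defined (empty-feature) image.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (rows x cols) with values in [0, 1].
#' @export
load_grayscale_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)")
  )
  img <- as_gray_matrix(img)
  if (nrow(img) < 3 || ncol(img) < 3)
    stop_validation("image must be at least 3x3 pixels, got ",
                    nrow(img), "x", ncol(img))
  normalize01(img)
}

# Collapse a decoded image array to a single-channel matrix.
# RGB(A) -> mean of the first three channels; alpha is ignored.
as_gray_matrix <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    if (nch >= 3L) return((img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3)
    return(img[, , 1L])
  }
  stop_validation("cannot interpret decoded image of dimension ",
                  paste(dim(img), collapse = "x"))
}

#' Linearly rescale a matrix to [0, 1]
#'
#' @param x Numeric matrix with finite entries.
#' @return Matrix with minimum 0 and maximum 1; constant input maps to zeros.
#' @export
normalize01 <- function(x) {
  if (!all(is.finite(x))) stop_validation("image contains non-finite values")
  rng <- range(x)
  if (rng[2] == rng[1]) return(array(0, dim = dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Default localization kernel scale
#'
#' The kernel scale of the localized region energy is tied to the image
#' size: `sigma = round((dim_y + dim_x) / 16)` pixels (half-up rounding),
#' clamped below at 1. Larger images get proportionally wider local
#' neighborhoods.
#'
#' @param dim_y,dim_x Image height and width in pixels (each >= 3).
#' @return Kernel scale in pixels (integer-valued numeric, >= 1).
#' @examples
#' default_sigma(110, 110) # 14
#' @export
default_sigma <- function(dim_y, dim_x) {
  if (dim_y < 3 || dim_x < 3)
    stop_validation("image dimensions must be >= 3, got ", dim_y, "x", dim_x)
  max(1, floor((dim_y + dim_x) / 16 + 0.5))
}

#' Extract the zero contour of a level-set field
#'
#' Sub-pixel polylines where `phi` changes sign, obtained by linear
#' interpolation between 4-neighboring grid points (marching squares via
#' [grDevices::contourLines()]). Pixels with `phi` exactly 0 are treated as
#' contour points on the interior side. Returns an empty list when `phi`
#' does not attain both signs.
#'
#' @param phi Numeric matrix, the level-set field (interior `phi < 0`).
#' @return List of contour components; each is a data.frame with columns
#'   `row`, `col` (1-based pixel coordinates) and an attribute `closed`.
#' @export
extract_zero_contour <- function(phi) {
  if (!all(is.finite(phi))) stop_validation("phi contains non-finite values")
  p <- phi
  p[p == 0] <- -1e-12  # exact zeros belong to the contour; nudge inward
  if (all(p > 0) || all(p < 0)) return(list())
  cl <- grDevices::contourLines(x = seq_len(nrow(p)), y = seq_len(ncol(p)),
                                z = p, levels = 0)
  lapply(cl, function(comp) {
    r <- comp$x
    c <- comp$y
    n <- length(r)
    closed <- n > 2 && isTRUE(all.equal(c(r[1], c[1]), c(r[n], c[n])))
    if (closed) {
      r <- r[-n]
      c <- c[-n]
    }
    out <- data.frame(row = r, col = c)
    attr(out, "closed") <- closed
    out
  })
}

#' Rasterize closed contours back to a binary interior mask
#'
#' Fills the region enclosed by the closed components of a contour list
#' using the even-odd rule (nested contours alternate interior/exterior),
#' with point-in-polygon tests from [mgcv::in.out()]. Open components are
#' ignored.
#'
#' @param contours A contour list as returned by [extract_zero_contour()].
#' @param dim Integer vector `c(rows, cols)` of the target grid.
#' @return Logical matrix; `TRUE` inside the contours.
#' @export
rasterize_contours <- function(contours, dim) {
  mask <- matrix(FALSE, dim[1], dim[2])
  pts <- cbind(rep(seq_len(dim[1]), times = dim[2]),
               rep(seq_len(dim[2]), each = dim[1]))
  for (comp in contours) {
    if (!isTRUE(attr(comp, "closed")) || nrow(comp) < 3) next
    bnd <- rbind(as.matrix(comp[, c("row", "col")]),
                 c(comp$row[1], comp$col[1]))
    inside <- mgcv::in.out(bnd, pts)
    mask <- xor(mask, matrix(inside, dim[1], dim[2]))
  }
  mask
}

#' Combine a contour list into one point table
#'
#' @param contours List from [extract_zero_contour()].
#' @return data.frame with columns `component`, `row`, `col`.
#' @export
contour_points <- function(contours) {
  if (length(contours) == 0)
    return(data.frame(component = integer(), row = numeric(), col = numeric()))
  do.call(rbind, lapply(seq_along(contours), function(i) {
    data.frame(component = i, row = contours[[i]]$row, col = contours[[i]]$col)
  }))
}

#' @rdname contour_points
#' @param path Output CSV path (header `component,row,col`).
#' @export
write_contours_csv <- function(contours, path) {
  utils::write.csv(contour_points(contours), path, row.names = FALSE)
  invisible(path)
}

#' Read a contour point table written by [write_contours_csv()]
#'
#' @param path CSV path with columns `component`, `row`, `col`.
#' @return data.frame with those columns.
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("component", "row", "col")
  if (!all(need %in% names(df)))
    stop_validation("contour CSV must have columns component,row,col")
  df[, need]
}

#' Binary mask PNG input/output
#'
#' Masks are written as 8-bit PNGs with values 0/255 and read back by
#' thresholding at 0.5.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param path PNG file path.
#' @return `write_mask_png` returns the path invisibly; `read_mask_png`
#'   returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(array(as.numeric(mask), dim = dim(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  as_gray_matrix(png::readPNG(path)) > 0.5
}
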