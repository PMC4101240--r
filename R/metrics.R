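#' Modified root mean squared error between two contours
#'
#' Compares a truth contour against an evolved contour as point sets. Each
#' truth point is matched to the nearest evolved point inside its
#' `(2r+1) x (2r+1)` window (many truth points may share an evolved point);
#' `k1` counts matched truth points, `k2` unmatched truth points, and `k3`
#' evolved points that were never selected as a match and have no truth
#' point within their own window. The metric is
#' `(sum of matched squared distances + 2 (k2 + k3) r^2) / (k1 + k2 + k3)`
#' -- a mean of squared distances in squared-pixel units (no square root is
#' taken), with each unmatched point charged the `2 r^2` penalty.
#'
#' @param truth,evolved Point sets: data.frames or matrices with `row`,
#'   `col` columns (sub-pixel coordinates allowed).
#' @param r Window radius in pixels (default 12).
#' @return Object of class `mrmse_result`: list with `value`, `k1`, `k2`,
#'   `k3`, `r`.
#' @export
mrmse <- function(truth, evolved, r = 12) {
  if (r < 1) stop_validation("window radius r must be >= 1")
  tp <- as_points(truth)
  ep <- as_points(evolved)
  n_t <- nrow(tp)
  n_e <- nrow(ep)
  if (n_t == 0 && n_e == 0)
    stop_validation("MRMSE is undefined for two empty contours")

  matched_d2 <- numeric(0)
  used <- rep(FALSE, n_e)
  k1 <- 0L
  if (n_t > 0 && n_e > 0) {
    for (i in seq_len(n_t)) {
      dr <- ep[, 1] - tp[i, 1]
      dc <- ep[, 2] - tp[i, 2]
      inwin <- abs(dr) <= r & abs(dc) <= r
      if (!any(inwin)) next
      d2 <- dr[inwin]^2 + dc[inwin]^2
      j <- which(inwin)[which.min(d2)]
      matched_d2 <- c(matched_d2, min(d2))
      used[j] <- TRUE
      k1 <- k1 + 1L
    }
  }
  k2 <- n_t - k1
  # evolved points never selected and with no truth point in their window
  k3 <- 0L
  if (n_e > 0) {
    for (j in seq_len(n_e)) {
      if (used[j]) next
      if (n_t > 0) {
        inwin <- abs(tp[, 1] - ep[j, 1]) <= r & abs(tp[, 2] - ep[j, 2]) <= r
        if (any(inwin)) next
      }
      k3 <- k3 + 1L
    }
  }
  value <- (sum(matched_d2) + 2 * (k2 + k3) * r^2) / (k1 + k2 + k3)
  structure(list(value = value, k1 = k1, k2 = k2, k3 = k3, r = r),
            class = "mrmse_result")
}

as_points <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("row", "col")])
  if (is.null(x) || length(x) == 0) return(matrix(numeric(0), 0, 2))
  x <- as.matrix(x)
  if (ncol(x) != 2) stop_validation("point set must have two columns (row, col)")
  if (!all(is.finite(x))) stop_validation("point coordinates must be finite")
  x
}

#' @export
print.mrmse_result <- function(x, ...) {
  cat(sprintf("MRMSE = %.4f (r = %d; k1 = %d matched, k2 = %d, k3 = %d)\n",
              x$value, x$r, x$k1, x$k2, x$k3))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2 |A & B| / (|A| + |B|)` for two binary masks of the same shape;
#' defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b Logical (or 0/1) matrices.
#' @return Scalar in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop_validation("masks must have the same shape")
  a <- mask_a > 0
  b <- mask_b > 0
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  2 * sum(a & b) / tot
}

#' Boundary points of a binary mask as a contour point set
#'
#' Traces the mask boundary the same way segmentation contours are
#' produced: through the zero level of the three-valued embedding of the
#' mask, so truth and prediction are compared on equal footing.
#'
#' @param mask Logical matrix.
#' @return data.frame with columns `component`, `row`, `col`.
#' @export
mask_boundary_points <- function(mask) {
  contour_points(extract_zero_contour(init_level_set(mask, rho = 2)))
}
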