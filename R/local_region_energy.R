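#' Energy weights of the localized region model
#'
#' @param lambda1,lambda2 Weights of the interior/exterior squared residuals
#'   in the data term. Kept equal (default 1) for a fair competition between
#'   the two regions; raising one penalizes growth of that region.
#' @param v Length-penalty weight (default 0.2) on the contour arc length.
#' @param mu Distance-regularization weight (default 1.0) on
#'   `(|grad(phi)| - 1)^2 / 2`, which keeps `phi` close to a signed distance
#'   function near the front without explicit reinitialization.
#' @return List of class `energy_weights`.
#' @export
energy_weights <- function(lambda1 = 1, lambda2 = 1, v = 0.2, mu = 1.0) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, v = v, mu = mu)
  if (any(unlist(w) < 0)) stop_validation("energy weights must be >= 0")
  structure(w, class = "energy_weights")
}

# at_points: 2-column (row, col) integer matrix, or NULL for every pixel in
# column-major order (so results reshape with matrix(x, nr, nc)).
resolve_points <- function(at_points, dm) {
  if (is.null(at_points)) {
    cbind(row = rep(seq_len(dm[1]), times = dm[2]),
          col = rep(seq_len(dm[2]), each = dm[1]))
  } else {
    pts <- as.matrix(at_points)
    if (ncol(pts) != 2 || nrow(pts) == 0)
      stop_validation("at_points must be a non-empty 2-column (row, col) matrix")
    storage.mode(pts) <- "integer"
    pts
  }
}

#' Local interior/exterior fitting means
#'
#' At each requested pixel x, the kernel-weighted mean intensity of the
#' interior (`f1`) and exterior (`f2`) as seen through the smoothed interior
#' membership `H(-phi)` (the interior is the region `phi < 0`):
#' `f1(x) = sum_y K(x,y) H(-phi(y)) I(y) / sum_y K(x,y) H(-phi(y))`
#' and the complementary-membership analogue for `f2`, the sums running over the kernel
#' stencil clipped to the image (numerator and denominator clip identically,
#' so no per-pixel renormalization is needed). A denominator at or below
#' 1e-10 -- a pixel with no local interior (or exterior) mass -- marks the
#' pixel undefined and falls back to the plain kernel-weighted mean of the
#' image there.
#'
#' @param image Numeric intensity matrix in [0, 1].
#' @param phi Level-set matrix, same shape (interior `phi < 0`).
#' @param kernel A [gaussian_kernel()] window.
#' @param eps_h Heaviside regularization width (default 1).
#' @param at_points 2-column (row, col) integer matrix of pixels to evaluate,
#'   or `NULL` for the whole image.
#' @return Object of class `fitting_fields`: list with `points`, vectors
#'   `f1`, `f2`, logical `defined`, and `dim` of the image.
#' @export
compute_fitting_means <- function(image, phi, kernel, eps_h = 1,
                                  at_points = NULL) {
  if (!identical(dim(image), dim(phi)))
    stop_validation("image and phi must have the same shape")
  pts <- resolve_points(at_points, dim(image))
  # interior indicator: the contour interior is {phi < 0}, so the smoothed
  # membership of the interior is H_eps(-phi)
  hphi <- heaviside_eps(-phi, eps_h)
  res <- fitting_means_cpp(image, hphi, kernel$weights,
                           pts[, 1], pts[, 2], 1e-10)
  structure(list(points = pts, f1 = res$f1, f2 = res$f2,
                 defined = res$defined, dim = dim(image)),
            class = "fitting_fields")
}

# Scatter a fitting_fields object into full-image matrices (NA where the
# fitting means were not evaluated; such pixels must never be touched by a
# kernel window, or the force is undefined there and errors downstream).
fit_matrices <- function(fits) {
  if (nrow(fits$points) == prod(fits$dim)) {
    # full-grid column-major evaluation: reshape directly
    return(list(f1 = matrix(fits$f1, fits$dim[1], fits$dim[2]),
                f2 = matrix(fits$f2, fits$dim[1], fits$dim[2])))
  }
  f1 <- matrix(NA_real_, fits$dim[1], fits$dim[2])
  f2 <- f1
  lin <- (fits$points[, 2] - 1L) * fits$dim[1] + fits$points[, 1]
  f1[lin] <- fits$f1
  f2[lin] <- fits$f2
  list(f1 = f1, f2 = f2)
}

#' Localized region force (full gradient-descent flow)
#'
#' The right-hand side of the level-set gradient descent of the localized
#' energy at the requested pixels z: the data force
#' `delta(phi(z)) * sum_x K(z,x) delta(phi(x)) *
#'   (lambda1 (I(z)-f1(x))^2 - lambda2 (I(z)-f2(x))^2)`
#' (the squared residuals compare the intensity at the updated pixel with
#' the local interior/exterior means carried by the nearby contour points),
#' plus the length term `v * delta(phi) * div(grad phi / |grad phi|)` and
#' the distance-regularization term `mu * (laplacian(phi) - curvature)`.
#' A negative value moves the pixel toward the interior (`phi` decreases).
#'
#' @inheritParams compute_fitting_means
#' @param fits A [compute_fitting_means()] result covering the kernel
#'   window of every requested pixel (in practice: computed on the full
#'   image or on the narrowband dilated by the kernel radius).
#' @param weights An [energy_weights()] object.
#' @return Numeric vector of updates, one per row of `at_points`.
#' @export
lrf_force <- function(image, phi, fits, kernel, eps_h = 1,
                      weights = energy_weights(), at_points = NULL) {
  pts <- resolve_points(at_points, dim(image))
  dphi <- dirac_eps(phi, eps_h)
  fm <- fit_matrices(fits)
  s <- data_force_cpp(image, dphi, kernel$weights, pts[, 1], pts[, 2],
                      fm$f1, fm$f2,
                      weights$lambda1, weights$lambda2)
  if (anyNA(s))
    stop_validation("fitting means missing inside the kernel window of ",
                    sum(is.na(s)), " requested pixel(s)")
  kappa <- fd_curvature(phi)
  lap <- fd_laplacian(phi)
  lin <- cbind(pts[, 1], pts[, 2])
  dphi[lin] * s +
    weights$v * dphi[lin] * kappa[lin] +
    weights$mu * (lap[lin] - kappa[lin])
}

#' Total localized region energy
#'
#' Discretization (pixel area 1) of the full functional: the localized data
#' double sum, the length penalty `v * sum delta(phi) |grad phi|`, and the
#' distance regularization `mu * sum (|grad phi| - 1)^2 / 2`. Reported per
#' iteration as a diagnostic; the evolution stops on a sign-change
#' criterion, not on the energy.
#'
#' @inheritParams lrf_force
#' @return Scalar energy, with attribute `components` naming the
#'   data/length/regularization parts.
#' @export
total_energy <- function(image, phi, kernel, eps_h = 1,
                         weights = energy_weights()) {
  if (!identical(dim(image), dim(phi)))
    stop_validation("image and phi must have the same shape")
  fits <- compute_fitting_means(image, phi, kernel, eps_h, at_points = NULL)
  f1m <- matrix(fits$f1, nrow(image), ncol(image))
  f2m <- matrix(fits$f2, nrow(image), ncol(image))
  hphi <- heaviside_eps(-phi, eps_h)  # interior membership, interior = {phi < 0}
  dphi <- dirac_eps(phi, eps_h)
  e_data <- energy_data_cpp(image, hphi, dphi, kernel$weights, f1m, f2m,
                            weights$lambda1, weights$lambda2)
  g <- fd_gradient(phi)
  mag <- sqrt(g$dr^2 + g$dc^2)
  e_len <- weights$v * sum(dphi * mag)
  e_reg <- weights$mu * sum((mag - 1)^2) / 2
  structure(e_data + e_len + e_reg,
            components = c(data = e_data, length = e_len, regularization = e_reg))
}
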