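# Multiscale Hessian vesselness and the vascular vector field (VVF).
#
# Convolutions are separable and implemented as banded matrix products with
# replicated (Neumann) borders; second derivatives are exact central
# differences of the Gaussian-smoothed field, scale-normalized by sigma^2.

# n x n one-dimensional convolution operator with replicate boundary.
conv_operator <- function(n, k) {
  h <- (length(k) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (t in -h:h) {
    src <- pmin(pmax(seq_len(n) - t, 1L), n)
    A[cbind(seq_len(n), src)] <- A[cbind(seq_len(n), src)] + k[t + h + 1L]
  }
  A
}

gauss_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_smooth <- function(image, sigma) {
  k <- gauss_1d(sigma)
  A <- conv_operator(nrow(image), k)
  B <- conv_operator(ncol(image), k)
  A %*% image %*% t(B)
}

#' Scale-normalized Hessian of a Gaussian-smoothed image
#'
#' Smooths the image with an isotropic Gaussian of scale `sigma_h` and takes
#' second-order central differences, each multiplied by `sigma_h^2` so that
#' responses are comparable across scales. Field naming: `hxx` is the second
#' derivative along rows, `hyy` along columns, `hxy` the mixed derivative
#' (a single array; the Hessian is symmetric by construction).
#'
#' @param image Numeric intensity matrix.
#' @param sigma_h Hessian scale in pixels (> 0).
#' @return Object of class `hessian_field`: list `hxx`, `hxy`, `hyy`,
#'   `sigma_h`.
#' @export
hessian_at_scale <- function(image, sigma_h) {
  if (!is.numeric(sigma_h) || length(sigma_h) != 1 || sigma_h <= 0)
    stop_validation("sigma_h must be a positive scalar")
  s <- gauss_smooth(image, sigma_h)
  nr <- nrow(s)
  nc <- ncol(s)
  up    <- s[c(1, 1:(nr - 1)), , drop = FALSE]
  down  <- s[c(2:nr, nr), , drop = FALSE]
  left  <- s[, c(1, 1:(nc - 1)), drop = FALSE]
  right <- s[, c(2:nc, nc), drop = FALSE]
  n2 <- sigma_h^2
  structure(list(hxx = n2 * (up + down - 2 * s),
                 hyy = n2 * (left + right - 2 * s),
                 hxy = n2 * d_dc(d_dr(s)),
                 sigma_h = sigma_h),
            class = "hessian_field")
}

#' Closed-form eigendecomposition of a symmetric 2x2 Hessian field
#'
#' Per-pixel eigenvalues ordered by absolute value (`|lam1| <= |lam2|`) and
#' the unit eigenvector `v1 = (v1r, v1c)` of the smaller-magnitude
#' eigenvalue -- the direction along a tubular structure. The degenerate
#' zero Hessian gets `v1 = (1, 0)` by convention (its vesselness is 0, so
#' the choice never acts).
#'
#' @param h A [hessian_at_scale()] result.
#' @return List with matrices `lam1`, `lam2`, `v1r`, `v1c`.
#' @export
eigen2x2 <- function(h) {
  m <- (h$hxx + h$hyy) / 2
  half_diff <- (h$hxx - h$hyy) / 2
  disc <- sqrt(half_diff^2 + h$hxy^2)
  ea <- m + disc
  eb <- m - disc
  swap <- abs(ea) > abs(eb)
  lam1 <- ifelse(swap, eb, ea)
  lam2 <- ifelse(swap, ea, eb)
  # eigenvector of lam1: rows of (H - lam1 I) are orthogonal to it; take the
  # larger of the two candidate vectors for numerical stability
  c1r <- h$hxy
  c1c <- lam1 - h$hxx
  c2r <- lam1 - h$hyy
  c2c <- h$hxy
  n1 <- c1r^2 + c1c^2
  n2 <- c2r^2 + c2c^2
  use2 <- n2 > n1
  vr <- ifelse(use2, c2r, c1r)
  vc <- ifelse(use2, c2c, c1c)
  nm <- sqrt(vr^2 + vc^2)
  degen <- nm < 1e-300
  vr[degen] <- 1
  vc[degen] <- 0
  nm[degen] <- 1
  list(lam1 = lam1, lam2 = lam2, v1r = vr / nm, v1c = vc / nm)
}

#' Single-scale vesselness response
#'
#' For bright tubes on a dark background: 0 wherever `lam2 > 0`, otherwise
#' `exp(-RB^2 / (2 alpha^2)) * (1 - exp(-S^2 / (2 beta^2)))` with the
#' blobness ratio `RB = |lam1| / |lam2|` and the second-order structuredness
#' `S = sqrt(lam1^2 + lam2^2)`. A vanishing `S` (hence `lam2 = 0`) returns 0
#' without evaluating `RB`.
#'
#' @param lam1,lam2 Eigenvalue arrays with `|lam1| <= |lam2|` everywhere.
#' @param alpha Blobness sensitivity (default 0.5).
#' @param beta Structuredness sensitivity (> 0).
#' @return Array of responses in [0, 1].
#' @export
vesselness_response <- function(lam1, lam2, alpha = 0.5, beta) {
  if (any(abs(lam1) > abs(lam2) + 1e-12))
    stop_validation("eigenvalue ordering violated: need |lam1| <= |lam2|")
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop_validation("beta must be a positive scalar")
  S2 <- lam1^2 + lam2^2
  rb2 <- (lam1 / ifelse(lam2 == 0, 1, lam2))^2
  val <- exp(-rb2 / (2 * alpha^2)) * (1 - exp(-S2 / (2 * beta^2)))
  ifelse(lam2 <= 0 & S2 > 0, val, 0)
}

#' Multiscale vesselness field
#'
#' Pixelwise maximum of the single-scale responses over an increasing list
#' of Hessian scales; the vessel direction `v1` and `best_scale` are taken
#' from the maximizing scale (ties resolved toward the smallest scale, for
#' determinism). With `beta = NULL` the structuredness sensitivity adapts
#' per scale to half the maximum `S` observed in the image at that scale --
#' the standard data-driven choice, which keeps responses in a usable range
#' across modalities.
#'
#' @param image Numeric intensity matrix in [0, 1] (bright vessels on dark
#'   background; invert the image for the opposite polarity).
#' @param scales Increasing vector of Hessian scales in pixels (default
#'   `c(1, 1.5, 2, 3, 4, 5)`, spanning vessel diameters of roughly 2-10 px).
#' @param alpha Blobness sensitivity (default 0.5).
#' @param beta Structuredness sensitivity; `NULL` (default) for the per-scale
#'   adaptive choice.
#' @return Object of class `vesselness_field`: list with matrices `R` (in
#'   [0, 1]), `best_scale`, `v1r`, `v1c`, and `params`.
#' @export
multiscale_vesselness <- function(image, scales = c(1, 1.5, 2, 3, 4, 5),
                                  alpha = 0.5, beta = NULL) {
  if (length(scales) == 0) stop_validation("scale list must be non-empty")
  if (is.unsorted(scales, strictly = TRUE))
    stop_validation("scales must be strictly increasing")
  R <- matrix(-1, nrow(image), ncol(image))
  best <- matrix(NA_real_, nrow(image), ncol(image))
  v1r <- matrix(1, nrow(image), ncol(image))
  v1c <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    h <- hessian_at_scale(image, s)
    e <- eigen2x2(h)
    S <- sqrt(e$lam1^2 + e$lam2^2)
    b <- beta %||% max(max(S) / 2, .Machine$double.eps)
    Rs <- vesselness_response(e$lam1, e$lam2, alpha, b)
    take <- Rs > R  # strict: first maximizer wins ties
    R[take] <- Rs[take]
    best[take] <- s
    v1r[take] <- e$v1r[take]
    v1c[take] <- e$v1c[take]
  }
  structure(list(R = R, best_scale = best, v1r = v1r, v1c = v1c,
                 params = list(scales = scales, alpha = alpha, beta = beta)),
            class = "vesselness_field")
}

#' Vascular vector field direction
#'
#' The vessel direction `v1` wherever the vesselness exceeds the threshold
#' `tau`, the zero vector elsewhere; then sign-aligned with the level-set
#' gradient (flipped wherever `V . grad(phi) < 0`) so the field always
#' points with the outward contour normal.
#'
#' @param vess A [multiscale_vesselness()] field.
#' @param grad_phi A [fd_gradient()] list for the current level set.
#' @param tau Vesselness threshold (default 0.05).
#' @return List of matrices `Vr`, `Vc`.
#' @export
vvf_direction <- function(vess, grad_phi, tau = 0.05) {
  on <- vess$R > tau
  Vr <- ifelse(on, vess$v1r, 0)
  Vc <- ifelse(on, vess$v1c, 0)
  flip <- (Vr * grad_phi$dr + Vc * grad_phi$dc) < 0
  Vr[flip] <- -Vr[flip]
  Vc[flip] <- -Vc[flip]
  list(Vr = Vr, Vc = Vc)
}

#' VVF speed function
#'
#' `f(R) = (1 + (2/pi) * atan((R - eps_v)/eps_v)) / 2`: strictly increasing
#' in the vesselness, 0.5 exactly at `R = eps_v`, rising quickly above the
#' threshold and falling toward 0 below it -- the front moves fast inside
#' vessels, slows at their boundaries, and stalls outside.
#'
#' @param R Vesselness values.
#' @param eps_v Speed threshold (> 0, default 0.05).
#' @return Values in (0, 1), same shape as `R`.
#' @export
vvf_speed <- function(R, eps_v = 0.05) {
  if (!is.numeric(eps_v) || length(eps_v) != 1 || eps_v <= 0)
    stop_validation("eps_v must be a positive scalar")
  (1 + (2 / pi) * atan((R - eps_v) / eps_v)) / 2
}

#' VVF force term
#'
#' `lam_vvf * f(R) * |V . grad(phi)|`. With the conventional negative
#' `lam_vvf` this inflates the contour along vessel directions, pushing the
#' front into thin and weak branches; a positive weight instead shrinks the
#' contour onto thick vessels.
#'
#' @param V A [vvf_direction()] list.
#' @param fR Speed values from [vvf_speed()].
#' @param grad_phi A [fd_gradient()] list.
#' @param lam_vvf Scalar weight (default -0.1).
#' @return Matrix of per-pixel force values.
#' @export
vvf_force <- function(V, fR, grad_phi, lam_vvf = -0.1) {
  lam_vvf * fR * abs(V$Vr * grad_phi$dr + V$Vc * grad_phi$dc)
}
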