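# Independent brute-force oracles, written as plain double loops over the
# defining sums. They share no code with the package internals (beyond the
# closed-form Heaviside/Dirac, re-stated here) and are only run on tiny
# instances.

oracle_heaviside <- function(x, eps) {
  if (x > eps) return(1)
  if (x < -eps) return(0)
  (1 + 2 * atan(x / eps) / pi) / 2
}

oracle_dirac <- function(x, eps) eps / (pi * (eps^2 + x^2))

# f1/f2 at one pixel by direct summation of the kernel-weighted means,
# clipping the stencil at the borders (interior = {phi < 0}).
oracle_fitting_means <- function(image, phi, kw, eps, r0, c0) {
  rad <- kw$radius
  n1 <- d1 <- n2 <- d2 <- 0
  for (dr in -rad:rad) for (dc in -rad:rad) {
    r <- r0 + dr; c <- c0 + dc
    if (r < 1 || r > nrow(image) || c < 1 || c > ncol(image)) next
    k <- kw$weights[dr + rad + 1, dc + rad + 1]
    h <- oracle_heaviside(-phi[r, c], eps)
    n1 <- n1 + k * h * image[r, c];      d1 <- d1 + k * h
    n2 <- n2 + k * (1 - h) * image[r, c]; d2 <- d2 + k * (1 - h)
  }
  c(f1 = n1 / d1, f2 = n2 / d2)
}

# Data force (descent of the localized energy) at one pixel z: the residual
# uses I(z); the fitting means and the Dirac weight come from the neighbors.
oracle_data_force <- function(image, phi, kw, eps, f1m, f2m, r0, c0,
                              l1 = 1, l2 = 1) {
  rad <- kw$radius
  s <- 0
  Iz <- image[r0, c0]
  for (dr in -rad:rad) for (dc in -rad:rad) {
    r <- r0 + dr; c <- c0 + dc
    if (r < 1 || r > nrow(image) || c < 1 || c > ncol(image)) next
    k <- kw$weights[dr + rad + 1, dc + rad + 1]
    s <- s + k * oracle_dirac(phi[r, c], eps) *
      (l1 * (Iz - f1m[r, c])^2 - l2 * (Iz - f2m[r, c])^2)
  }
  oracle_dirac(phi[r0, c0], eps) * s
}

# Full discretized energy by direct double summation (data term) plus the
# length and distance-regularization sums on package finite differences.
oracle_total_energy <- function(image, phi, kw, eps, w) {
  rad <- kw$radius
  fits <- compute_fitting_means(image, phi, kw, eps)
  f1m <- matrix(fits$f1, nrow(image)); f2m <- matrix(fits$f2, nrow(image))
  e_data <- 0
  for (r0 in seq_len(nrow(image))) for (c0 in seq_len(ncol(image))) {
    s <- 0
    for (dr in -rad:rad) for (dc in -rad:rad) {
      r <- r0 + dr; c <- c0 + dc
      if (r < 1 || r > nrow(image) || c < 1 || c > ncol(image)) next
      k <- kw$weights[dr + rad + 1, dc + rad + 1]
      h <- oracle_heaviside(-phi[r, c], eps)
      s <- s + k * (h * w$lambda1 * (image[r, c] - f1m[r0, c0])^2 +
                    (1 - h) * w$lambda2 * (image[r, c] - f2m[r0, c0])^2)
    }
    e_data <- e_data + oracle_dirac(phi[r0, c0], eps) * s
  }
  g <- fd_gradient(phi)
  mag <- sqrt(g$dr^2 + g$dc^2)
  e_data + w$v * sum(dirac_eps(phi, eps) * mag) + w$mu * sum((mag - 1)^2) / 2
}

# Exhaustive MRMSE: nearest evolved point within the Chebyshev-r window of
# each truth point; k3 = evolved points never chosen and with empty windows.
oracle_mrmse <- function(tp, ep, r) {
  k1 <- 0; sumd2 <- 0
  used <- rep(FALSE, nrow(ep))
  if (nrow(tp) > 0 && nrow(ep) > 0) {
    for (i in seq_len(nrow(tp))) {
      best <- Inf; bj <- 0
      for (j in seq_len(nrow(ep))) {
        if (abs(ep[j, 1] - tp[i, 1]) > r || abs(ep[j, 2] - tp[i, 2]) > r) next
        d2 <- (ep[j, 1] - tp[i, 1])^2 + (ep[j, 2] - tp[i, 2])^2
        if (d2 < best) { best <- d2; bj <- j }
      }
      if (bj > 0) { k1 <- k1 + 1; sumd2 <- sumd2 + best; used[bj] <- TRUE }
    }
  }
  k2 <- nrow(tp) - k1
  k3 <- 0
  for (j in seq_len(nrow(ep))) {
    if (used[j]) next
    hit <- FALSE
    if (nrow(tp) > 0)
      for (i in seq_len(nrow(tp)))
        if (abs(ep[j, 1] - tp[i, 1]) <= r && abs(ep[j, 2] - tp[i, 2]) <= r) {
          hit <- TRUE; break
        }
    if (!hit) k3 <- k3 + 1
  }
  (sumd2 + 2 * (k2 + k3) * r^2) / (k1 + k2 + k3)
}

# A rendered straight horizontal bright bar on a dark canvas.
make_bar_image <- function(nr, nc, row_center, half_width, intensity = 1) {
  img <- matrix(0, nr, nc)
  rows <- abs(seq_len(nr) - row_center) <= half_width
  img[rows, ] <- intensity
  img
}
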