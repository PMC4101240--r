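#' Evolution parameters
#'
#' Defaults follow the model's standard settings: explicit Euler step
#' `dt = 0.1`, length weight `v = 0.2`, distance-regularization weight
#' `mu = 1.0`, VVF weight `lam_vvf = -0.1` (negative: inflate along
#' vessels). The remaining knobs control the acceleration machinery:
#' `band_width` is the narrowband half-width in pixels (Chebyshev distance
#' from a sign change of `phi`), `freeze_patience` the number of
#' consecutive sign-stable iterations before a pixel is frozen,
#' `stop_frac`/`stop_patience` the convergence rule (stop when the fraction
#' of band pixels changing sign stays below `stop_frac` for `stop_patience`
#' consecutive iterations).
#'
#' @param dt Time step (> 0).
#' @param v Length-penalty weight.
#' @param mu Distance-regularization weight.
#' @param lam_vvf VVF force weight.
#' @param lambda1,lambda2 Interior/exterior data weights.
#' @param band_width Narrowband half-width in pixels (>= 2).
#' @param freeze_patience Consecutive stable iterations before freezing
#'   (>= 1); use `Inf` to disable freezing.
#' @param max_iters Iteration cap.
#' @param stop_frac Sign-change fraction below which the front counts as
#'   stationary.
#' @param stop_patience Number of consecutive stationary iterations required
#'   to stop.
#' @param eps_h Heaviside/Dirac regularization width.
#' @param rho Initialization height (used in the freeze guard `|phi| >=
#'   rho/2`).
#' @param tau VVF direction threshold.
#' @param eps_v VVF speed threshold.
#' @param energy_every Compute the total energy every this many iterations
#'   for the energy trace (0 disables the trace; the energy is diagnostic,
#'   not a stopping rule).
#' @return List of class `evolve_params`.
#' @export
evolve_params <- function(dt = 0.1, v = 0.2, mu = 1.0, lam_vvf = -0.1,
                          lambda1 = 1, lambda2 = 1,
                          band_width = 4, freeze_patience = 10,
                          max_iters = 500, stop_frac = 1e-3,
                          stop_patience = 20, eps_h = 1, rho = 2,
                          tau = 0.05, eps_v = 0.05, energy_every = 1) {
  if (dt <= 0) stop_validation("dt must be > 0")
  if (band_width < 2) stop_validation("band_width must be >= 2")
  if (freeze_patience < 1) stop_validation("freeze_patience must be >= 1")
  structure(list(dt = dt, v = v, mu = mu, lam_vvf = lam_vvf,
                 lambda1 = lambda1, lambda2 = lambda2,
                 band_width = band_width, freeze_patience = freeze_patience,
                 max_iters = max_iters, stop_frac = stop_frac,
                 stop_patience = stop_patience, eps_h = eps_h, rho = rho,
                 tau = tau, eps_v = eps_v, energy_every = energy_every),
            class = "evolve_params")
}

# Pixels adjacent (4-neighborhood) to a sign change of phi, including both
# sides of the crossing; sign(0) counts as its own state.
sign_change_pixels <- function(phi) {
  s <- sign(phi)
  nr <- nrow(s)
  nc <- ncol(s)
  cross <- matrix(FALSE, nr, nc)
  dv <- s[-nr, ] != s[-1, ]
  cross[-nr, ] <- cross[-nr, ] | dv
  cross[-1, ] <- cross[-1, ] | dv
  dh <- s[, -nc] != s[, -1]
  cross[, -nc] <- cross[, -nc] | dh
  cross[, -1] <- cross[, -1] | dh
  cross
}

# Chebyshev dilation of a set of linear pixel indices by `radius`; returns
# the dilated set as a (row, col) matrix. Falls back to the full grid when
# the dilation covers (almost) everything.
dilate_points <- function(idx, dm, radius) {
  m <- matrix(FALSE, dm[1], dm[2])
  m[idx] <- TRUE
  m <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1),
                                          EBImage::makeBrush(2 * radius + 1,
                                                             "box"))) > 0
  if (all(m)) return(NULL)  # NULL = full grid for compute_fitting_means
  which(m, arr.ind = TRUE)
}

# One 3x3 binary dilation (Chebyshev ball of radius 1), replicate borders.
dilate1 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  v <- m | m[c(1, 1:(nr - 1)), ] | m[c(2:nr, nr), ]
  v | v[, c(1, 1:(nc - 1))] | v[, c(2:nc, nc)]
}

#' Build the narrowband of active pixels
#'
#' All non-frozen pixels within Chebyshev distance `band_width` of a
#' 4-neighbor sign change of `phi`. Restricting the update to this band
#' leaves the evolution unchanged (forces vanish away from the front up to
#' the Dirac tail) while cutting the per-iteration cost.
#'
#' @param phi Level-set matrix.
#' @param band_width Half-width in pixels.
#' @param frozen Optional logical matrix of permanently frozen pixels.
#' @return Integer vector of linear (column-major) pixel indices; empty when
#'   `phi` has no sign change.
#' @export
build_narrowband <- function(phi, band_width = 4, frozen = NULL) {
  band <- sign_change_pixels(phi)
  for (i in seq_len(band_width)) band <- dilate1(band)
  if (!is.null(frozen)) band <- band & !frozen
  which(band)
}

#' Create the evolution state for a level set
#'
#' @param phi Initial level-set matrix (e.g. from [init_level_set()]).
#' @param params An [evolve_params()] object.
#' @return List of class `evolution_state`: `phi`, `iter`, logical `frozen`,
#'   integer `band` (linear indices), `sign_hist` (consecutive sign-stable
#'   iteration counts), `prev_sign`, `energy_trace`, `sign_change_frac`.
#' @export
init_evolution_state <- function(phi, params = evolve_params()) {
  frozen <- matrix(FALSE, nrow(phi), ncol(phi))
  structure(list(phi = phi, iter = 0L, frozen = frozen,
                 band = build_narrowband(phi, params$band_width, frozen),
                 sign_hist = matrix(0L, nrow(phi), ncol(phi)),
                 prev_sign = sign(phi),
                 energy_trace = numeric(0),
                 sign_change_frac = numeric(0)),
            class = "evolution_state")
}

#' One explicit evolution step on the narrowband
#'
#' Updates `phi` at band pixels only by
#' `phi <- phi + dt * (localized region force + VVF force)`; frozen and
#' off-band pixels are untouched. The fitting means and the VVF sign
#' alignment are recomputed from the current `phi`; the vesselness map and
#' speed are `phi`-independent and passed in precomputed. The band and the
#' sign-stability counters are refreshed afterwards.
#'
#' @param state An [init_evolution_state()] state.
#' @param image Intensity matrix.
#' @param kernel A [gaussian_kernel()] window.
#' @param vess A [multiscale_vesselness()] field (or `NULL` to disable the
#'   VVF term).
#' @param params An [evolve_params()] object.
#' @return The updated state.
#' @export
evolve_step <- function(state, image, kernel, vess, params = evolve_params()) {
  if (!identical(dim(state$phi), dim(image)))
    stop_validation("state and image shapes disagree")
  phi <- state$phi
  band <- state$band
  if (length(band) > 0) {
    pts <- cbind(row = ((band - 1L) %% nrow(phi)) + 1L,
                 col = ((band - 1L) %/% nrow(phi)) + 1L)
    w <- energy_weights(params$lambda1, params$lambda2, params$v, params$mu)
    # the data force at a band pixel reads f1/f2 across its whole kernel
    # window: evaluate the fitting means on the band dilated by the radius
    fit_pts <- dilate_points(band, dim(phi), kernel$radius)
    fits <- compute_fitting_means(image, phi, kernel, params$eps_h, fit_pts)
    force <- lrf_force(image, phi, fits, kernel, params$eps_h, w, pts)
    if (!is.null(vess) && params$lam_vvf != 0) {
      g <- fd_gradient(phi)
      V <- vvf_direction(vess, g, params$tau)
      fR <- vess$fR %||% vvf_speed(vess$R, params$eps_v)
      vf <- vvf_force(V, fR, g, params$lam_vvf)
      force <- force + vf[band]
    }
    phi[band] <- phi[band] + params$dt * force
  }
  new_sign <- sign(phi)
  changed <- new_sign != state$prev_sign
  state$sign_hist <- ifelse(changed, 0L, state$sign_hist + 1L)
  state$sign_change_frac <- c(state$sign_change_frac,
                              if (length(band) > 0) sum(changed[band]) / length(band)
                              else 0)
  state$prev_sign <- new_sign
  state$phi <- phi
  state$iter <- state$iter + 1L
  state$band <- build_narrowband(phi, params$band_width, state$frozen)
  state
}

#' Freeze steadily evolved pixels
#'
#' Band pixels whose `phi`-sign has not changed for `freeze_patience`
#' consecutive iterations and whose `|phi| >= rho/2` are frozen permanently
#' and removed from the band: their segmentation label is regarded as
#' final, so they are skipped in all subsequent iterations. The `|phi|`
#' guard keeps pixels sitting on the contour itself (stable sign, unstable
#' position) active.
#'
#' @param state An evolution state.
#' @param params An [evolve_params()] object (`freeze_patience`, `rho`,
#'   `band_width`).
#' @return The updated state.
#' @export
update_freeze_labels <- function(state, params = evolve_params()) {
  M <- params$freeze_patience
  if (!is.finite(M) || length(state$band) == 0) return(state)
  b <- state$band
  hit <- b[state$sign_hist[b] >= M & abs(state$phi[b]) >= params$rho / 2]
  if (length(hit)) {
    state$frozen[hit] <- TRUE
    state$band <- setdiff(state$band, hit)
  }
  state
}

#' Segment vessels in a grayscale image
#'
#' Full pipeline: multiscale vesselness -> automatic rough-mask
#' initialization (or a user-supplied mask) -> three-valued level-set
#' initialization -> narrowband evolution under the localized region force
#' plus the VVF force, with steady-point freezing -- until the front is
#' stationary (sign-change fraction below `stop_frac` for `stop_patience`
#' consecutive iterations), the band empties, or `max_iters` is reached.
#'
#' @param image Intensity matrix in [0, 1].
#' @param config A configuration list from [default_config()] (or a
#'   modified copy).
#' @param init_mask Optional logical matrix to use instead of the automatic
#'   initialization.
#' @param log Optional connection or file path for per-iteration log lines
#'   (iteration, band size, frozen count, sign-change fraction, energy).
#' @return Object of class `vessel_segmentation`: list with `mask`
#'   (logical, the `phi < 0` region), `phi`, `contours`, `init_mask`,
#'   `energy_trace`, `sign_change_frac`, `iterations`, `converged`,
#'   `frozen_count`, `vesselness`, and the `config` used.
#' @export
segment_vessels <- function(image, config = default_config(),
                            init_mask = NULL, log = NULL) {
  config <- validate_config(config)
  image <- normalize01(image)
  if (isTRUE(config$invert)) image <- 1 - image
  sigma <- config$sigma %||% default_sigma(nrow(image), ncol(image))
  kernel <- gaussian_kernel(sigma)
  vess <- multiscale_vesselness(image, config$scales, config$alpha, config$beta)
  vess$fR <- vvf_speed(vess$R, config$eps_v)

  if (is.null(init_mask)) {
    init_mask <- rough_vessel_mask(image, vess, config$init_threshold,
                                   config$min_object_px)
  } else {
    if (!identical(dim(init_mask), dim(image)))
      stop_validation("init_mask shape must match the image")
    init_mask <- init_mask > 0
  }
  phi0 <- init_level_set(init_mask, config$rho)

  params <- evolve_params(
    dt = config$dt, v = config$v, mu = config$mu, lam_vvf = config$lam_vvf,
    lambda1 = config$lambda1, lambda2 = config$lambda2,
    band_width = config$band_width, freeze_patience = config$freeze_patience,
    max_iters = config$max_iters, stop_frac = config$stop_frac,
    stop_patience = config$stop_patience, eps_h = config$eps_h,
    rho = config$rho, tau = config$tau, eps_v = config$eps_v,
    energy_every = config$energy_every)
  w <- energy_weights(params$lambda1, params$lambda2, params$v, params$mu)

  logcon <- NULL
  if (!is.null(log)) {
    logcon <- if (inherits(log, "connection")) log else file(log, "w")
    if (!inherits(log, "connection")) on.exit(close(logcon), add = TRUE)
    writeLines(paste0("# config: ", paste(names(config), unlist(lapply(config,
      function(x) paste(format(x), collapse = " "))), sep = "=",
      collapse = " ")), logcon)
    writeLines("iteration band_size frozen sign_change_frac energy", logcon)
  }

  state <- init_evolution_state(phi0, params)
  converged <- FALSE
  stationary <- 0L
  while (state$iter < params$max_iters) {
    if (length(state$band) == 0) { converged <- TRUE; break }
    state <- evolve_step(state, image, kernel, vess, params)
    state <- update_freeze_labels(state, params)
    frac <- state$sign_change_frac[state$iter]
    energy <- NA_real_
    if (params$energy_every > 0 && state$iter %% params$energy_every == 0) {
      energy <- as.numeric(total_energy(image, state$phi, kernel,
                                        params$eps_h, w))
      state$energy_trace <- c(state$energy_trace, energy)
    }
    if (!is.null(logcon))
      writeLines(sprintf("%d %d %d %.6g %.8g", state$iter,
                         length(state$band), sum(state$frozen), frac, energy),
                 logcon)
    stationary <- if (frac < params$stop_frac) stationary + 1L else 0L
    if (stationary >= params$stop_patience) { converged <- TRUE; break }
  }

  structure(list(mask = state$phi < 0, phi = state$phi,
                 contours = extract_zero_contour(state$phi),
                 init_mask = init_mask,
                 energy_trace = state$energy_trace,
                 sign_change_frac = state$sign_change_frac,
                 iterations = state$iter, converged = converged,
                 frozen_count = sum(state$frozen),
                 vesselness = vess, config = config),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat("vessel_segmentation:", nrow(x$mask), "x", ncol(x$mask), "image\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  cat("  mask area:", sum(x$mask), "px (",
      round(100 * mean(x$mask), 1), "% of image )\n")
  cat("  contour components:", length(x$contours),
      "; frozen pixels:", x$frozen_count, "\n")
  invisible(x)
}
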