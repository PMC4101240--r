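test_that("narrowband is an annulus around the front and monotone in width", {
  d <- sqrt(outer((1:50 - 25)^2, (1:50 - 25)^2, `+`))
  phi <- d - 10
  b3 <- build_narrowband(phi, 3)
  b5 <- build_narrowband(phi, 5)
  expect_true(all(b3 %in% b5))
  # distance-transform oracle: band pixels lie within band_width (Chebyshev)
  # of a 4-neighbor sign change
  cross <- which(vesselac:::sign_change_pixels(phi), arr.ind = TRUE)
  pts <- arrayInd(b3, c(50, 50))
  cheb <- vapply(seq_len(nrow(pts)), function(i)
    min(pmax(abs(cross[, 1] - pts[i, 1]), abs(cross[, 2] - pts[i, 2]))),
    numeric(1))
  expect_true(all(cheb <= 3))
  expect_length(build_narrowband(matrix(1, 10, 10), 3), 0)
})

test_that("a narrowband step equals the full-grid step at band pixels", {
  ph <- render_phantom(default_y_phantom(seed = 3, noise_fraction = 0.1))
  v <- multiscale_vesselness(ph$image)
  v$fR <- vvf_speed(v$R, 0.05)
  kern <- gaussian_kernel(default_sigma(110, 110))
  p <- evolve_params()
  m0 <- rough_vessel_mask(ph$image, v)
  st <- init_evolution_state(init_level_set(m0, 2), p)
  band <- st$band
  st_band <- evolve_step(st, ph$image, kern, v, p)
  st_full <- st
  st_full$band <- seq_along(st$phi)
  st_full <- evolve_step(st_full, ph$image, kern, v, p)
  expect_lt(max(abs(st_band$phi[band] - st_full$phi[band])), 1e-12)
  # off-band pixels untouched in the banded step
  off <- setdiff(seq_along(st$phi), band)
  expect_identical(st_band$phi[off], st$phi[off])
})

test_that("frozen pixels never change and patience above the horizon freezes nothing", {
  img <- make_bar_image(30, 30, 15, 3)
  v <- multiscale_vesselness(img)
  v$fR <- vvf_speed(v$R, 0.05)
  kern <- gaussian_kernel(default_sigma(30, 30))
  p <- evolve_params(freeze_patience = 2)
  st <- init_evolution_state(init_level_set(rough_vessel_mask(img, v), 2), p)
  for (i in 1:6) {
    st <- evolve_step(st, img, kern, v, p)
    st <- update_freeze_labels(st, p)
  }
  expect_gt(sum(st$frozen), 0)
  frozen_before <- st$phi[st$frozen]
  for (i in 1:5) st <- evolve_step(st, img, kern, v, p)
  expect_identical(st$phi[st$frozen], frozen_before)
  expect_false(any(st$frozen[st$band]))

  # freeze_patience = Inf: nothing is ever frozen
  p2 <- evolve_params(freeze_patience = Inf)
  st2 <- init_evolution_state(init_level_set(rough_vessel_mask(img, v), 2), p2)
  for (i in 1:6) {
    st2 <- evolve_step(st2, img, kern, v, p2)
    st2 <- update_freeze_labels(st2, p2)
  }
  expect_equal(sum(st2$frozen), 0)
})

test_that("sign-stability counters reset on flips and guard |phi| >= rho/2", {
  p <- evolve_params(freeze_patience = 3, rho = 2)
  phi <- matrix(c(-2, 2), 6, 6)
  st <- init_evolution_state(phi, p)
  st$sign_hist[] <- 5L
  # a pixel sitting on the contour (|phi| < rho/2) is not frozen
  lin <- st$band[1]
  st$phi[lin] <- 0.4
  pre_band <- st$band
  st <- update_freeze_labels(st, p)
  expect_false(st$frozen[lin])
  # every stable off-contour band pixel is frozen
  lin2 <- pre_band[abs(st$phi[pre_band]) >= 1]
  expect_true(all(st$frozen[lin2]))
  # counters below the patience do not freeze
  st2 <- init_evolution_state(phi, p)
  st2$sign_hist[] <- 2L
  st2 <- update_freeze_labels(st2, p)
  expect_equal(sum(st2$frozen), 0)
})

test_that("curve shortening shrinks the enclosed area with only the length term", {
  d <- sqrt(outer((1:40 - 20)^2, (1:40 - 20)^2, `+`))
  phi <- d - 8
  img <- matrix(0.5, 40, 40)  # uniform: data term vanishes
  kern <- gaussian_kernel(2)
  p <- evolve_params(lam_vvf = 0, mu = 0, v = 1, freeze_patience = Inf,
                     max_iters = 150)
  st <- init_evolution_state(phi, p)
  area0 <- sum(st$phi < 0)
  areas <- numeric(150)
  for (i in 1:150) {
    st <- evolve_step(st, img, kern, NULL, p)
    areas[i] <- sum(st$phi < 0)
  }
  expect_true(all(diff(c(area0, areas)) <= 0))
  expect_lt(areas[150], area0)
})

test_that("zero iterations return the initialization unchanged", {
  ph <- render_phantom(default_y_phantom(seed = 1, noise_fraction = 0))
  cfg <- default_config()
  cfg$max_iters <- 0
  cfg$energy_every <- 0
  res <- segment_vessels(ph$image, cfg)
  expect_equal(res$iterations, 0)
  expect_setequal(unique(as.vector(res$phi)), c(-2, 0, 2))
  expect_identical(res$mask, res$phi < 0)
})

test_that("segmentation of the noiseless phantom recovers the truth", {
  ph <- render_phantom(default_y_phantom(seed = 1, noise_fraction = 0))
  cfg <- default_config()
  cfg$energy_every <- 0
  res <- segment_vessels(ph$image, cfg)
  expect_gte(dice(res$mask, ph$mask), 0.9)
  expect_true(res$converged)
})

test_that("runs are deterministic and phi stays near unit slope on the band", {
  ph <- render_phantom(default_y_phantom(seed = 4, noise_fraction = 0.1))
  cfg <- default_config()
  cfg$energy_every <- 0
  r1 <- segment_vessels(ph$image, cfg)
  r2 <- segment_vessels(ph$image, cfg)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$phi, r2$phi)
  g <- fd_gradient(r1$phi)
  # distance regularization keeps |grad phi| near 1 where the evolution was
  # active: the Dirac-weighted zone |phi| < eps-support around the contour
  # (frozen flanks keep their three-valued plateaus by design)
  active <- which(abs(r1$phi) < 1)
  expect_lt(mean(abs(sqrt(g$dr^2 + g$dc^2) - 1)[active]), 0.3)
})

test_that("configuration validation rejects unknown keys and round-trips", {
  expect_error(validate_config(list(dd = 1)), "dd")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  cfg <- default_config()
  cfg$v <- 0.3
  write_config(cfg, tmp)
  back <- read_config(tmp)
  expect_equal(back$v, 0.3)
  expect_equal(back$scales, cfg$scales)
  expect_equal(back$dt, 0.1)
})
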