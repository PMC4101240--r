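test_that("fitting means of a constant image equal the constant", {
  img <- matrix(0.7, 15, 15)
  phi <- matrix(rep(c(-2, 2), length.out = 225), 15, 15)
  fits <- compute_fitting_means(img, phi, gaussian_kernel(2))
  expect_true(all(abs(fits$f1[fits$defined] - 0.7) < 1e-12))
  expect_true(all(abs(fits$f2[fits$defined] - 0.7) < 1e-12))
})

test_that("fitting means match the direct-summation oracle on random fields", {
  set.seed(42)
  img <- matrix(runif(400), 20, 20)
  phi <- matrix(rnorm(400, sd = 2), 20, 20)
  kw <- gaussian_kernel(1.5)
  pts <- cbind(sample(20, 12, TRUE), sample(20, 12, TRUE))
  fits <- compute_fitting_means(img, phi, kw, eps_h = 1, at_points = pts)
  for (i in seq_len(nrow(pts))) {
    o <- oracle_fitting_means(img, phi, kw, 1, pts[i, 1], pts[i, 2])
    expect_equal(fits$f1[i], o[["f1"]], tolerance = 1e-10)
    expect_equal(fits$f2[i], o[["f2"]], tolerance = 1e-10)
  }
  # bounded by local intensity range wherever defined
  expect_true(all(fits$f1 >= 0 & fits$f1 <= 1))
  expect_true(all(fits$f2 >= 0 & fits$f2 <= 1))
})

test_that("fitting means separate a step image and fall back off-support", {
  n <- 40
  img <- cbind(matrix(0, n, 20), matrix(1, n, 20))
  phi <- cbind(matrix(2, n, 20), matrix(-2, n, 20))  # interior = bright right
  kw <- gaussian_kernel(2)
  # probes whose window still straddles the step: the saturated Heaviside
  # makes the separation exact
  pts <- cbind(20, c(22, 24))
  fits <- compute_fitting_means(img, phi, kw, eps_h = 1, at_points = pts)
  expect_true(all(abs(fits$f1 - 1) < 1e-6))
  expect_true(all(abs(fits$f2 - 0) < 1e-6))
  expect_true(all(fits$defined))
  # deep inside the interior the truncated kernel has no exterior mass:
  # the pixel is flagged undefined and f2 falls back to the plain local mean
  deep <- compute_fitting_means(img, phi, kw, eps_h = 1,
                                at_points = cbind(20, 34))
  expect_false(deep$defined)
  expect_equal(deep$f2, 1)
})

test_that("narrowband-restricted fitting means equal the full-image values", {
  set.seed(7)
  img <- matrix(runif(18 * 18), 18, 18)
  phi <- matrix(rnorm(18 * 18), 18, 18)
  kw <- gaussian_kernel(2)
  pts <- cbind(sample(18, 9, TRUE), sample(18, 9, TRUE))
  sub <- compute_fitting_means(img, phi, kw, at_points = pts)
  full <- compute_fitting_means(img, phi, kw)
  lin <- (pts[, 2] - 1) * 18 + pts[, 1]
  expect_identical(sub$f1, full$f1[lin])
  expect_identical(sub$f2, full$f2[lin])
})

test_that("data force matches the brute-force oracle and has the right sign", {
  set.seed(11)
  img <- matrix(runif(256), 16, 16)
  phi <- matrix(rnorm(256, sd = 1.5), 16, 16)
  kw <- gaussian_kernel(1.2)
  w <- energy_weights(v = 0, mu = 0)
  fits <- compute_fitting_means(img, phi, kw)
  f1m <- matrix(fits$f1, 16, 16); f2m <- matrix(fits$f2, 16, 16)
  pts <- cbind(sample(16, 10, TRUE), sample(16, 10, TRUE))
  force <- lrf_force(img, phi, fits, kw, 1, w, pts)
  for (i in seq_len(nrow(pts))) {
    o <- oracle_data_force(img, phi, kw, 1, f1m, f2m, pts[i, 1], pts[i, 2])
    expect_equal(force[i], o, tolerance = 1e-10)
  }

  # constant image: data term identically zero (residuals cancel)
  cimg <- matrix(0.4, 16, 16)
  cfits <- compute_fitting_means(cimg, phi, kw)
  cforce <- lrf_force(cimg, phi, cfits, kw, 1, w, pts)
  expect_true(all(abs(cforce) < 1e-12))

  # a pixel matching the interior mean better than the exterior one is
  # pulled inward (phi decreases, interior = {phi < 0})
  img2 <- matrix(0, 16, 16); img2[6:11, 6:11] <- 1
  phi2 <- matrix(2, 16, 16); phi2[7:10, 7:10] <- -2
  phi2[6:11, 6] <- 0
  fits2 <- compute_fitting_means(img2, phi2, kw)
  f2 <- lrf_force(img2, phi2, fits2, kw, 1, w, cbind(8, 6))
  expect_lt(f2, 0)
})

test_that("total energy matches the double-loop oracle and splits correctly", {
  set.seed(3)
  img <- matrix(runif(144), 12, 12)
  phi <- matrix(rnorm(144), 12, 12)
  kw <- gaussian_kernel(1)
  w <- energy_weights()
  E <- total_energy(img, phi, kw, 1, w)
  expect_equal(as.numeric(E), oracle_total_energy(img, phi, kw, 1, w),
               tolerance = 1e-8)
  comp <- attr(E, "components")
  expect_gte(comp[["data"]], 0)
  expect_gte(comp[["regularization"]], 0)

  # constant image: zero data term, positive length-like term
  d <- sqrt(outer((1:30 - 15.5)^2, (1:30 - 15.5)^2, `+`))
  E2 <- total_energy(matrix(0.5, 30, 30), d - 8, gaussian_kernel(2), 1, w)
  comp2 <- attr(E2, "components")
  expect_lt(abs(comp2[["data"]]), 1e-10)
  expect_gt(comp2[["length"]], 0)
})
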