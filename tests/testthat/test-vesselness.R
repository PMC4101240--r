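test_that("Hessian responses vanish on flat images and scale on quadratics", {
  flat <- matrix(0.3, 20, 20)
  h <- hessian_at_scale(flat, 1)
  expect_true(all(abs(h$hxx) < 1e-12))
  expect_true(all(abs(h$hxy) < 1e-12))
  expect_true(all(abs(h$hyy) < 1e-12))

  # I = col^2: second derivative along columns is 2, normalized by sigma^2
  q <- outer(1:40, 1:40, function(r, c) c^2) / 1600
  for (s in c(1, 2)) {
    h <- hessian_at_scale(q * 1600, s)
    interior <- h$hyy[15:25, 15:25]
    expect_lt(max(abs(interior - 2 * s^2)) / (2 * s^2), 0.02)
  }
})

test_that("closed-form 2x2 eigendecomposition reconstructs random Hessians", {
  set.seed(5)
  n <- 1000
  hxx <- rnorm(n); hyy <- rnorm(n); hxy <- rnorm(n)
  h <- list(hxx = hxx, hxy = hxy, hyy = hyy)
  e <- eigen2x2(h)
  expect_true(all(abs(e$lam1) <= abs(e$lam2) + 1e-12))
  # v1 is a unit eigenvector of lam1: (H - lam1 I) v1 = 0
  r1 <- (hxx - e$lam1) * e$v1r + hxy * e$v1c
  r2 <- hxy * e$v1r + (hyy - e$lam1) * e$v1c
  expect_lt(max(abs(c(r1, r2))), 1e-10)
  expect_equal(e$v1r^2 + e$v1c^2, rep(1, n))
  # eigenvalues satisfy trace and determinant identities (V Lam V^T = H)
  expect_equal(e$lam1 + e$lam2, hxx + hyy, tolerance = 1e-10)
  expect_equal(e$lam1 * e$lam2, hxx * hyy - hxy^2, tolerance = 1e-10)

  ed <- eigen2x2(list(hxx = -1, hxy = 0, hyy = -10))
  expect_equal(ed$lam1, -1); expect_equal(ed$lam2, -10)
  expect_equal(abs(ed$v1r), 1)
  e0 <- eigen2x2(list(hxx = 0, hxy = 0, hyy = 0))
  expect_equal(c(e0$v1r, e0$v1c), c(1, 0))  # degenerate convention
})

test_that("vesselness response obeys the sign gate and closed form", {
  expect_equal(vesselness_response(1, 3, 0.5, 1), 0)    # lam2 > 0
  expect_equal(vesselness_response(0, 0, 0.5, 1), 0)    # S = 0
  for (L in c(0.1, 1, 10)) {
    expect_equal(vesselness_response(0, -L, 0.5, 1), 1 - exp(-L^2 / 2))
  }
  expect_error(vesselness_response(5, 1, 0.5, 1), "ordering")
  set.seed(1)
  lam2 <- -abs(rnorm(50)); lam1 <- lam2 * runif(50)
  R <- vesselness_response(lam1, lam2, 0.5, 0.7)
  expect_true(all(R >= 0 & R <= 1))
})

test_that("multiscale vesselness picks larger scales for wider bars", {
  img <- matrix(0, 60, 80)
  img[abs(1:60 - 15) <= 1, ] <- 1  # 3 px bar
  img[abs(1:60 - 45) <= 4, ] <- 1  # 9 px bar
  v <- multiscale_vesselness(img, c(1, 1.5, 2, 3, 4, 5))
  expect_true(all(v$R >= 0 & v$R <= 1))
  narrow <- median(v$best_scale[15, 20:60])
  wide <- median(v$best_scale[45, 20:60])
  expect_gt(wide, narrow)

  # single-scale list reduces to that scale's response
  v1 <- multiscale_vesselness(img, 2)
  h <- hessian_at_scale(img, 2)
  e <- eigen2x2(h)
  S <- sqrt(e$lam1^2 + e$lam2^2)
  direct <- vesselness_response(e$lam1, e$lam2, 0.5, max(S) / 2)
  expect_equal(v1$R, direct)
  # multiscale max dominates each member scale
  expect_true(all(v$R - v1$R >= -1e-12))
})

test_that("tube vesselness is high on the centerline and low far away", {
  set.seed(9)
  img <- make_bar_image(60, 90, 30, 2.5)       # width-5 bright tube
  noisy <- pmin(pmax(img + matrix(rnorm(60 * 90, 0, 0.05), 60, 90), 0), 1)
  v <- multiscale_vesselness(noisy, c(1, 1.5, 2, 3, 4, 5))
  expect_gt(median(v$R[30, 10:80]), 0.5)
  far <- abs(1:60 - 30) >= 12.5  # >= 10 px from the tube edge
  expect_lt(median(v$R[far, ]), 0.05)

  # noiseless: centerline direction within 10 degrees of the tube axis
  v0 <- multiscale_vesselness(img, c(1, 1.5, 2, 3, 4, 5))
  ang <- abs(v0$v1c[30, 10:80])  # |cos| of angle to the (0,1) axis
  expect_gte(mean(ang > cos(10 * pi / 180)), 0.9)
})

test_that("VVF direction gates on tau and aligns with grad phi", {
  vess <- list(R = matrix(c(0.04, 0.2, 0.2, 0.5), 2, 2),
               v1r = matrix(0, 2, 2), v1c = matrix(1, 2, 2))
  g <- list(dr = matrix(0, 2, 2), dc = matrix(c(0.3, 0.3, -0.3, 0.3), 2, 2))
  V <- vvf_direction(vess, g, tau = 0.05)
  expect_equal(V$Vc[1, 1], 0)        # below threshold: zero vector
  expect_equal(V$Vc[2, 1], 1)        # aligned: unchanged
  expect_equal(V$Vc[1, 2], -1)       # anti-aligned: flipped
  expect_true(all((V$Vr * g$dr + V$Vc * g$dc) >= 0))
})

test_that("VVF speed is the arctan sigmoid with the stated checkpoints", {
  expect_equal(vvf_speed(0.05, 0.05), 0.5)
  expect_equal(vvf_speed(0, 0.05), 0.25)
  expect_equal(vvf_speed(1, 0.05), (1 + (2 / pi) * atan(19)) / 2)
  R <- seq(0, 1, by = 0.01)
  f <- vvf_speed(R, 0.05)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  expect_error(vvf_speed(0.5, 0), "eps_v")
})

test_that("VVF force vanishes for zero or orthogonal fields and scales linearly", {
  g <- list(dr = matrix(1, 3, 3), dc = matrix(0, 3, 3))
  V0 <- list(Vr = matrix(0, 3, 3), Vc = matrix(0, 3, 3))
  expect_true(all(vvf_force(V0, matrix(1, 3, 3), g, -0.1) == 0))
  Vperp <- list(Vr = matrix(0, 3, 3), Vc = matrix(1, 3, 3))
  expect_true(all(vvf_force(Vperp, matrix(1, 3, 3), g, -0.1) == 0))
  V <- list(Vr = matrix(2, 3, 3), Vc = matrix(0, 3, 3))
  expect_true(all(vvf_force(V, matrix(1, 3, 3), g, -0.1) == -0.2))
})
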