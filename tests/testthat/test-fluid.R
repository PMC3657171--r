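test_that("velocity solver: zero force, modal closed form, solver agreement", {
  pars <- fluid_params(mu = 1.3, lambda = 0.7)
  d <- c(10, 9, 8)
  z <- solve_velocity(array(0, c(d, 3)), pars, c(1, 1, 1))
  expect_true(all(z$v == 0))
  # single-harmonic force along x: v = F / ((2 mu + lambda) k^2)
  n <- 48; dd <- c(n, 8, 8)
  k <- pi * 1 / (n - 1)
  x <- 0:(n - 1)
  F1 <- array(0, c(dd, 3))
  F1[, , , 1] <- array(sin(k * x), dd)
  sol <- solve_velocity(F1, pars, c(1, 1, 1))
  vexp <- sin(k * x) / ((2 * 1.3 + 0.7) * k^2)
  expect_lt(max(abs(sol$v[, 4, 4, 1] - vexp)) / max(abs(vexp)), 1e-3)
  expect_lt(max(abs(sol$v[, , , 2:3])), 1e-9 * max(abs(vexp)))
  expect_lt(sol$residual, 1e-3)
})

test_that("spectral and SOR solvers agree on smooth localized forces", {
  dm <- c(14, 12, 10)
  set.seed(7)
  idx <- gmatrophy:::index_grid(dm)
  g <- array(0, c(dm, 3))
  for (i in 1:3) {
    bump <- exp(-((idx[1, ] - 6)^2 + (idx[2, ] - 5)^2 +
                    (idx[3, ] - 4.5)^2) / 6) * rnorm(1)
    g[, , , i] <- array(bump, dm)
  }
  pars_f <- fluid_params(mu = 1, lambda = 0.5)
  pars_s <- fluid_params(mu = 1, lambda = 0.5, solver = "sor",
                         sor_tol = 5e-4, sor_max_iter = 2000)
  sf <- solve_velocity(g, pars_f, c(1, 1, 1))
  ss <- solve_velocity(g, pars_s, c(1, 1, 1))
  rel <- sqrt(sum((sf$v - ss$v)^2) / sum(sf$v^2))
  expect_lt(rel, 1e-3)
  expect_lt(sf$residual, 1e-12)  # direct solver is exact for its system
})

test_that("body force is zero at the optimum and points along a shift", {
  ph <- small_phantom(seed = 6)
  crop <- crop_dilated(ph$image, ph$brain, 1)
  mask <- apply_crop(ph$brain, attr(crop, "bbox"))
  bf0 <- body_force(crop, crop, mask)
  # stationary point: the residual is pure round-off
  expect_lt(max(abs(bf0$force)), 1e-12)
  expect_equal(bf0$ncc, 1)
  # monotone intensity edge vs slightly shifted copy: the force points
  # along the shift axis with a single sign wherever it is appreciable
  # (a purely linear ramp is invisible to NCC: centring removes a
  # uniform translation of it, so the profile needs curvature)
  d <- c(20, 6, 6)
  ramp <- voxel_image(array(rep(50 * tanh((seq(0, 19) - 9.5) / 4),
                                times = 36), d))
  xf <- diag(4); xf[1, 4] <- 0.4
  shifted <- resample(ramp, xf, ramp, method = "trilinear")
  m <- binary_mask(array(TRUE, d))
  m$data[c(1, 20), , ] <- FALSE
  bf <- body_force(ramp, shifted, m)
  fx <- bf$force[7:14, , , 1]  # the transition zone of the edge
  expect_true(all(fx > 0) || all(fx < 0))
  expect_lt(max(abs(bf$force[, , , 2:3])), 1e-12)
  # antisymmetry to first order: F(A,B) ~ -F(B,A) for small perturbations
  bfr <- body_force(shifted, ramp, m)
  fsum <- bf$force[5:15, , , 1] + bfr$force[5:15, , , 1]
  expect_lt(max(abs(fsum)), 0.15 * max(abs(bf$force[5:15, , , 1])))
  # zero-variance image errors out
  flat <- voxel_image(array(1, d))
  expect_error(body_force(flat, flat, m), "zero-variance")
})

test_that("jacobian determinants match analytic fields", {
  d <- c(12, 12, 12)
  f0 <- deformation_field(array(0, c(d, 3)), c(1.2, 1, 0.8))
  expect_true(all(jacobian_determinant(f0)$data == 1))
  # uniform 1% linear contraction: det J = 0.99^3 exactly in the interior
  idx <- gmatrophy:::index_grid(d)
  sp <- c(2, 2, 2)
  u <- array(0, c(d, 3))
  for (i in 1:3) u[, , , i] <- array(-0.01 * idx[i, ] * sp[i], d)
  dj <- jacobian_determinant(deformation_field(u, sp))
  expect_equal(unique(round(as.vector(dj$data[2:11, 2:11, 2:11]), 12)),
               0.970299)
  # folding raises an error naming voxels
  ubad <- array(0, c(d, 3))
  ubad[, , , 1] <- array(-1.2 * idx[1, ] * sp[1], d)
  expect_error(jacobian_determinant(deformation_field(ubad, sp)),
               "folding")
})

test_that("jacobian determinant matches an oversampled oracle on smooth fields", {
  # analytic gradient field on a coarse grid vs 10x oversampled finite
  # differences of the same analytic map
  sp <- c(2, 2, 2); d <- c(16, 16, 16)
  idx <- gmatrophy:::index_grid(d)
  pts <- idx * sp
  cc <- (d - 1) * sp / 2
  pot <- function(p) exp(-((p[1, ] - cc[1])^2 + (p[2, ] - cc[2])^2 +
                             (p[3, ] - cc[3])^2) / 400)
  dispf <- function(p) {
    f <- pot(p)
    rbind(-2 * (p[1, ] - cc[1]) / 400 * f * 6,
          -2 * (p[2, ] - cc[2]) / 400 * f * 6,
          -2 * (p[3, ] - cc[3]) / 400 * f * 6)
  }
  u <- array(t(dispf(pts)), c(d, 3))
  dj <- jacobian_determinant(deformation_field(u, sp))$data
  h <- 0.02  # 1/100 voxel: the oracle derivative is near-exact
  oracle <- array(1, d)
  G <- array(0, c(3, 3, prod(d)))
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    G[, j, ] <- (dispf(pts + e) - dispf(pts - e)) / (2 * h)
  }
  det3 <- function(m) {
    m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
      m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
      m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  }
  oracle <- vapply(seq_len(prod(d)),
                   function(p) det3(diag(3) + G[, , p]), numeric(1))
  # interior only: the grid operator is one-sided at faces
  interior <- array(FALSE, d); interior[2:15, 2:15, 2:15] <- TRUE
  expect_lt(max(abs(dj[interior] - array(oracle, d)[interior])), 1e-3)
})

test_that("identity pair exits immediately with a null field", {
  ph <- small_phantom(seed = 6)
  crop <- crop_dilated(ph$image, ph$brain, 2)
  mask <- apply_crop(ph$brain, attr(crop, "bbox"))
  fr <- fluid_register(crop, crop, mask)
  expect_true(fr$converged)
  expect_equal(fr$stop_reason, "force_threshold")
  expect_equal(fr$iterations, 1L)
  expect_lt(max(abs(fr$field$disp)) / min(crop$spacing), 0.02)
  expect_true(all(abs(fr$detj$data - 1) < 0.005))
})

test_that("fluid cost is monotone and the mean force is logged", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 8))
  fu <- apply_known_atrophy(ph$image, ph$truth, 0.02, seed = 108,
                            mode = "gm", refine = 2)
  crop <- crop_dilated(ph$image, ph$brain, 3)
  bbox <- attr(crop, "bbox")
  rep_c <- apply_crop(fu$image, bbox)
  mask <- apply_crop(ph$brain, bbox)
  fr <- fluid_register(crop, rep_c, mask, fluid_params(max_iter = 15))
  lg <- fr$log[fr$log$step_mm > 0, ]
  expect_true(all(diff(lg$ncc) > 0))  # accepted steps strictly improve
  expect_true(all(is.finite(lg$mean_force)))
  expect_true(all(fr$detj$data > 0))
})

test_that("forward and reverse registration give opposite volume changes", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 9))
  fu <- apply_known_atrophy(ph$image, ph$truth, 0.03, seed = 109,
                            mode = "gm", refine = 2)
  crop <- crop_dilated(ph$image, ph$brain, 3)
  bbox <- attr(crop, "bbox")
  rep_c <- apply_crop(fu$image, bbox)
  mask <- apply_crop(ph$brain, bbox)
  gm <- apply_crop(binary_mask(ph$truth$labels == 2, ph$image$spacing,
                               ph$image$affine), bbox)
  fab <- fluid_register(crop, rep_c, mask)
  fba <- fluid_register(rep_c, crop, mask)
  vv <- prod(crop$spacing) / 1000
  ch_ab <- sum(1 - fab$detj$data[gm$data]) * vv
  ch_ba <- sum(1 - fba$detj$data[gm$data]) * vv
  expect_lt(ch_ba, 0)  # reverse direction measures growth
  expect_lt(abs(ch_ab + ch_ba) / abs(ch_ab), 0.15)
})
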