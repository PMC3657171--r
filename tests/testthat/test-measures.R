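mask_of <- function(vol_ml, d = c(12, 10, 10)) {
  # a mask of exactly vol_ml mL out of 0.5 mL voxels
  n <- vol_ml * 2
  stopifnot(n == round(n), n <= prod(d))
  m <- array(FALSE, d); m[seq_len(n)] <- TRUE
  binary_mask(m, c(10, 10, 5))
}

test_that("segmentation-subtraction arithmetic and sign convention", {
  gm1 <- mask_of(540); gm2 <- mask_of(527.5)
  r <- seg_subtract(gm1, gm2, 365.25)
  expect_equal(r$change_ml, 12.5)
  expect_equal(r$rate_pct_yr, 100 * 12.5 / 540, tolerance = 1e-12)
  expect_equal(round(r$rate_pct_yr, 4), 2.3148)
  # identical masks: exactly zero
  r0 <- seg_subtract(gm1, gm1, 200)
  expect_equal(r0$change_ml, 0)
  expect_equal(r0$rate_pct_yr, 0)
  # growth is negative
  rg <- seg_subtract(gm2, gm1, 365.25)
  expect_lt(rg$rate_pct_yr, 0)
  # mismatched voxel volumes refuse
  bad <- mask_of(527.5); bad$spacing <- c(1, 1, 1)
  expect_error(seg_subtract(gm1, bad, 365.25), "grid error")
})

test_that("jacobian integration is the ROI sum of 1 - det J", {
  d <- c(10, 10, 10)
  roi <- binary_mask(array(TRUE, d), rep(10, 3))  # 1 mL voxels, 1000 mL
  roi$data[1:5] <- FALSE                          # 995 voxels
  one <- voxel_image(array(1, d), rep(10, 3))
  class(one) <- c("jacobian_map", class(one))
  expect_equal(jacobian_integrate(one, roi, 365.25)$change_ml, 0)
  # det J = 0.98 uniformly over a 100 mL ROI: 2 mL = 2%
  roi100 <- binary_mask(array(c(rep(TRUE, 100), rep(FALSE, 900)), d),
                        rep(10, 3))
  dj <- voxel_image(array(0.98, d), rep(10, 3))
  class(dj) <- c("jacobian_map", class(dj))
  r <- jacobian_integrate(dj, roi100, 365.25)
  expect_equal(r$change_ml, 2, tolerance = 1e-12)
  expect_equal(r$percent_change, 2, tolerance = 1e-12)
  empty <- binary_mask(array(FALSE, d), rep(10, 3))
  expect_error(jacobian_integrate(dj, empty, 365.25), "region error")
})

test_that("measured change is nearly linear in the displacement scale", {
  sp <- c(2, 2, 2); d <- c(16, 16, 16)
  idx <- gmatrophy:::index_grid(d)
  cc <- (d - 1) * sp / 2
  f <- exp(-((idx[1, ] * 2 - cc[1])^2 + (idx[2, ] * 2 - cc[2])^2 +
               (idx[3, ] * 2 - cc[3])^2) / 200)
  u1 <- array(0, c(d, 3))
  for (i in 1:3) u1[, , , i] <- array(-(idx[i, ] * 2 - cc[i]) * f * 0.02,
                                      d)
  roi <- binary_mask(array(TRUE, d), sp)
  interval <- 365.25
  ch <- function(alpha) {
    dj <- jacobian_determinant(deformation_field(alpha * u1, sp))
    jacobian_integrate(dj, roi, interval)$change_ml
  }
  c1 <- ch(1); chalf <- ch(0.5)
  expect_lt(abs(chalf - c1 / 2) / abs(c1), 0.05)  # O(alpha^2) residual
})

test_that("the BBSI window follows the quarter-gap rule", {
  d <- c(6, 6, 6)
  tiss <- tissue_maps(array(rep(c(1, 0), each = 108), d),
                      array(rep(c(0, 1), each = 108), d),
                      array(0, d))
  img <- voxel_image(array(rep(c(20, 100), each = 108), d))
  w <- bbsi_window(img, img, tiss)
  expect_equal(w$i_low, 40)
  expect_equal(w$i_high, 80)
  # inverted contrast errors out
  bad <- voxel_image(array(rep(c(100, 20), each = 108), d))
  expect_error(bbsi_window(bad, bad, tiss), "contrast error")
})

test_that("BBSI is exactly zero on an identical pair", {
  ph <- small_phantom(seed = 5)
  par <- binary_mask(ph$truth$labels >= 2, ph$image$spacing,
                     ph$image$affine)
  win <- bbsi_window(ph$image, ph$image, ph$truth$tissues)
  r <- bbsi(ph$image, ph$image, par, par, win, 365.25)
  expect_identical(r$change_ml, 0)
})

test_that("BBSI recovers the analytic shrinkage of a sphere", {
  # bright sphere with a one-voxel linear partial-volume edge (the
  # intensity profile a scanner would give), radius 20 -> 19.8 voxels
  d <- c(48, 48, 48)
  idx <- gmatrophy:::index_grid(d)
  r <- sqrt(colSums((idx - 23.5)^2))
  edge <- function(R) 100 * pmin(pmax(R - r + 0.5, 0), 1)
  base <- voxel_image(array(edge(20), d))
  repi <- voxel_image(array(edge(19.8), d))
  mb <- binary_mask(array(r <= 20, d))
  mr <- binary_mask(array(r <= 19.8, d))
  win <- structure(list(i_low = 25, i_high = 75, csf_mean = 0,
                        gm_mean = 100, frac = 0.25),
                   class = "bbsi_window")
  res <- bbsi(base, repi, mb, mr, win, 365.25)
  analytic <- 4 / 3 * pi * (20^3 - 19.8^3) / 1000
  expect_lt(abs(res$change_ml - analytic) / analytic, 0.03)
})

test_that("BBSI tracks a known 1% parenchymal loss", {
  st <- bbsi_study(10L)
  expect_lt(abs(mean(st$bbsi) - mean(st$truth)), 0.3)
})

test_that("atrophy results annualise and serialise consistently", {
  r <- atrophy_result("bbsi", 1000, 10, 182.625)
  expect_equal(r$percent_change, 1)
  expect_equal(r$rate_pct_yr, 2)
  r$qc <- list(band_voxels = 7)
  df <- as.data.frame(r)
  expect_equal(df$rate_pct_yr, 2)
  expect_match(df$qc_json, "band_voxels")
  expect_error(atrophy_result("bbsi", 1000, 1, 0), "interval")
})
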