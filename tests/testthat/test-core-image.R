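test_that("voxel_image validates geometry and exposes voxel volume", {
  img <- voxel_image(array(1, c(4, 4, 4)), c(0.9735, 0.9735, 1.5))
  expect_equal(voxel_volume(img), 0.9735^2 * 1.5, tolerance = 1e-12)
  expect_error(voxel_image(array(NA_real_, c(3, 3, 3))), "NaN")
  expect_error(voxel_image(array(1, c(3, 3, 3)), c(1, -1, 1)), "spacing")
  aff <- diag(c(2, 1, 1, 1))  # inconsistent with spacing 1,1,1
  expect_error(voxel_image(array(1, c(3, 3, 3)), c(1, 1, 1), aff),
               "inconsistent")
  m <- binary_mask(array(c(TRUE, FALSE), c(4, 4, 4)), c(2, 2, 2))
  expect_equal(mask_volume_ml(m), 32 * 8 / 1000)
})

test_that("NIfTI round trip preserves data, spacing and affine", {
  aff <- diag(c(0.9735, 0.9735, 1.5, 1)); aff[1:3, 4] <- c(-10, 5, 2)
  img <- tiny_image(c(6, 5, 4), c(0.9735, 0.9735, 1.5))
  img <- voxel_image(img$data, img$spacing, aff)
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(img, tf)
  back <- read_nifti(tf)
  expect_equal(back$data, img$data)
  expect_lt(max(abs(back$affine - img$affine)), 1e-6)
  expect_lt(max(abs(back$spacing - img$spacing)), 1e-6)
  # masks survive as binary content
  m <- binary_mask(img$data > 0, img$spacing, aff)
  tm <- withr::local_tempfile(fileext = ".nii")
  write_nifti(m, tm)
  expect_equal(read_nifti(tm)$data > 0.5, m$data)
})

test_that("read_nifti rejects 4D input and missing files", {
  tf <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), tf)
  expect_error(read_nifti(tf), "4D|3D")
  expect_error(read_nifti("/nonexistent/file.nii"), "no such file")
})

test_that("resampling is exact where interpolation theory says so", {
  img <- tiny_image(c(16, 16, 16))
  for (meth in c("trilinear", "sinc")) {
    r <- resample(img, method = meth)
    expect_lt(max(abs(r$data - img$data)), 1e-6)
  }
  # integer-voxel translation, trilinear: exact on the overlap
  xf <- diag(4); xf[1:3, 4] <- c(2, 0, -1)
  r <- resample(img, xf, method = "trilinear")
  expect_equal(r$data[1:14, , 2:16], img$data[3:16, , 1:15])
  # half-voxel shift of a linear ramp: interior matches the analytic ramp
  ramp <- voxel_image(array(rep(0:15, times = 256), c(16, 16, 16)))
  xs <- diag(4); xs[1, 4] <- 0.5
  rs <- resample(ramp, xs, method = "trilinear")
  expect_lt(max(abs(rs$data[2:14, , ] - (ramp$data[2:14, , ] + 0.5))),
            1e-6)
  expect_error(resample(img, matrix(0, 4, 4)), "singular")
})

test_that("morphology uses the 6-connected element and is monotone", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  d1 <- morph(binary_mask(m), "dilate", 1)
  expect_equal(sum(d1$data), 7)
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  e1 <- morph(binary_mask(cube), "erode", 1)
  expect_equal(sum(e1$data), 27)
  expect_warning(morph(binary_mask(m), "erode", 1), "empty")
  # monotonicity and volume ordering on a random mask
  set.seed(4)
  big <- array(runif(17^3) < 0.4, c(17, 17, 17))
  small <- big & array(runif(17^3) < 0.7, c(17, 17, 17))
  mb <- binary_mask(big); ms <- binary_mask(small)
  expect_true(all(morph(ms, "dilate", 1)$data <= morph(mb, "dilate",
                                                       1)$data))
  expect_true(all(suppressWarnings(morph(ms, "erode", 1))$data <=
                    suppressWarnings(morph(mb, "erode", 1))$data))
  expect_gte(mask_volume_ml(morph(mb, "dilate", 1)), mask_volume_ml(mb))
  expect_lte(mask_volume_ml(suppressWarnings(morph(mb, "erode", 1))),
             mask_volume_ml(mb))
})

test_that("dilate-then-erode of a sphere is a tight superset", {
  d <- c(24, 24, 24)
  idx <- expand.grid(i = 1:24, j = 1:24, k = 1:24)
  r2 <- (idx$i - 12.5)^2 + (idx$j - 12.5)^2 + (idx$k - 12.5)^2
  sph <- binary_mask(array(r2 <= 64, d))  # radius 8 voxels
  closed <- morph(morph(sph, "dilate", 3), "erode", 3)
  expect_true(all(closed$data[sph$data]))  # superset
  added <- sum(closed$data) - sum(sph$data)
  expect_lte(added, 0.02 * sum(sph$data))
})

test_that("central gradients are exact for linear fields and O(h^2)", {
  con <- voxel_image(array(5, c(6, 6, 6)))
  g <- central_gradient(con)
  expect_true(all(g$gx == 0) && all(g$gy == 0) && all(g$gz == 0))
  d <- c(12, 6, 6)
  x <- array(rep(0:11, times = 36), d)  # f = 2x with x in mm at 1 mm
  g2 <- central_gradient(voxel_image(2 * x))
  expect_true(all(abs(g2$gx - 2) < 1e-12))
  # f = sin(x) at 0.5 mm: interior error bounded by h^2/6 * max|f'''|
  n <- 40; h <- 0.5
  xx <- (0:(n - 1)) * h
  f <- voxel_image(array(rep(sin(xx), times = 16), c(n, 4, 4)),
                   c(h, 1, 1))
  gs <- central_gradient(f)
  err <- abs(gs$gx[2:(n - 1), , ] -
               array(rep(cos(xx[2:(n - 1)]), times = 16), c(n - 2, 4, 4)))
  expect_lt(max(err), 0.05)
})

test_that("deformation fields round trip through NIfTI", {
  set.seed(2)
  disp <- array(rnorm(5 * 6 * 7 * 3, sd = 0.3), c(5, 6, 7, 3))
  f <- deformation_field(disp, c(1, 1, 2))
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_deformation(f, tf)
  back <- read_deformation(tf)
  expect_equal(back$disp, f$disp)
  expect_lt(max(abs(back$affine - f$affine)), 1e-6)
})
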