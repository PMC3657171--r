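#' World-to-world affine transform
#'
#' Wraps a 4x4 homogeneous matrix used in pullback convention: the matrix
#' maps coordinates of the *reference* (target) world into the *source*
#' image's world, so resampling evaluates `source(T %*% y)` at each target
#' world position `y`.
#'
#' @param matrix 4x4 homogeneous matrix.
#' @param dof 6 (rigid) or 12 (full affine).  For `dof = 6` the upper-left
#'   3x3 must be a proper rotation (orthogonal, det +1, within 1e-6).
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4), dof = 12L) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4)) || any(!is.finite(matrix)))
    stop("transform must be a finite 4x4 matrix")
  if (abs(det(matrix)) < 1e-12) stop("transform is singular")
  if (!dof %in% c(6L, 12L)) stop("dof must be 6 or 12")
  if (dof == 6L) {
    R <- matrix[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop("dof=6 requires a proper rotation in the upper-left 3x3")
  }
  structure(list(matrix = matrix, dof = as.integer(dof)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> dof =", x$dof, "\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

# Zero-pad an array by `w` voxels on every side.  Sampling a padded array
# with indices clamped into the pad ring reproduces exact zero-fill
# interpolation without per-tap bounds checks.
pad_zero <- function(a, w) {
  d <- dim(a)
  out <- array(0, d + 2L * w)
  out[w + seq_len(d[1]), w + seq_len(d[2]), w + seq_len(d[3])] <- a
  out
}

# Trilinear interpolation at continuous 0-based voxel coords; 0 outside
# (compiled kernel).
interp_trilinear <- function(a, ci, cj, ck) {
  interp_trilinear_cpp(a, dim(a), ci, cj, ck)
}

# Hann-windowed sinc interpolation, half-width 3 voxels per axis, weights
# renormalised to unit sum per axis; 0 outside the field.
interp_sinc <- function(a, ci, cj, ck) {
  taps <- -2:3
  axis_weights <- function(f) {
    w <- vapply(taps, function(t) {
      d <- f - t
      s <- ifelse(abs(d) < 1e-12, 1, sin(pi * d) / (pi * d))
      s * 0.5 * (1 + cos(pi * d / 3)) * (abs(d) <= 3)
    }, numeric(length(f)))
    w / rowSums(w)
  }
  d <- dim(a)
  pw <- 6L  # wide enough that clamped far-outside taps stay in the pad
  ap <- pad_zero(a, pw)
  dp <- d + 2L * pw
  i0 <- floor(ci); j0 <- floor(cj); k0 <- floor(ck)
  wi <- axis_weights(ci - i0); wj <- axis_weights(cj - j0)
  wk <- axis_weights(ck - k0)
  i0 <- pmin.int(pmax.int(i0 + pw, 2), dp[1] - 4)
  j0 <- pmin.int(pmax.int(j0 + pw, 2), dp[2] - 4)
  k0 <- pmin.int(pmax.int(k0 + pw, 2), dp[3] - 4)
  base <- i0 + dp[1] * (j0 + dp[2] * k0) + 1
  sy <- dp[1]; sz <- dp[1] * dp[2]
  v <- 0
  for (a1 in seq_along(taps)) for (a2 in seq_along(taps)) {
    w12 <- wi[, a1] * wj[, a2]
    off12 <- taps[a1] + sy * taps[a2]
    for (a3 in seq_along(taps)) {
      v <- v + w12 * wk[, a3] * ap[base + off12 + sz * taps[a3]]
    }
  }
  v
}

# 3 x N matrix of 0-based voxel indices covering a grid of dimensions d.
index_grid <- function(d) {
  rbind(rep(0:(d[1] - 1), times = d[2] * d[3]),
        rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
        rep(0:(d[3] - 1), each = d[1] * d[2]))
}

as_grid_spec <- function(target) {
  if (inherits(target, "voxel_image") || inherits(target, "binary_mask"))
    list(shape = dim(target$data), spacing = target$spacing,
         affine = target$affine)
  else {
    if (!all(c("shape", "spacing", "affine") %in% names(target)))
      stop("target grid spec needs shape, spacing and affine")
    target
  }
}

#' Resample an image onto a target grid
#'
#' Evaluates the source image at `inv(A_src) %*% T %*% A_tgt %*% index` for
#' every target voxel, i.e. `xform` maps target world coordinates into the
#' source world (pullback convention).  Voxels falling outside the source
#' field of view are filled with 0.
#'
#' @param img source `voxel_image`.
#' @param xform an [affine_transform()] or 4x4 matrix (target world to source
#'   world); identity if `NULL`.
#' @param target target grid: a `voxel_image`/`binary_mask` template or a
#'   list with `shape`, `spacing`, `affine`.
#' @param method `"trilinear"` or `"sinc"` (Hann-windowed, half-width 3
#'   voxels).
#' @return `voxel_image` on the target grid.
#' @export
resample <- function(img, xform = NULL, target = img,
                     method = c("trilinear", "sinc")) {
  method <- match.arg(method)
  tg <- as_grid_spec(target)
  if (is.null(xform)) xform <- diag(4)
  if (inherits(xform, "affine_transform")) xform <- xform$matrix
  if (abs(det(xform)) < 1e-12) stop("singular transform")
  M <- solve(img$affine) %*% xform %*% tg$affine
  idx <- index_grid(tg$shape)
  src <- M[1:3, 1:3] %*% idx + M[1:3, 4]
  fun <- if (method == "trilinear") interp_trilinear else interp_sinc
  vals <- fun(img$data, src[1, ], src[2, ], src[3, ])
  voxel_image(array(vals, tg$shape), spacing = tg$spacing, affine = tg$affine)
}

#' Warp an image by a dense displacement field
#'
#' Computes `img(x + u(x))`: for each voxel of the field's grid the source
#' image is sampled at the world position displaced by `u` (mm).
#'
#' @param img source `voxel_image`.
#' @param field a `deformation_field` (displacements in world mm on the
#'   output grid).
#' @param method interpolation method, as for [resample()].
#' @return `voxel_image` on the field's grid.
#' @export
warp_image <- function(img, field, method = c("trilinear", "sinc")) {
  method <- match.arg(method)
  d <- dim(field$disp)[1:3]
  idx <- index_grid(d)
  world <- field$affine[1:3, 1:3] %*% idx + field$affine[1:3, 4]
  world <- world + rbind(as.vector(field$disp[, , , 1]),
                         as.vector(field$disp[, , , 2]),
                         as.vector(field$disp[, , , 3]))
  Ai <- solve(img$affine)
  src <- Ai[1:3, 1:3] %*% world + Ai[1:3, 4]
  fun <- if (method == "trilinear") interp_trilinear else interp_sinc
  vals <- fun(img$data, src[1, ], src[2, ], src[3, ])
  voxel_image(array(vals, d), spacing = field$spacing, affine = field$affine)
}
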