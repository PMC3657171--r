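# Pairwise pre-processing: 12-dof affine registration, tissue-based
# intensity normalisation, dilated-brain cropping.

# Build a world-to-world affine (pullback: baseline world -> repeat world)
# from parameters about a centre: translation (mm), Euler rotations (rad),
# log-scales, shears.
params_to_affine <- function(p, centre) {
  tr <- p[1:3]
  r <- if (length(p) >= 6) p[4:6] else c(0, 0, 0)
  sc <- if (length(p) >= 9) exp(p[7:9]) else c(1, 1, 1)
  sh <- if (length(p) >= 12) p[10:12] else c(0, 0, 0)
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  A3 <- Rz %*% Ry %*% Rx %*% diag(sc) %*% Sh
  M <- diag(4)
  M[1:3, 1:3] <- A3
  M[1:3, 4] <- tr + centre - A3 %*% centre
  M
}

# Block-mean downsample an image (factor 2 per axis), spacing doubled,
# affine shifted to the new voxel centres.
downsample2 <- function(img) {
  d <- dim(img$data)
  d2 <- floor(d / 2)
  a <- img$data[1:(2 * d2[1]), 1:(2 * d2[2]), 1:(2 * d2[3])]
  a <- a[seq(1, 2 * d2[1], 2), , ] + a[seq(2, 2 * d2[1], 2), , ]
  a <- a[, seq(1, 2 * d2[2], 2), ] + a[, seq(2, 2 * d2[2], 2), ]
  a <- a[, , seq(1, 2 * d2[3], 2)] + a[, , seq(2, 2 * d2[3], 2)]
  a <- a / 8
  S <- diag(c(2, 2, 2, 1)); S[1:3, 4] <- 0.5
  voxel_image(a, img$spacing * 2, img$affine %*% S)
}

#' Affine registration of a repeat image to baseline
#'
#' Maximises normalised cross-correlation inside the mask over a rigid
#' (6-dof) or full affine (12-dof) parameter space, coarse-to-fine over a
#' 3-level image pyramid, with parameters nested 6 -> 9 (scales) -> 12
#' (shears).  Deterministic (Nelder-Mead from fixed starts).
#'
#' @param baseline fixed `voxel_image`.
#' @param repeat_img moving `voxel_image` on the same grid class (any grid).
#' @param mask `binary_mask` on the baseline grid (nonempty).
#' @param dof 6 or 12.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @return object of class `registration_result`: `transform` (an
#'   [affine_transform()], pullback baseline-world to repeat-world),
#'   `similarity` (final NCC), `similarity_identity`, `iterations`,
#'   `converged`.
#' @export
register_affine <- function(baseline, repeat_img, mask, dof = 12L,
                            maxit = 200L) {
  if (!any(mask$data)) stop("mask is empty")
  if (!dof %in% c(6L, 12L)) stop("dof must be 6 or 12")
  # pyramid (level 1 = full resolution)
  pyr <- list(list(b = baseline, m = mask))
  for (l in 2:3) {
    prev <- pyr[[l - 1]]
    bm <- binary_mask(downsample2(voxel_image(
      array(as.numeric(prev$m$data), dim(prev$m$data)),
      prev$m$spacing, prev$m$affine))$data > 0.25,
      prev$b$spacing * 2, downsample2(prev$b)$affine)
    pyr[[l]] <- list(b = downsample2(prev$b), m = bm)
  }
  idx_world <- function(img, msk) {
    idx <- index_grid(dim(img$data))[, as.vector(msk$data), drop = FALSE]
    img$affine[1:3, 1:3] %*% idx + img$affine[1:3, 4]
  }
  Ai <- solve(repeat_img$affine)
  cost_fn <- function(p, lvl, centre) {
    M <- params_to_affine(p, centre)
    src <- Ai[1:3, 1:3] %*% (M[1:3, 1:3] %*% lvl$w + M[1:3, 4]) +
      Ai[1:3, 4]
    v <- interp_trilinear(repeat_img$data, src[1, ], src[2, ], src[3, ])
    if (stats::sd(v) < 1e-12) return(1)  # left the overlap
    -stats::cor(lvl$bv, v)
  }
  nev <- 0L
  p <- rep(0, 12)
  stages <- if (dof == 6L) list(1:6) else list(1:6, 1:9, 1:12)
  for (l in 3:1) {
    lvl <- pyr[[l]]
    lvl$w <- idx_world(lvl$b, lvl$m)
    lvl$bv <- lvl$b$data[lvl$m$data]
    centre <- rowMeans(lvl$w)
    for (st in stages) {
      np <- max(st)
      obj <- function(q) cost_fn(c(q, rep(0, 12 - np))[1:12], lvl, centre)
      # optimise the active parameters from the current estimate
      init <- p[1:np]
      o <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = c(rep(1, 3), rep(0.02, 3),
                                                    rep(0.01, 3),
                                                    rep(0.01, 3))[1:np]))
      p[1:np] <- o$par
      nev <- nev + o$counts[1]
    }
  }
  lvl1 <- pyr[[1]]
  lvl1$w <- idx_world(lvl1$b, lvl1$m)
  lvl1$bv <- lvl1$b$data[lvl1$m$data]
  centre1 <- rowMeans(lvl1$w)
  sim_id <- -cost_fn(rep(0, 12), lvl1, centre1)
  sim <- -cost_fn(p, lvl1, centre1)
  if (sim < sim_id) {  # never worse than the identity initialisation
    p <- rep(0, 12)
    sim <- sim_id
  }
  M <- params_to_affine(p, centre1)
  xf <- if (dof == 6L) {
    # re-orthogonalise against numerical drift before the dof-6 check
    sv <- svd(M[1:3, 1:3])
    R <- sv$u %*% t(sv$v)
    M2 <- M; M2[1:3, 1:3] <- R
    affine_transform(M2, 6L)
  } else affine_transform(M, 12L)
  structure(list(transform = xf, similarity = sim,
                 similarity_identity = sim_id, iterations = nev,
                 converged = TRUE, params = p),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> NCC ", signif(x$similarity, 6),
      " (identity ", signif(x$similarity_identity, 6), "), ",
      x$iterations, " cost evaluations\n", sep = "")
  print(x$transform)
  invisible(x)
}

#' Tissue-based linear intensity normalisation
#'
#' Ordinary least squares of the baseline tissue mean intensities (CSF, GM,
#' WM, whole brain: 4 points) on the corresponding repeat means.  The
#' returned scale/offset are applied to the repeat image to bring it onto
#' the baseline intensity scale.
#'
#' @param baseline,repeat_img images on a common grid.
#' @param tissues a [tissue_maps()] on the same grid (thresholded at 0.5 to
#'   define the tissue samples; brain = union of the three).
#' @return object of class `intensity_map`: `scale`, `offset`, and the
#'   4 x 2 matrix of tissue means used.
#' @export
normalize_intensity <- function(baseline, repeat_img, tissues) {
  check_same_grid(baseline, repeat_img, "baseline and repeat")
  sel <- list(csf = tissues$p_csf >= 0.5, gm = tissues$p_gm >= 0.5,
              wm = tissues$p_wm >= 0.5)
  sel$brain <- sel$csf | sel$gm | sel$wm
  bm <- vapply(sel, function(s) mean(baseline$data[s]), numeric(1))
  rm_ <- vapply(sel, function(s) mean(repeat_img$data[s]), numeric(1))
  if (stats::sd(rm_) < 1e-9) {
    warning("degenerate tissue means; falling back to identity map")
    scale <- 1; offset <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, rm_), bm)
    offset <- fit$coefficients[1]
    scale <- fit$coefficients[2]
    if (abs(scale - 1) < 1e-12 && abs(offset) < 1e-9 * max(abs(bm))) {
      # numerically the identity (e.g. identical images): snap exactly
      scale <- 1; offset <- 0
    }
    if (scale <= 0) {
      warning("non-positive regression slope; falling back to identity map")
      scale <- 1; offset <- 0
    }
  }
  structure(list(scale = unname(scale), offset = unname(offset),
                 means = cbind(baseline = bm, repeat_ = rm_)),
            class = "intensity_map")
}

#' Apply an intensity map to an image
#' @param img a `voxel_image`.
#' @param map an `intensity_map` from [normalize_intensity()].
#' @return the rescaled `voxel_image`.
#' @export
apply_intensity_map <- function(img, map) {
  voxel_image(map$scale * img$data + map$offset, img$spacing, img$affine)
}

#' @export
print.intensity_map <- function(x, ...) {
  cat("<intensity_map> scale ", signif(x$scale, 6), ", offset ",
      signif(x$offset, 6), "\n", sep = "")
  invisible(x)
}

#' Crop an image with the dilated brain region
#'
#' Zeroes everything outside the brain mask dilated `dilations` times, then
#' tightens the bounding box to the dilated mask plus a 1-voxel margin.  The
#' crop box is attached as attribute `"bbox"` (1-based index ranges) so the
#' same crop can be applied to companion images and masks with
#' [apply_crop()].
#'
#' @param img `voxel_image` to crop.
#' @param brain `binary_mask` on the same grid (nonempty).
#' @param dilations number of 6-connected dilations (default 3; 0 crops to
#'   the brain mask itself).
#' @return the cropped `voxel_image` with attribute `bbox`.
#' @export
crop_dilated <- function(img, brain, dilations = 3L) {
  check_same_grid(img, brain, "image and brain mask")
  if (!any(brain$data)) stop("brain mask is empty")
  m <- if (dilations >= 1L) morph(brain, "dilate", dilations) else brain
  d <- dim(img$data)
  w <- which(m$data, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, d)
  bbox <- list(lo = lo, hi = hi)
  masked <- img$data * m$data
  out <- apply_crop(voxel_image(masked, img$spacing, img$affine), bbox)
  attr(out, "bbox") <- bbox
  out
}

#' Apply a crop box produced by [crop_dilated()]
#' @param obj a `voxel_image` or `binary_mask`.
#' @param bbox list with 1-based `lo`/`hi` index triples.
#' @return the cropped object with its affine origin updated.
#' @export
apply_crop <- function(obj, bbox) {
  lo <- bbox$lo; hi <- bbox$hi
  a <- obj$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  aff <- obj$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% (lo - 1)
  if (inherits(obj, "binary_mask")) binary_mask(a, obj$spacing, aff)
  else voxel_image(a, obj$spacing, aff)
}
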