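#' Specification of a three-tissue digital brain phantom
#'
#' The phantom is an ellipsoidal "head": an outer CSF shell, a convoluted
#' cortical gray-matter ribbon (an ellipsoidal shell whose radius carries a
#' sinusoidal angular perturbation), a white-matter core and two deep
#' gray-matter blobs.  Voxel intensities are tissue means plus Gaussian
#' noise, modulated by a smooth low-order polynomial bias field.  The default
#' geometry is a 64^3 grid at 2 mm isotropic; `preset = "native"` switches to
#' the acquisition-like anisotropic geometry (0.9735 x 0.9735 x 1.5 mm).
#'
#' @param shape voxel grid dimensions (length 3).
#' @param spacing mm per axis.
#' @param means named tissue mean intensities `c(csf=, gm=, wm=)`; must be
#'   increasing (T1-like contrast).
#' @param noise_sd Gaussian noise SD (intensity units); must stay below half
#'   the GM-WM gap so classes remain separable.
#' @param bias_amp fractional amplitude of the multiplicative bias field.
#' @param ribbon_thickness GM ribbon thickness in mm.
#' @param harmonics integer order of the angular perturbation (cortical
#'   convolution).
#' @param perturb_frac radial perturbation amplitude as a fraction of the
#'   normalised radius.
#' @param pv_grid partial-volume subsampling grid per axis: tissue
#'   fractions per voxel are estimated from `pv_grid^3` analytic label
#'   samples and intensities are fraction-weighted tissue means, emulating
#'   scanner partial-volume mixing at boundaries.  `1` gives pure
#'   voxel-centre labels (piecewise-constant intensities).
#' @param seed integer seed; all phantom randomness flows through it.
#' @param preset `"coarse"` (default 64^3 at 2 mm) or `"native"`
#'   (128 x 128 x 84 at 0.9735 x 0.9735 x 1.5 mm).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                         means = c(csf = 20, gm = 70, wm = 110),
                         noise_sd = 2, bias_amp = 0.05,
                         ribbon_thickness = 12, harmonics = 3L,
                         perturb_frac = 0.06, pv_grid = 3L, seed = 1L,
                         preset = c("coarse", "native")) {
  preset <- match.arg(preset)
  if (preset == "native") {
    shape <- c(128, 128, 84)
    spacing <- c(0.9735, 0.9735, 1.5)
  }
  means <- as.numeric(means[c("csf", "gm", "wm")])
  if (anyNA(means) || !(means[1] < means[2] && means[2] < means[3]))
    stop("tissue means must satisfy CSF < GM < WM")
  if (noise_sd < 0 || noise_sd >= (means[3] - means[2]) / 2)
    stop("noise SD must be in [0, (WM-GM)/2) to keep classes separable")
  if (bias_amp < 0) stop("bias amplitude must be >= 0")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 means = c(csf = means[1], gm = means[2], wm = means[3]),
                 noise_sd = noise_sd, bias_amp = bias_amp,
                 ribbon_thickness = ribbon_thickness,
                 harmonics = as.integer(harmonics),
                 perturb_frac = perturb_frac,
                 pv_grid = max(1L, as.integer(pv_grid)),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Geometry derived from a phantom_spec: ellipsoid centre/semi-axes (mm) and
# the normalised radii of the GM ribbon boundaries.
phantom_geometry <- function(spec) {
  half <- (spec$shape - 1) * spec$spacing / 2
  centre <- half
  axes <- c(0.88, 0.92, 0.80) * half
  rho_out <- 0.85
  abar <- mean(axes)
  rho_in <- rho_out - spec$ribbon_thickness / abar
  if (rho_in <= 0.2)
    stop("ribbon thickness too large for this head size")
  if (spec$ribbon_thickness < max(spec$spacing))
    stop("resolution error: GM ribbon thinner than one voxel")
  blob_r <- 0.22 * min(axes)
  blobs <- rbind(centre + c(0.25 * axes[1], 0.10 * axes[2], 0),
                 centre - c(0.25 * axes[1], 0.10 * axes[2], 0))
  list(centre = centre, axes = axes, rho_in = rho_in, rho_out = rho_out,
       eps = spec$perturb_frac, harmonics = spec$harmonics,
       blobs = blobs, blob_r = blob_r)
}

# Normalised ellipsoidal radius of 3 x N world points.
phantom_rho <- function(geom, pts) {
  u1 <- (pts[1, ] - geom$centre[1]) / geom$axes[1]
  u2 <- (pts[2, ] - geom$centre[2]) / geom$axes[2]
  u3 <- (pts[3, ] - geom$centre[3]) / geom$axes[3]
  sqrt(u1^2 + u2^2 + u3^2)
}

# Angular perturbation S(x) in [-1, 1] (zero at the poles and at the centre).
phantom_perturb <- function(geom, pts) {
  u1 <- (pts[1, ] - geom$centre[1]) / geom$axes[1]
  u2 <- (pts[2, ] - geom$centre[2]) / geom$axes[2]
  u3 <- (pts[3, ] - geom$centre[3]) / geom$axes[3]
  rho <- sqrt(u1^2 + u2^2 + u3^2)
  rho[rho == 0] <- 1
  theta <- atan2(u2, u1)
  phi <- acos(pmin(pmax(u3 / rho, -1), 1))
  sin(geom$harmonics * theta) * sin(geom$harmonics * phi)
}

# Tissue labels for 3 x N world points: 0 background, 1 CSF, 2 GM, 3 WM.
phantom_labels <- function(geom, pts) {
  rho <- phantom_rho(geom, pts)
  s <- phantom_perturb(geom, pts)
  r_out <- geom$rho_out + geom$eps * s
  r_in <- geom$rho_in + geom$eps * s
  lab <- integer(ncol(pts))
  lab[rho <= 1] <- 1L                       # CSF shell
  lab[rho <= r_out] <- 2L                   # cortical GM ribbon
  lab[rho <= r_in] <- 3L                    # WM core
  # deep GM blobs inside the WM core
  for (b in 1:nrow(geom$blobs)) {
    db <- sqrt((pts[1, ] - geom$blobs[b, 1])^2 +
               (pts[2, ] - geom$blobs[b, 2])^2 +
               (pts[3, ] - geom$blobs[b, 3])^2)
    lab[lab == 3L & db <= geom$blob_r] <- 2L
  }
  lab
}

# Smooth low-order polynomial bias field, normalised to [1-amp, 1+amp].
phantom_bias <- function(spec, pts) {
  if (spec$bias_amp == 0) return(rep(1, ncol(pts)))
  half <- (spec$shape - 1) * spec$spacing / 2
  z <- (pts - half) / half   # centred, in [-1, 1]
  b <- z[1, ] + 0.6 * z[2, ] - 0.4 * z[3, ] + 0.8 * z[1, ] * z[3, ] +
       0.5 * z[2, ]^2
  b <- b / max(abs(b))
  1 + spec$bias_amp * b
}

#' Generate a three-tissue brain phantom
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_pair` start point with elements:
#'   `image` (noisy biased `voxel_image`), `truth` (a `phantom_truth`:
#'   noise-free image, hard tissue maps, true GM volume in mL, geometry,
#'   spec), and `brain` (`binary_mask`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  affine <- diag(c(spec$spacing, 1))
  pts <- diag(spec$spacing) %*% index_grid(spec$shape)
  lab <- phantom_labels(geom, pts)
  means <- c(0, spec$means)  # background 0
  g <- spec$pv_grid
  if (g > 1L) {
    # partial-volume intensities: fraction-weighted tissue means from
    # analytic subvoxel label sampling
    offs <- (seq_len(g) - (g + 1) / 2) / g
    clean <- numeric(ncol(pts))
    for (oi in offs) for (oj in offs) for (ok in offs) {
      sub <- pts + c(oi, oj, ok) * spec$spacing
      clean <- clean + means[phantom_labels(geom, sub) + 1L]
    }
    clean <- clean / g^3
  } else {
    clean <- means[lab + 1L]
  }
  set.seed(spec$seed)
  inb <- lab > 0L
  clean[!inb] <- 0  # brain-extracted: exact zero background
  noisy <- clean
  noisy[inb] <- noisy[inb] + stats::rnorm(sum(inb), 0, spec$noise_sd)
  noisy <- noisy * phantom_bias(spec, pts)
  noisy[!inb] <- 0
  shape <- spec$shape
  to_arr <- function(v) array(v, shape)
  tissues <- tissue_maps(
    p_csf = to_arr(as.numeric(lab == 1L)),
    p_gm = to_arr(as.numeric(lab == 2L)),
    p_wm = to_arr(as.numeric(lab == 3L)),
    spacing = spec$spacing, affine = affine)
  truth <- structure(list(
    spec = spec, geom = geom,
    clean_image = voxel_image(to_arr(clean), spec$spacing, affine),
    tissues = tissues,
    labels = to_arr(lab),
    gm_volume_ml = sum(lab == 2L) * prod(spec$spacing) / 1000,
    brain_volume_ml = sum(inb) * prod(spec$spacing) / 1000,
    deformation = NULL), class = "phantom_truth")
  list(image = voxel_image(to_arr(noisy), spec$spacing, affine),
       truth = truth,
       brain = binary_mask(to_arr(inb), spec$spacing, affine))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> GM ", signif(x$gm_volume_ml, 5), " mL, brain ",
      signif(x$brain_volume_ml, 5), " mL", sep = "")
  if (!is.null(x$deformation))
    cat(", known ", x$deformation$mode, " loss ",
        signif(100 * x$deformation$achieved_loss, 4), "%", sep = "")
  cat("\n")
  invisible(x)
}
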