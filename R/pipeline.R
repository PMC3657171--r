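#' Simple threshold-based brain extraction
#'
#' Intended for phantom-style brain-extracted or high-contrast inputs:
#' voxels above a fraction of the 99th intensity percentile, closed by one
#' dilate/erode pass to fill small gaps.
#'
#' @param img a `voxel_image`.
#' @param frac threshold as a fraction of the 99th percentile (default
#'   0.15).
#' @return a `binary_mask`.
#' @export
extract_brain <- function(img, frac = 0.15) {
  thr <- frac * stats::quantile(img$data, 0.99, names = FALSE)
  m <- binary_mask(img$data > thr, img$spacing, img$affine)
  morph(morph(m, "dilate", 1), "erode", 1)
}

#' Run the full measurement pipeline on one image pair
#'
#' Orchestrates affine registration, intensity normalisation, cropping with
#' the thrice-dilated baseline brain, and the selected measures:
#' segmentation + subtraction, fluid registration + Jacobian integration
#' over GM, and/or the brain boundary shift integral.
#'
#' @param baseline,repeat_img `voxel_image`s or NIfTI paths.
#' @param brain_base,brain_repeat `binary_mask`s or NIfTI paths; derived
#'   with [extract_brain()] when `NULL`.
#' @param interval_days scan interval (days).
#' @param methods subset of `c("seg_subtract", "jacobian_gm", "bbsi")`.
#' @param fluid a [fluid_params()].
#' @param dilations crop dilations (default 3).
#' @param seed integer seed (segmentation restarts).
#' @param skip_affine set `TRUE` when the pair is already aligned on a
#'   common grid (e.g. phantom follow-ups).
#' @param output_dir if non-`NULL`, writes `results.csv`, QC images
#'   (difference map, det-J map) and a provenance JSON there.
#' @param verbose print stage progress.
#' @return object of class `pair_result`: `results` (data.frame, one row
#'   per method), `measures` (list of `atrophy_result`), `fluid` (the
#'   `fluid_result`, if run), and `provenance`.
#' @export
run_pair <- function(baseline, repeat_img, brain_base = NULL,
                     brain_repeat = NULL, interval_days = 365,
                     methods = c("seg_subtract", "jacobian_gm", "bbsi"),
                     fluid = fluid_params(), dilations = 3L, seed = 1L,
                     skip_affine = FALSE, output_dir = NULL,
                     verbose = FALSE) {
  if (length(methods) < 1L) stop("validation error: no method selected")
  methods <- match.arg(methods, several.ok = TRUE)
  for (p in list(baseline, repeat_img, brain_base, brain_repeat))
    if (is.character(p) && !file.exists(p))
      stop("validation error: missing input ", p)
  say <- function(...) if (verbose) message(format(Sys.time(),
                                                   "%H:%M:%S "), ...)
  if (is.character(baseline)) baseline <- read_nifti(baseline)
  if (is.character(repeat_img)) repeat_img <- read_nifti(repeat_img)
  as_mask <- function(x, img) {
    if (is.null(x)) return(extract_brain(img))
    if (is.character(x)) x <- read_nifti(x)
    if (inherits(x, "voxel_image"))
      x <- binary_mask(x$data > 0.5, x$spacing, x$affine)
    x
  }
  brain_base <- as_mask(brain_base, baseline)
  brain_repeat <- as_mask(brain_repeat, repeat_img)

  if (!skip_affine) {
    say("affine registration (12 dof)")
    reg <- register_affine(baseline, repeat_img, brain_base, dof = 12L)
    repeat_rs <- resample(repeat_img, reg$transform, baseline,
                          method = "sinc")
    brep <- resample(voxel_image(array(as.numeric(brain_repeat$data),
                                       dim(brain_repeat$data)),
                                 brain_repeat$spacing,
                                 brain_repeat$affine),
                     reg$transform, baseline, method = "trilinear")
    brain_repeat <- binary_mask(brep$data > 0.5, baseline$spacing,
                                baseline$affine)
  } else {
    reg <- NULL
    repeat_rs <- repeat_img
  }

  say("tissue segmentation (baseline)")
  tiss_base <- segment_tissues(baseline, brain_base, seed = seed)
  imap <- normalize_intensity(baseline, repeat_rs, tiss_base)
  repeat_n <- apply_intensity_map(repeat_rs, imap)

  say("cropping with dilated brain region")
  base_c <- crop_dilated(baseline, brain_base, dilations)
  bbox <- attr(base_c, "bbox")
  rep_c <- apply_crop(repeat_n, bbox)
  bb_c <- apply_crop(brain_base, bbox)
  br_c <- apply_crop(brain_repeat, bbox)

  tiss_c <- segment_tissues(base_c, bb_c, seed = seed)
  gm_base <- binarize_gm(tiss_c)
  measures <- list()
  fl <- NULL
  tiss_rep <- NULL
  if (any(c("seg_subtract", "bbsi") %in% methods)) {
    say("tissue segmentation (repeat)")
    tiss_rep <- segment_tissues(rep_c, br_c, seed = seed + 1L)
  }
  if ("seg_subtract" %in% methods) {
    say("segmentation and subtraction")
    measures$seg_subtract <- seg_subtract(gm_base, binarize_gm(tiss_rep),
                                          interval_days)
  }
  if ("jacobian_gm" %in% methods) {
    say("fluid registration")
    fl <- fluid_register(base_c, rep_c, bb_c, fluid)
    measures$jacobian_gm <- jacobian_integrate(fl$detj, gm_base,
                                               interval_days)
  }
  if ("bbsi" %in% methods) {
    say("boundary shift integral")
    win <- bbsi_window(base_c, rep_c, tiss_c)
    # the BBSI's "brain region" is the parenchyma (GM + WM): its
    # boundary is the tissue/CSF interface the intensity window spans
    par_base <- binary_mask(tiss_c$p_gm + tiss_c$p_wm >= 0.5,
                            base_c$spacing, base_c$affine)
    par_rep <- binary_mask(tiss_rep$p_gm + tiss_rep$p_wm >= 0.5,
                           base_c$spacing, base_c$affine)
    measures$bbsi <- bbsi(base_c, rep_c, par_base, par_rep, win,
                          interval_days)
  }
  results <- do.call(rbind, lapply(measures, as.data.frame))
  rownames(results) <- NULL
  prov <- list(
    package = "gmatrophy",
    version = as.character(utils::packageVersion("gmatrophy")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, methods = methods, interval_days = interval_days,
    skip_affine = skip_affine, dilations = dilations,
    fluid_params = unclass(fluid),
    intensity_map = list(scale = imap$scale, offset = imap$offset),
    affine_similarity = if (!is.null(reg)) reg$similarity,
    fluid_iterations = if (!is.null(fl)) fl$iterations,
    fluid_converged = if (!is.null(fl)) fl$converged)
  prov$config_hash <- substr(paste(
    as.hexmode(utf8ToInt(jsonlite::toJSON(
      prov[c("seed", "methods", "interval_days", "skip_affine",
             "dilations", "fluid_params")], auto_unbox = TRUE))),
    collapse = ""), 1, 40)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(prov, file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    diffmap <- voxel_image(base_c$data - rep_c$data, base_c$spacing,
                           base_c$affine)
    write_nifti(diffmap, file.path(output_dir, "qc_difference.nii.gz"))
    if (!is.null(fl)) {
      write_nifti(fl$detj, file.path(output_dir, "qc_detj.nii.gz"))
      utils::write.csv(fl$log, file.path(output_dir, "fluid_log.csv"),
                       row.names = FALSE)
    }
  }
  structure(list(results = results, measures = measures, fluid = fl,
                 registration = reg, intensity_map = imap,
                 provenance = prov),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat("<pair_result>\n")
  for (m in x$measures) print(m)
  invisible(x)
}
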