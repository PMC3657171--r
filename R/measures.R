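#' A single atrophy measurement
#'
#' Common result container for the three measures.  Shrinkage is positive:
#' `volume_change_ml = baseline - repeat` volume, `percent_change` is
#' relative to the baseline volume, and the annualised rate uses
#' 365.25 days per year.  Growth therefore yields negative values.
#'
#' @param method one of `"seg_subtract"`, `"jacobian_gm"`, `"bbsi"`.
#' @param baseline_ml baseline volume of the measured region (mL).
#' @param change_ml volume change in mL (positive = loss).
#' @param interval_days scan interval in days (> 0).
#' @param qc named list of method-specific diagnostics.
#' @return object of class `atrophy_result`.
#' @export
atrophy_result <- function(method, baseline_ml, change_ml, interval_days,
                           qc = list()) {
  if (interval_days <= 0) stop("interval must be positive")
  if (baseline_ml <= 0) stop("baseline volume must be positive")
  pct <- 100 * change_ml / baseline_ml
  structure(list(method = method, baseline_ml = baseline_ml,
                 change_ml = change_ml, percent_change = pct,
                 interval_days = interval_days,
                 rate_pct_yr = annualize(pct, interval_days), qc = qc),
            class = "atrophy_result")
}

#' @export
print.atrophy_result <- function(x, ...) {
  cat("<atrophy_result> ", x$method, ": ", signif(x$change_ml, 5),
      " mL of ", signif(x$baseline_ml, 5), " mL (",
      signif(x$percent_change, 4), "%) over ", x$interval_days,
      " d = ", signif(x$rate_pct_yr, 4), " %/yr\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.atrophy_result <- function(x, ...) {
  data.frame(method = x$method, baseline_vol_ml = x$baseline_ml,
             delta_ml = x$change_ml, pct = x$percent_change,
             interval_days = x$interval_days,
             rate_pct_yr = x$rate_pct_yr,
             qc_json = as.character(jsonlite::toJSON(x$qc,
                                                     auto_unbox = TRUE)))
}

#' Segmentation-and-subtraction volume change
#'
#' Volume change = baseline GM mask volume minus repeat GM mask volume.
#'
#' @param gm_base,gm_repeat GM masks (from [binarize_gm()]); grids must
#'   have equal voxel volume.
#' @param interval_days scan interval (days).
#' @return an [atrophy_result()] with method `"seg_subtract"`.
#' @export
seg_subtract <- function(gm_base, gm_repeat, interval_days) {
  if (abs(prod(gm_base$spacing) - prod(gm_repeat$spacing)) >
      1e-9 * prod(gm_base$spacing))
    stop("grid error: voxel volumes differ between time points")
  vb <- mask_volume_ml(gm_base)
  vr <- mask_volume_ml(gm_repeat)
  atrophy_result("seg_subtract", vb, vb - vr, interval_days,
                 qc = list(repeat_vol_ml = vr))
}

#' Jacobian integration over a region of interest
#'
#' Volume change (mL) is the sum of `(1 - det J)` over the ROI voxels times
#' the voxel volume: contraction (det J < 1) contributes loss, expansion
#' negative loss.  Percent change is relative to the baseline ROI volume.
#'
#' @param detj a `jacobian_map` on the baseline grid.
#' @param roi GM (or other) `binary_mask` on the same grid.
#' @param interval_days scan interval (days).
#' @return an [atrophy_result()] with method `"jacobian_gm"`.
#' @export
jacobian_integrate <- function(detj, roi, interval_days) {
  check_same_grid(detj, roi, "Jacobian map and ROI")
  if (!any(roi$data)) stop("region error: ROI is empty")
  vv <- prod(detj$spacing) / 1000
  dj <- detj$data[roi$data]
  change <- sum(1 - dj) * vv
  atrophy_result("jacobian_gm", sum(roi$data) * vv, change, interval_days,
                 qc = list(min_detj = min(dj), max_detj = max(dj)))
}

#' Intensity window for the boundary shift integral
#'
#' The window is placed inside the CSF-GM transition: with `g` the gap
#' between the (baseline/repeat averaged) CSF and GM mean intensities, the
#' window is `[CSF + frac * g, GM - frac * g]` (default `frac = 0.25`).
#'
#' @param baseline,repeat_img the image pair (repeat already normalised).
#' @param tissues [tissue_maps()] on the common grid (thresholded at 0.5 to
#'   sample tissue intensities).
#' @param frac fraction of the CSF-GM gap trimmed from each end.
#' @return object of class `bbsi_window`: `i_low`, `i_high`, and the tissue
#'   means used.
#' @export
bbsi_window <- function(baseline, repeat_img, tissues, frac = 0.25) {
  csf_sel <- tissues$p_csf >= 0.5
  gm_sel <- tissues$p_gm >= 0.5
  csf <- mean(c(baseline$data[csf_sel], repeat_img$data[csf_sel]))
  gm <- mean(c(baseline$data[gm_sel], repeat_img$data[gm_sel]))
  if (csf >= gm)
    stop("contrast error: CSF mean (", signif(csf, 5),
         ") not below GM mean (", signif(gm, 5), ")")
  gap <- gm - csf
  structure(list(i_low = csf + frac * gap, i_high = gm - frac * gap,
                 csf_mean = csf, gm_mean = gm, frac = frac),
            class = "bbsi_window")
}

#' @export
print.bbsi_window <- function(x, ...) {
  cat("<bbsi_window> [", signif(x$i_low, 6), ", ", signif(x$i_high, 6),
      "] from CSF ", signif(x$csf_mean, 6), " / GM ", signif(x$gm_mean, 6),
      "\n", sep = "")
  invisible(x)
}

#' Brain boundary shift integral
#'
#' Integrates the clipped intensity difference over the boundary band
#' `B = dilate(base & repeat, 1) \ erode(base & repeat, 1)` and converts it
#' to a volume through the intensity window width:
#' `change_mL = voxel_volume / (i_high - i_low) * sum_B(clip(base) -
#' clip(repeat))`.  Percent change is relative to the baseline region
#' volume.
#'
#' @param baseline baseline `voxel_image`.
#' @param repeat_img repeat image, affine-aligned and intensity-normalised.
#' @param region_base,region_repeat brain region masks at the two time
#'   points, on the common grid.
#' @param window a [bbsi_window()].
#' @param interval_days scan interval (days).
#' @return an [atrophy_result()] with method `"bbsi"`.
#' @export
bbsi <- function(baseline, repeat_img, region_base, region_repeat, window,
                 interval_days) {
  check_same_grid(baseline, repeat_img, "baseline and repeat")
  check_same_grid(region_base, region_repeat, "region masks")
  inter <- binary_mask(region_base$data & region_repeat$data,
                       region_base$spacing, region_base$affine)
  if (!any(inter$data)) stop("region error: empty region intersection")
  band <- morph(inter, "dilate", 1)$data & !morph(inter, "erode", 1)$data
  if (!any(band)) stop("region error: empty boundary band")
  clip <- function(a) pmin(pmax(a, window$i_low), window$i_high)
  diff_sum <- sum(clip(baseline$data[band]) - clip(repeat_img$data[band]))
  vv <- prod(baseline$spacing)
  change_ml <- vv / (window$i_high - window$i_low) * diff_sum / 1000
  atrophy_result("bbsi", mask_volume_ml(region_base), change_ml,
                 interval_days,
                 qc = list(band_voxels = sum(band),
                           window = c(window$i_low, window$i_high)))
}
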