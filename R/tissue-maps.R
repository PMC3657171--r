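#' CSF/GM/WM probability maps
#'
#' Container for three tissue probability images on a common grid.  At every
#' brain voxel the probabilities sum to 1 (within 1e-6); outside the brain
#' all three are 0.
#'
#' @param p_csf,p_gm,p_wm 3D arrays of probabilities in `[0, 1]`.
#' @param spacing,affine grid geometry.
#' @return object of class `tissue_maps`.
#' @export
tissue_maps <- function(p_csf, p_gm, p_wm, spacing = c(1, 1, 1),
                        affine = NULL) {
  geom <- voxel_image(as.array(p_csf), spacing, affine)
  p_csf <- as.array(p_csf); p_gm <- as.array(p_gm); p_wm <- as.array(p_wm)
  if (!all(dim(p_gm) == dim(p_csf)) || !all(dim(p_wm) == dim(p_csf)))
    stop("probability maps must share a grid")
  tot <- p_csf + p_gm + p_wm
  bad <- tot > 1e-6 & abs(tot - 1) > 1e-6
  if (any(bad))
    stop("probabilities must sum to 1 at brain voxels (", sum(bad),
         " violations)")
  if (min(p_csf, p_gm, p_wm) < -1e-9 || max(p_csf, p_gm, p_wm) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
  structure(list(p_csf = p_csf, p_gm = p_gm, p_wm = p_wm,
                 spacing = geom$spacing, affine = geom$affine),
            class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  vv <- prod(x$spacing) / 1000
  cat("<tissue_maps> ", paste(dim(x$p_gm), collapse = " x "),
      " voxels; soft volumes (mL): CSF ", signif(sum(x$p_csf) * vv, 5),
      ", GM ", signif(sum(x$p_gm) * vv, 5),
      ", WM ", signif(sum(x$p_wm) * vv, 5), "\n", sep = "")
  invisible(x)
}

#' Threshold the GM probability map to a binary mask
#'
#' Voxels with `p_gm >= threshold` (inclusive) are included.
#'
#' @param tissues a [tissue_maps()].
#' @param threshold probability cut in (0, 1); default 0.5.
#' @return object of class `gm_mask`: a `binary_mask` with extra fields
#'   `threshold` and `volume_ml`.
#' @export
binarize_gm <- function(tissues, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  m <- binary_mask(tissues$p_gm >= threshold, tissues$spacing,
                   tissues$affine)
  m$threshold <- threshold
  m$volume_ml <- mask_volume_ml(m)
  class(m) <- c("gm_mask", class(m))
  m
}
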