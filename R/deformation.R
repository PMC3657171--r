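#' Dense displacement field
#'
#' Per-voxel 3-vector displacements in world millimetres, defined on a
#' reference grid: the deformation maps a grid point at world position `x` to
#' `x + u(x)`.
#'
#' @param disp 4D array `dim x 3` of displacements (mm).
#' @param spacing,affine grid geometry, as for [voxel_image()].
#' @param regrids number of regridding events accumulated while the field was
#'   built (0 for analytic fields).
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(disp, spacing = c(1, 1, 1), affine = NULL,
                              regrids = 0L) {
  disp <- as.array(disp)
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement must be a 4D array with 3 components")
  if (any(!is.finite(disp))) stop("displacement contains NaN/Inf")
  geom <- voxel_image(array(0, d[1:3]), spacing, affine)
  structure(list(disp = disp, spacing = geom$spacing, affine = geom$affine,
                 regrids = as.integer(regrids)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat("<deformation_field> ", paste(dim(x$disp)[1:3], collapse = " x "),
      " voxels, |u| mean ", signif(mean(mag), 4), " mm, max ",
      signif(max(mag), 4), " mm, regrids ", x$regrids, "\n", sep = "")
  invisible(x)
}
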