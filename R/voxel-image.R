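#' 3D image container with voxel geometry
#'
#' A `voxel_image` wraps a 3D scalar array together with its voxel spacing
#' (mm per axis) and a 4x4 voxel-to-world affine.  Voxel indices are 0-based:
#' world = affine %*% c(i, j, k, 1).  All displacements and coordinates used
#' by the package are in millimetres.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per axis; all entries must be > 0.
#' @param affine 4x4 voxel-to-world matrix.  Defaults to `diag(spacing)` with
#'   a zero origin.
#' @return An object of class `voxel_image` with elements `data`, `spacing`,
#'   `affine`.
#' @export
voxel_image <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("voxel_image requires a 3D array, got ", length(dim(data)), "D")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("affine is singular")
  if (any(!is.finite(data)))
    stop("image data contains NaN/Inf")
  vv <- abs(det(affine[1:3, 1:3]))
  if (abs(vv - prod(spacing)) > 1e-9 * prod(spacing))
    stop("affine 3x3 determinant (", vv, ") inconsistent with spacing volume (",
         prod(spacing), ")")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat("<voxel_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 6), collapse = " x "),
      " mm, voxel volume ", signif(voxel_volume(x), 6), " mm^3\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 6), ", ",
      signif(max(x$data), 6), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

#' Voxel volume in mm^3
#' @param img a `voxel_image` or `binary_mask`.
#' @return product of the voxel spacings (mm^3).
#' @export
voxel_volume <- function(img) prod(img$spacing)

#' Binary mask on a voxel grid
#'
#' @param data logical (or coercible) 3D array.
#' @param spacing,affine voxel geometry, as for [voxel_image()].
#' @return An object of class `binary_mask` (fields `data`, `spacing`,
#'   `affine`).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("binary_mask requires a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA")
  img <- voxel_image(array(0, dim(data)), spacing, affine)
  structure(list(data = data, spacing = img$spacing, affine = img$affine),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " set, volume ", signif(mask_volume_ml(x), 6), " mL\n",
      sep = "")
  invisible(x)
}

#' Mask volume in millilitres
#' @param mask a `binary_mask`.
#' @return count of set voxels times voxel volume, in mL.
#' @export
mask_volume_ml <- function(mask) sum(mask$data) * prod(mask$spacing) / 1000

# Check two grid-bearing objects share geometry (shape, spacing, affine).
check_same_grid <- function(a, b, what = "images") {
  if (!all(dim(a$data) == dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$affine - b$affine)) > 1e-6)
    stop(what, " are not on the same grid")
  invisible(TRUE)
}

#' Finite-difference spatial gradient
#'
#' Central differences in the interior, one-sided at the faces, scaled by the
#' voxel spacing per axis, so units are intensity per mm along each *grid*
#' axis.
#'
#' @param img a `voxel_image` (every dimension must be >= 3).
#' @return list of three 3D arrays `gx`, `gy`, `gz`.
#' @export
central_gradient <- function(img) {
  a <- img$data
  d <- dim(a)
  if (any(d < 3L)) stop("central_gradient needs >= 3 voxels per axis")
  g <- lapply(1:3, function(ax) axis_gradient(a, ax) / img$spacing[ax])
  names(g) <- c("gx", "gy", "gz")
  g
}

# d/d(index) along axis ax: central interior, one-sided at the two faces.
axis_gradient <- function(a, ax) {
  d <- dim(a)
  n <- d[ax]
  g <- array(0, d)
  if (ax == 1L) {
    g[2:(n - 1), , ] <- (a[3:n, , ] - a[1:(n - 2), , ]) / 2
    g[1, , ] <- a[2, , ] - a[1, , ]
    g[n, , ] <- a[n, , ] - a[n - 1, , ]
  } else if (ax == 2L) {
    g[, 2:(n - 1), ] <- (a[, 3:n, ] - a[, 1:(n - 2), ]) / 2
    g[, 1, ] <- a[, 2, ] - a[, 1, ]
    g[, n, ] <- a[, n, ] - a[, n - 1, ]
  } else {
    g[, , 2:(n - 1)] <- (a[, , 3:n] - a[, , 1:(n - 2)]) / 2
    g[, , 1] <- a[, , 2] - a[, , 1]
    g[, , n] <- a[, , n] - a[, , n - 1]
  }
  g
}
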