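# Shift a logical/numeric 3D array by one voxel along an axis, filling with
# `fill`.  by = +1 shifts content toward higher indices.
shift_array <- function(a, ax, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[ax]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  sel <- function(i) {
    s <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); s[[ax]] <- i; s
  }
  out <- do.call(`[<-`, c(list(out), sel(dst),
                          list(do.call(`[`, c(list(a), sel(src))))))
  out
}

#' Separable Gaussian smoothing
#'
#' Truncated (3 sigma) separable Gaussian kernel applied along each grid
#' axis, with zero fill outside the volume.
#'
#' @param img a `voxel_image`.
#' @param sigma_vox kernel SD in voxels (scalar; 0 returns the input).
#' @return the smoothed `voxel_image`.
#' @export
gaussian_smooth <- function(img, sigma_vox) {
  if (sigma_vox <= 0) return(img)
  a <- img$data
  r <- ceiling(3 * sigma_vox)
  k <- stats::dnorm(-r:r, 0, sigma_vox)
  k <- k / sum(k)
  for (ax in 1:3) {
    out <- a * k[r + 1]
    for (s in seq_len(r))
      out <- out + k[r + 1 + s] * shift_array(a, ax, s, 0) +
        k[r + 1 - s] * shift_array(a, ax, -s, 0)
    a <- out
  }
  voxel_image(a, img$spacing, img$affine)
}

#' Morphological dilation / erosion of a binary mask
#'
#' Uses the 6-connected (face-neighbour) structuring element, applied
#' iteratively.  Outside the volume counts as background, so erosion strips
#' voxels touching the volume faces.
#'
#' @param mask a `binary_mask`.
#' @param op `"dilate"` or `"erode"`.
#' @param iterations number of one-voxel passes (>= 1).
#' @return the transformed `binary_mask`.
#' @export
morph <- function(mask, op = c("dilate", "erode"), iterations = 1L) {
  op <- match.arg(op)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  m <- mask$data
  for (it in seq_len(iterations)) {
    nb <- list(shift_array(m, 1, 1), shift_array(m, 1, -1),
               shift_array(m, 2, 1), shift_array(m, 2, -1),
               shift_array(m, 3, 1), shift_array(m, 3, -1))
    if (op == "dilate") {
      m <- m | nb[[1]] | nb[[2]] | nb[[3]] | nb[[4]] | nb[[5]] | nb[[6]]
    } else {
      m <- m & nb[[1]] & nb[[2]] & nb[[3]] & nb[[4]] & nb[[5]] & nb[[6]]
    }
  }
  if (op == "erode" && !any(m)) warning("erosion produced an empty mask")
  binary_mask(m, spacing = mask$spacing, affine = mask$affine)
}
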