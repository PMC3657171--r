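#' Three-class Gaussian-mixture tissue segmentation
#'
#' Fits a 3-component Gaussian mixture to the intensities of brain voxels by
#' expectation-maximisation, initialised from the intensity terciles, and
#' returns per-voxel posterior probabilities as CSF/GM/WM maps.  Components
#' are mapped to tissues by ascending mean (CSF < GM < WM), so the labelling
#' is invariant to initialisation order.  An optional spatial regularisation
#' averages each posterior over the 6-connected neighbourhood (brain voxels
#' only) for a fixed number of sweeps, then renormalises.
#'
#' @param img a `voxel_image`.
#' @param brain `binary_mask` of brain voxels (nonempty; intensities must
#'   not be constant inside it).
#' @param seed integer seed (used for jittered restarts if EM degenerates;
#'   the fit is deterministic given the seed).
#' @param smooth_sweeps number of 6-neighbour posterior averaging sweeps
#'   (default 2; 0 disables regularisation).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return a [tissue_maps()] on the image grid (zero outside the brain).
#' @export
segment_tissues <- function(img, brain, seed = 1L, smooth_sweeps = 2L,
                            max_iter = 100L, tol = 1e-6) {
  check_same_grid(img, brain, "image and brain mask")
  inb <- brain$data
  if (!any(inb)) stop("brain mask is empty")
  x <- img$data[inb]
  if (stats::sd(x) < 1e-12) stop("intensities are constant inside the brain")
  set.seed(seed)
  fit <- NULL
  for (attempt in 1:3) {
    fit <- tryCatch(gmm3_em(x, jitter = (attempt - 1) * 0.05,
                            max_iter = max_iter, tol = tol),
                    error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error"))
    stop("EM failed after 3 restarts: ", conditionMessage(fit))
  # order components by mean: CSF < GM < WM
  ord <- order(fit$mu)
  post <- fit$post[, ord, drop = FALSE]
  d <- dim(img$data)
  maps <- lapply(1:3, function(k) {
    a <- array(0, d); a[inb] <- post[, k]; a
  })
  if (smooth_sweeps > 0) {
    bnum <- array(as.numeric(inb), d)
    for (s in seq_len(smooth_sweeps)) {
      nb_count <- neighbour_sum(bnum) + bnum
      for (k in 1:3) {
        sm <- (neighbour_sum(maps[[k]]) + maps[[k]]) / pmax(nb_count, 1)
        maps[[k]] <- sm * bnum
      }
    }
    tot <- maps[[1]] + maps[[2]] + maps[[3]]
    tot[tot == 0] <- 1
    maps <- lapply(maps, function(m) m / tot * bnum)
  }
  tissue_maps(maps[[1]], maps[[2]], maps[[3]], img$spacing, img$affine)
}

# Sum of the 6 face neighbours (zero fill at volume faces).
neighbour_sum <- function(a) {
  shift_array(a, 1, 1, 0) + shift_array(a, 1, -1, 0) +
    shift_array(a, 2, 1, 0) + shift_array(a, 2, -1, 0) +
    shift_array(a, 3, 1, 0) + shift_array(a, 3, -1, 0)
}

# 3-component univariate Gaussian mixture EM, tercile initialisation.
gmm3_em <- function(x, jitter = 0, max_iter = 100L, tol = 1e-6) {
  n <- length(x)
  q <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
  grp <- 1L + (x > q[1]) + (x > q[2])
  mu <- tapply(x, grp, mean)
  sg <- tapply(x, grp, stats::sd)
  if (length(mu) < 3L) stop("degenerate tercile initialisation")
  sg[!is.finite(sg) | sg < 1e-6] <- stats::sd(x) / 10
  if (jitter > 0) {
    mu <- mu * (1 + jitter * stats::rnorm(3))
    sg <- sg * (1 + abs(jitter * stats::rnorm(3)))
  }
  pi_k <- tabulate(grp, 3L) / n
  floor_sd <- 1e-4 * stats::sd(x)
  ll_old <- -Inf
  post <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k)
      pi_k[k] * stats::dnorm(x, mu[k], sg[k]), numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    post <- dens / tot
    nk <- colSums(post)
    if (any(nk < 1)) stop("vanishing mixture component")
    mu <- colSums(post * x) / nk
    sg <- sqrt(colSums(post * (x - rep(mu, each = n))^2) / nk)
    if (any(!is.finite(sg))) stop("vanishing variance in EM")
    # noise-free classes are delta spikes: clamp rather than fail
    sg <- pmax(sg, floor_sd)
    pi_k <- nk / n
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sg, pi = pi_k, post = post, loglik = ll, iters = it)
}
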