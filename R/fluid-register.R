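#' Jacobian determinant map of a deformation field
#'
#' For the map `x -> x + u(x)` the Jacobian is `J = det(I + du/dx)`, with
#' the displacement gradient taken by central differences (one-sided at the
#' faces) and scaled to physical mm through the grid affine.  Values above 1
#' mark local expansion, below 1 local contraction.
#'
#' @param field a `deformation_field` (>= 3 voxels per axis).
#' @param allow_negative keep going when `det J <= 0` occurs (used for
#'   diagnostic maps); by default folding raises an error listing the first
#'   offending voxels.
#' @return object of class `jacobian_map`: a `voxel_image` whose `data` is
#'   `det J`.
#' @export
jacobian_determinant <- function(field, allow_negative = FALSE) {
  d <- dim(field$disp)[1:3]
  if (any(d < 3L)) stop("need >= 3 voxels per axis")
  Ai <- solve(field$affine[1:3, 1:3])
  # G[[i]][[j]] = d u_i / d x_j (world mm)
  G <- vector("list", 3)
  for (i in 1:3) {
    gi <- lapply(1:3, function(ax) axis_gradient(field$disp[, , , i], ax))
    G[[i]] <- lapply(1:3, function(j)
      gi[[1]] * Ai[1, j] + gi[[2]] * Ai[2, j] + gi[[3]] * Ai[3, j])
  }
  a11 <- 1 + G[[1]][[1]]; a12 <- G[[1]][[2]]; a13 <- G[[1]][[3]]
  a21 <- G[[2]][[1]]; a22 <- 1 + G[[2]][[2]]; a23 <- G[[2]][[3]]
  a31 <- G[[3]][[1]]; a32 <- G[[3]][[2]]; a33 <- 1 + G[[3]][[3]]
  detj <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  if (!allow_negative && any(detj <= 0)) {
    w <- which(detj <= 0, arr.ind = TRUE)
    stop("folding error: det J <= 0 at ", nrow(w), " voxels, first at (",
         paste(w[1, ], collapse = ", "), ")")
  }
  out <- voxel_image(detj, field$spacing, field$affine)
  class(out) <- c("jacobian_map", class(out))
  out
}

#' Body force of the fluid registration
#'
#' Analytic gradient of the global normalised cross-correlation between the
#' baseline and the (currently warped) repeat image with respect to the
#' per-voxel displacement.  Both mean-subtraction terms vanish exactly
#' because the centred residuals sum to zero, leaving
#' `F(x) = [a(x) - C (|a|/|b|) b(x)] / (|a||b|) * grad W(x)` inside the
#' mask and zero outside (`a`, `b` the centred baseline/warped intensities,
#' `C` the current correlation).  Pointing along +F increases the
#' correlation.
#'
#' @param baseline fixed `voxel_image`.
#' @param warped current warped repeat `voxel_image` (same grid).
#' @param mask `binary_mask` support of the correlation.
#' @return list: `force` (4D `dim x 3` array, intensity^0 per mm), `ncc`
#'   (current correlation).
#' @export
body_force <- function(baseline, warped, mask) {
  check_same_grid(baseline, warped, "baseline and warped")
  m <- mask$data
  a <- baseline$data[m]; b <- warped$data[m]
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12)
    stop("zero-variance image inside mask: correlation gradient undefined")
  C <- sum(a * b) / (na * nb)
  coef <- array(0, dim(baseline$data))
  coef[m] <- (a - C * (na / nb) * b) / (na * nb)
  g <- central_gradient(warped)
  # map grid-axis derivatives to world axes
  Ai <- solve(baseline$affine[1:3, 1:3] %*% diag(1 / baseline$spacing))
  d <- dim(baseline$data)
  force <- array(0, c(d, 3))
  for (j in 1:3)
    force[, , , j] <- coef *
      (g$gx * Ai[1, j] + g$gy * Ai[2, j] + g$gz * Ai[3, j])
  list(force = force, ncc = C)
}

# Interpolate each displacement component at x + delta (compositive field
# update u_new = delta + u(x + delta)).  `idx` lets inner loops reuse the
# index grid.
compose_displacement <- function(disp, step_disp, spacing, idx = NULL) {
  d <- dim(disp)[1:3]
  if (is.null(idx)) idx <- index_grid(d)
  ci <- idx[1, ] + step_disp[, , , 1] / spacing[1]
  cj <- idx[2, ] + step_disp[, , , 2] / spacing[2]
  ck <- idx[3, ] + step_disp[, , , 3] / spacing[3]
  out <- step_disp
  for (i in 1:3)
    out[, , , i] <- step_disp[, , , i] +
      array(interp_trilinear(disp[, , , i], ci, cj, ck), d)
  out
}

# Trilinear warp of a source on its own grid by displacement u.
warp_same_grid <- function(adata, disp, spacing, idx) {
  d <- dim(adata)
  ci <- idx[1, ] + disp[, , , 1] / spacing[1]
  cj <- idx[2, ] + disp[, , , 2] / spacing[2]
  ck <- idx[3, ] + disp[, , , 3] / spacing[3]
  array(interp_trilinear(adata, ci, cj, ck), d)
}

#' Viscous-fluid registration of a repeat image to baseline
#'
#' Greedy time-stepping of the compressible viscous-fluid model: at each
#' iteration the body force (NCC gradient) is computed on the current
#' warped repeat, the fluid equation is solved for a velocity field, and
#' the displacement is advanced by a step sized so the largest increment is
#' `max_step` of a voxel, composing the increment with the running field.
#' When the incremental field's minimum Jacobian determinant falls below
#' the regrid threshold the incremental field is reset (a regrid) while the
#' total transformation keeps accumulating by composition.  Iteration stops
#' when the mean body-force norm over the mask falls below the threshold or
#' the cap is reached; the returned Jacobian map is that of the total
#' composed transformation, and the final warped repeat is rendered with
#' windowed-sinc interpolation.
#'
#' @param baseline fixed `voxel_image` (already cropped).
#' @param repeat_img moving `voxel_image`, affine-aligned and
#'   intensity-normalised to baseline, on the same grid.
#' @param mask `binary_mask` (brain region) on the same grid.
#' @param params a [fluid_params()].
#' @param verbose print per-iteration progress.
#' @return object of class `fluid_result`: `field` (`deformation_field`,
#'   total), `detj` (`jacobian_map` of the total field), `warped`
#'   (`voxel_image`), `log` (data.frame: iteration, ncc, mean_force,
#'   step_mm, max_increment_mm, min_detj_inc, regrid), `converged`,
#'   `iterations`, `regrids`.
#' @export
fluid_register <- function(baseline, repeat_img, mask,
                           params = fluid_params(), verbose = FALSE) {
  check_same_grid(baseline, repeat_img, "baseline and repeat")
  check_same_grid(baseline, mask, "baseline and mask")
  d <- dim(baseline$data)
  base_s <- gaussian_smooth(baseline, params$smooth_sigma)
  rep_s <- gaussian_smooth(repeat_img, params$smooth_sigma)
  u_tot <- array(0, c(d, 3))
  u_inc <- array(0, c(d, 3))
  msum <- sum(mask$data)
  log_rows <- vector("list", params$max_iter)
  converged <- FALSE
  stop_reason <- "max_iter"
  regrids <- 0L
  warped <- rep_s
  ncc_prev <- masked_ncc(base_s$data, warped$data, mask$data)
  step_cap <- params$max_step * min(baseline$spacing)
  last_step <- NULL
  idx <- index_grid(d)
  bvals <- base_s$data[mask$data]
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    bf <- body_force(base_s, warped, mask)
    fmag <- sqrt(bf$force[, , , 1]^2 + bf$force[, , , 2]^2 +
                   bf$force[, , , 3]^2)
    mean_force <- sum(fmag[mask$data]) / msum
    if (mean_force < params$force_threshold) {
      converged <- TRUE
      stop_reason <- "force_threshold"
      log_rows[[it]] <- data.frame(iteration = it, ncc = bf$ncc,
                                   mean_force = mean_force, step_mm = 0,
                                   max_increment_mm = 0,
                                   min_detj_inc = NA_real_,
                                   regrid = FALSE)
      break
    }
    vel <- if (params$solver == "fft")
      fluid_solve_fft(bf$force, params, baseline$spacing)
    else solve_velocity(bf$force, params, baseline$spacing)$v
    vmax <- max(abs(vel))
    if (vmax == 0) {
      converged <- TRUE
      stop_reason <- "zero_velocity"
      break
    }
    # adaptive step: start from twice the last accepted increment (capped
    # at max_step voxels) and halve until the correlation strictly improves
    step <- if (is.null(last_step)) step_cap
            else min(step_cap, 2 * last_step)
    accepted <- FALSE
    for (h in 0:8) {
      u_try <- compose_displacement(u_tot, vel * (step / vmax),
                                    baseline$spacing, idx)
      w_try <- warp_same_grid(rep_s$data, u_try, baseline$spacing, idx)
      ncc_try <- stats::cor(bvals, w_try[mask$data])
      if (ncc_try > ncc_prev) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      # no admissible step improves the cost: the greedy flow has
      # stagnated at (its) optimum
      converged <- TRUE
      stop_reason <- "stagnation"
      log_rows[[it]] <- data.frame(iteration = it, ncc = ncc_prev,
                                   mean_force = mean_force, step_mm = 0,
                                   max_increment_mm = 0,
                                   min_detj_inc = NA_real_,
                                   regrid = FALSE)
      break
    }
    u_tot <- u_try
    u_inc <- u_inc + vel * (step / vmax)
    warped <- voxel_image(w_try, baseline$spacing, baseline$affine)
    ncc_prev <- ncc_try
    last_step <- step
    # regrid watch every few iterations (increments are capped at
    # max_step voxels, so the incremental det J drifts slowly)
    min_dj <- NA_real_
    regrid <- FALSE
    if (it %% 3L == 0L || it == params$max_iter) {
      inc_field <- deformation_field(u_inc, baseline$spacing,
                                     baseline$affine)
      min_dj <- min(jacobian_determinant(inc_field,
                                         allow_negative = TRUE)$data)
      if (min_dj < params$regrid_threshold) {
        regrid <- TRUE
        regrids <- regrids + 1L
        u_inc <- array(0, c(d, 3))
      }
    }
    log_rows[[it]] <- data.frame(iteration = it, ncc = ncc_try,
                                 mean_force = mean_force, step_mm = step,
                                 max_increment_mm = step,
                                 min_detj_inc = min_dj, regrid = regrid)
    if (verbose)
      message(sprintf("iter %3d  ncc %.7f  mean|F| %.3e  step %.3f mm",
                      it, ncc_try, mean_force, step))
  }
  field <- deformation_field(u_tot, baseline$spacing, baseline$affine,
                             regrids = regrids)
  detj <- jacobian_determinant(field)
  warped_final <- warp_field_image(repeat_img, u_tot, baseline, "sinc")
  structure(list(field = field, detj = detj, warped = warped_final,
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                       logical(1))]),
                 converged = converged, stop_reason = stop_reason,
                 iterations = it, regrids = regrids),
            class = "fluid_result")
}

#' @export
print.fluid_result <- function(x, ...) {
  cat("<fluid_result> ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "iteration cap reached",
      ", regrids ", x$regrids, "\n", sep = "")
  cat("  final NCC ", signif(utils::tail(x$log$ncc, 1), 6),
      ", det J range [", signif(min(x$detj$data), 4), ", ",
      signif(max(x$detj$data), 4), "]\n", sep = "")
  invisible(x)
}

masked_ncc <- function(a, b, m) {
  stats::cor(a[m], b[m])
}

# Warp img by a raw displacement array defined on ref's grid.
warp_field_image <- function(img, disp, ref, method) {
  warp_image(img, deformation_field(disp, ref$spacing, ref$affine),
             method = method)
}
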