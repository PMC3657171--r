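# Replicate phantom studies shared between module and acceptance tests.
# Computed lazily once per test run (the fluid stage dominates runtime).

.study_env <- new.env(parent = emptyenv())

# n_rep matched pairs with 2% true GM loss; jacobian and seg-subtract
# rates per replicate plus the per-replicate truth.
recovery_study <- function(n_rep = 20L) {
  key <- paste0("recovery_", n_rep)
  if (!is.null(.study_env[[key]])) return(.study_env[[key]])
  jac <- segs <- truths <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    ph <- make_phantom(phantom_spec(seed = s))
    fu <- apply_known_atrophy(ph$image, ph$truth, 0.02, seed = 1000 + s,
                              mode = "gm")
    base_c <- crop_dilated(ph$image, ph$brain, 3)
    bbox <- attr(base_c, "bbox")
    rep_c <- apply_crop(fu$image, bbox)
    mask_c <- apply_crop(ph$brain, bbox)
    gm_b <- binarize_gm(segment_tissues(base_c, mask_c, seed = s))
    fr <- fluid_register(base_c, rep_c, mask_c)
    jac[s] <- jacobian_integrate(fr$detj, gm_b, 365.25)$rate_pct_yr
    gm_r <- binarize_gm(segment_tissues(rep_c, mask_c,
                                        seed = 10000 + s))
    segs[s] <- seg_subtract(gm_b, gm_r, 365.25)$rate_pct_yr
    truths[s] <- 100 * fu$truth$deformation$achieved_loss
  }
  out <- list(jacobian = jac, seg_subtract = segs, truth = truths)
  .study_env[[key]] <- out
  out
}

# Monte-Carlo check of the Pitman CI: paired Gaussian rates with the
# 1-year AD moments (SDs 0.96 vs 2.86, correlation 0.5, n = 37).
pitman_mc <- function(nrep = 2000L) {
  key <- paste0("pitman_", nrep)
  if (!is.null(.study_env[[key]])) return(.study_env[[key]])
  set.seed(20240915)
  true_ratio <- 0.96 / 2.86
  cover <- logical(nrep)
  est <- numeric(nrep)
  n <- 37
  for (i in seq_len(nrep)) {
    z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
    x <- 2.01 + 0.96 * z1
    y <- 2.37 + 2.86 * z2
    p <- pitman_sd_ratio(x, y)
    est[i] <- p$ratio
    cover[i] <- !anyNA(p$ci) && p$ci[1] <= true_ratio &&
      p$ci[2] >= true_ratio
  }
  out <- list(coverage = mean(cover), mean_ratio = mean(est),
              true_ratio = true_ratio)
  .study_env[[key]] <- out
  out
}

# n_rep pairs with 1% true parenchymal loss measured by the BBSI, using
# the analytic tissue geometry for regions and window provenance.
bbsi_study <- function(n_rep = 10L) {
  key <- paste0("bbsi_", n_rep)
  if (!is.null(.study_env[[key]])) return(.study_env[[key]])
  rates <- truths <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    ph <- make_phantom(phantom_spec(seed = 40 + s))
    fu <- apply_known_atrophy(ph$image, ph$truth, 0.01, seed = 2000 + s,
                              mode = "brain")
    sp <- ph$image$spacing
    pts <- diag(sp) %*% gmatrophy:::index_grid(dim(ph$image$data))
    par_base <- binary_mask(ph$truth$labels >= 2, sp, ph$image$affine)
    # analytic follow-up parenchyma: labels at the mapped positions
    disp <- fu$truth$deformation$field$disp
    moved <- pts + rbind(as.vector(disp[, , , 1]),
                         as.vector(disp[, , , 2]),
                         as.vector(disp[, , , 3]))
    lab_rep <- gmatrophy:::phantom_labels(ph$truth$geom, moved)
    par_rep <- binary_mask(array(lab_rep >= 2, dim(ph$image$data)), sp,
                           ph$image$affine)
    win <- bbsi_window(ph$image, fu$image, ph$truth$tissues)
    res <- bbsi(ph$image, fu$image, par_base, par_rep, win, 365.25)
    rates[s] <- res$rate_pct_yr
    truths[s] <- 100 * fu$truth$deformation$achieved_loss
  }
  out <- list(bbsi = rates, truth = truths)
  .study_env[[key]] <- out
  out
}
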