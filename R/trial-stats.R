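# Trial statistics: annualised rates, sample sizes, Pitman's test, BCa
# bootstrap ratios, covariate-adjusted group differences.

#' Annualise a percent change
#'
#' @param pct percent change over the interval.
#' @param interval_days interval length in days (> 0).
#' @return rate in percent per year (365.25-day years).
#' @export
annualize <- function(pct, interval_days) {
  if (any(interval_days <= 0)) stop("interval must be positive")
  pct * 365.25 / interval_days
}

#' Per-group summary of annualised rates
#'
#' @param label group label (e.g. `"AD"`, `"control"`).
#' @param n number of subjects (>= 2).
#' @param mean mean annualised rate (%/yr).
#' @param sd SD of the annualised rate (%/yr, >= 0).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Trial design for sample-size estimation
#'
#' `u` and `v` are the normal quantiles for power and the two-sided
#' significance level.  With `paper_rounding = TRUE` (default) the
#' conventional rounded values u = 1.28 (90% power), u = 0.84 (80% power)
#' and v = 1.96 (5% two-sided) are used, matching printed arithmetic;
#' otherwise full-precision quantiles.
#'
#' @param power target power in (0, 1); default 0.90.
#' @param alpha two-sided significance level; default 0.05.
#' @param effect fractional treatment effect `e` in (0, 1]; default 0.20.
#' @param aging if `TRUE`, a fully effective treatment reduces the patient
#'   rate to the control rate (normal aging) instead of to zero.
#' @param paper_rounding use rounded normal quantiles (see above).
#' @return object of class `trial_design`.
#' @export
trial_design <- function(power = 0.90, alpha = 0.05, effect = 0.20,
                         aging = FALSE, paper_rounding = TRUE) {
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (effect <= 0 || effect > 1) stop("effect must be in (0, 1]")
  structure(list(power = power, alpha = alpha, effect = effect,
                 aging = isTRUE(aging),
                 paper_rounding = isTRUE(paper_rounding)),
            class = "trial_design")
}

design_u <- function(design) {
  if (design$paper_rounding) {
    if (abs(design$power - 0.90) < 1e-9) return(1.28)
    if (abs(design$power - 0.80) < 1e-9) return(0.84)
  }
  stats::qnorm(design$power)
}

design_v <- function(design) {
  if (design$paper_rounding && abs(design$alpha - 0.05) < 1e-9) return(1.96)
  stats::qnorm(1 - design$alpha / 2)
}

#' Treatment-group mean rate under a fractional effect
#'
#' The treated mean is moved a fraction `e` of the way from the patient
#' rate towards the control rate (aging-adjusted) or towards zero (no
#' aging adjustment).
#'
#' @param mu_patient mean patient rate (%/yr).
#' @param mu_control mean control rate (%/yr); required when
#'   `aging = TRUE`.
#' @param effect fractional effect `e` in (0, 1].
#' @param aging logical.
#' @return the treated-group mean `mu2` (%/yr).
#' @export
treatment_mean <- function(mu_patient, mu_control = NULL, effect = 0.2,
                           aging = FALSE) {
  if (effect <= 0 || effect > 1) stop("effect must be in (0, 1]")
  if (aging) {
    if (is.null(mu_control))
      stop("aging adjustment requires a control summary")
    mu_patient - effect * (mu_patient - mu_control)
  } else {
    (1 - effect) * mu_patient
  }
}

#' Sample size per trial arm
#'
#' The standard two-arm formula `n = (u + v)^2 * 2 sigma^2 / (mu1 - mu2)^2`
#' with `sigma` the patient-group SD, `mu1` the patient (placebo) mean and
#' `mu2` the treated mean from [treatment_mean()].  The per-arm size is the
#' ceiling of the raw value.
#'
#' @param patient a [group_summary()] for the patient group.
#' @param control a [group_summary()] for controls (needed when
#'   `design$aging`).
#' @param design a [trial_design()].
#' @return object of class `sample_size_result`: `n_per_arm`, `n_raw`,
#'   `mu1`, `mu2`, `sigma`, `design`.
#' @export
sample_size_per_arm <- function(patient, control = NULL,
                                design = trial_design()) {
  if (patient$sd <= 0) stop("degenerate design: zero patient SD")
  mu1 <- patient$mean
  mu2 <- treatment_mean(mu1, if (!is.null(control)) control$mean,
                        design$effect, design$aging)
  if (mu1 == mu2) stop("mu1 equals mu2: infinite sample size")
  u <- design_u(design); v <- design_v(design)
  n_raw <- (u + v)^2 * 2 * patient$sd^2 / (mu1 - mu2)^2
  structure(list(n_per_arm = ceiling(n_raw), n_raw = n_raw, mu1 = mu1,
                 mu2 = mu2, sigma = patient$sd, design = design),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("<sample_size_result> ", x$n_per_arm, " per arm (raw ",
      signif(x$n_raw, 6), "); mu1 ", x$mu1, ", mu2 ", signif(x$mu2, 6),
      ", sigma ", x$sigma,
      if (x$design$aging) ", aging-adjusted" else "", "\n", sep = "")
  invisible(x)
}

#' Rescale a sample size to a different effect size or power
#'
#' Scales by the squared ratio of effect sizes and by the squared ratio of
#' `(u + v)`.  By default the rounded per-arm estimate is rescaled (the
#' convention used when extrapolating printed tables); `from = "raw"`
#' rescales the unrounded value instead.
#'
#' @param result a `sample_size_result`.
#' @param effect new fractional effect (default: unchanged).
#' @param power new power (default: unchanged).
#' @param from `"rounded"` or `"raw"`.
#' @return a new `sample_size_result`.
#' @export
rescale_design <- function(result, effect = NULL, power = NULL,
                           from = c("rounded", "raw")) {
  from <- match.arg(from)
  d_old <- result$design
  d_new <- d_old
  if (!is.null(effect)) d_new$effect <- effect
  if (!is.null(power)) d_new$power <- power
  fac <- (d_old$effect / d_new$effect)^2 *
    ((design_u(d_new) + design_v(d_new)) /
       (design_u(d_old) + design_v(d_old)))^2
  base <- if (from == "rounded") result$n_per_arm else result$n_raw
  n_raw <- base * fac
  structure(list(n_per_arm = ceiling(n_raw), n_raw = n_raw,
                 mu1 = result$mu1, mu2 = NA_real_, sigma = result$sigma,
                 design = d_new), class = "sample_size_result")
}

#' Multiplier converting sample sizes between power levels
#'
#' @param power_from,power_to power levels (e.g. 0.90 to 0.80).
#' @param design a [trial_design()] supplying alpha and the rounding
#'   convention.
#' @return the factor `((u_to + v) / (u_from + v))^2`.
#' @export
power_multiplier <- function(power_from = 0.90, power_to = 0.80,
                             design = trial_design()) {
  d1 <- design; d1$power <- power_from
  d2 <- design; d2$power <- power_to
  ((design_u(d2) + design_v(d2)) / (design_u(d1) + design_v(d1)))^2
}

#' Pitman's test for equality of correlated variances
#'
#' For paired samples, `Var(x) = Var(y)` exactly when `x + y` and `x - y`
#' are uncorrelated; the test is a t-test on that correlation with n - 2
#' degrees of freedom.  The confidence interval for the SD ratio inverts
#' the t bound: a hypothesised ratio `L` is in the interval when the
#' correlation between `x / L + y` and `x / L - y` is within the critical
#' range.
#'
#' @param x,y paired rate vectors (equal length >= 3).
#' @param conf confidence level (default 0.95).
#' @return object of class `pitman_result`: `ratio` (SD(x)/SD(y)), `ci`,
#'   `statistic`, `df`, `p_value`, `degenerate`.
#' @export
pitman_sd_ratio <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need paired vectors of length >= 3")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("degenerate: zero SD in a sample")
  ratio <- sx / sy
  r <- suppressWarnings(stats::cor(x + y, x - y))
  degenerate <- FALSE
  if (is.na(r)) {  # x + y or x - y constant (e.g. y identical to x)
    degenerate <- TRUE
    tstat <- 0; p <- 1
  } else if (abs(r) >= 1) {
    tstat <- sign(r) * Inf; p <- 0
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  tcrit <- stats::qt(1 - (1 - conf) / 2, n - 2)
  tfun <- function(L) {
    rr <- suppressWarnings(stats::cor(x / L + y, x / L - y))
    if (is.na(rr)) return(0)
    if (abs(rr) >= 1) return(sign(rr) * 1e12)
    rr * sqrt(n - 2) / sqrt(1 - rr^2)
  }
  # t(L) is decreasing in L; bracket and invert for both bounds
  invert <- function(target) {
    lo <- ratio; hi <- ratio
    flo <- tfun(lo) - target
    i <- 0
    while (flo < 0 && i < 60) { lo <- lo / 2; flo <- tfun(lo) - target; i <- i + 1 }
    fhi <- tfun(hi) - target
    i <- 0
    while (fhi > 0 && i < 60) { hi <- hi * 2; fhi <- tfun(hi) - target; i <- i + 1 }
    if (flo < 0 || fhi > 0) return(NA_real_)
    stats::uniroot(function(L) tfun(L) - target, c(lo, hi),
                   tol = 1e-9 * ratio)$root
  }
  ci <- if (degenerate) c(NA_real_, NA_real_)
        else c(invert(tcrit), invert(-tcrit))
  structure(list(ratio = ratio, ci = ci, statistic = tstat, df = n - 2,
                 p_value = p, degenerate = degenerate, conf = conf),
            class = "pitman_result")
}

#' @export
print.pitman_result <- function(x, ...) {
  cat("<pitman_result> SD ratio ", signif(x$ratio, 4), ", ",
      round(100 * x$conf), "% CI [", signif(x$ci[1], 4), ", ",
      signif(x$ci[2], 4), "], p = ", format.pval(x$p_value, digits = 3),
      if (x$degenerate) " (degenerate pair)" else "", "\n", sep = "")
  invisible(x)
}

#' BCa bootstrap CI for a ratio of sample sizes between two methods
#'
#' Subjects are resampled with replacement within each group; per
#' replicate both methods' sample sizes are recomputed from the resampled
#' per-subject rates (each subject carries both methods' values) and the
#' ratio method A / method B formed.  Replicates with `mu1 = mu2` yield an
#' infinite sample size and are retained (the interval is read from order
#' statistics, which accommodate infinities).  Bias correction `z0` comes
#' from the proportion of replicates below the point estimate,
#' acceleration `a` from the jackknife.
#'
#' @param data data.frame with columns `group` (two levels; the first level
#'   sorted is taken as the control group), `rate_a`, `rate_b`
#'   (per-subject annualised rates for the two methods).
#' @param patient_label value of `group` identifying the patient group.
#' @param design a [trial_design()].
#' @param reps bootstrap replicates (>= 1000; default 10000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return object of class `bootstrap_ratio_result`: `ratio`, `ci`,
#'   `n_a`, `n_b`, `prop_infinite`, `reps`.
#' @export
bootstrap_ratio_ci <- function(data, patient_label, design = trial_design(),
                               reps = 10000L, seed = 1L, conf = 0.95) {
  if (reps < 1000L) stop("reps must be >= 1000")
  stopifnot(all(c("group", "rate_a", "rate_b") %in% names(data)))
  is_pat <- data$group == patient_label
  if (!any(is_pat) || all(is_pat)) stop("need both patient and control rows")
  pat <- data[is_pat, ]; ctl <- data[!is_pat, ]
  ss_ratio <- function(p, cc) {
    one <- function(rates_p, rates_c) {
      mu1 <- mean(rates_p); sg <- stats::sd(rates_p)
      mu2 <- treatment_mean(mu1, mean(rates_c), design$effect, design$aging)
      if (sg == 0 || mu1 == mu2) return(Inf)
      (design_u(design) + design_v(design))^2 * 2 * sg^2 / (mu1 - mu2)^2
    }
    one(p$rate_a, cc$rate_a) / one(p$rate_b, cc$rate_b)
  }
  est <- ss_ratio(pat, ctl)
  set.seed(seed)
  boot <- numeric(reps)
  np <- nrow(pat); nc <- nrow(ctl)
  for (b in seq_len(reps)) {
    boot[b] <- ss_ratio(pat[sample.int(np, np, replace = TRUE), ],
                        ctl[sample.int(nc, nc, replace = TRUE), ])
  }
  prop_inf <- mean(!is.finite(boot))
  if (prop_inf > 0.05)
    warning("more than 5% of bootstrap replicates were infinite")
  if (all(boot == est)) {  # degenerate resampling distribution
    return(structure(list(ratio = est, ci = c(est, est),
                          prop_infinite = prop_inf, reps = reps, z0 = 0,
                          accel = 0, conf = conf),
                     class = "bootstrap_ratio_result"))
  }
  # BCa on order statistics (rank-based, infinities sort to the top)
  z0 <- stats::qnorm(min(max(mean(boot < est), 1 / (reps + 1)),
                         reps / (reps + 1)))
  jack <- numeric(np + nc)
  for (i in seq_len(np)) jack[i] <- ss_ratio(pat[-i, ], ctl)
  for (i in seq_len(nc)) jack[np + i] <- ss_ratio(pat, ctl[-i, ])
  jfin <- jack[is.finite(jack)]
  if (length(jfin) >= 3 && stats::sd(jfin) > 0) {
    jm <- mean(jfin)
    a <- sum((jm - jfin)^3) / (6 * sum((jm - jfin)^2)^1.5)
  } else a <- 0
  alpha2 <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zs <- stats::qnorm(alpha2)
  adj <- stats::pnorm(z0 + (z0 + zs) / (1 - a * (z0 + zs)))
  srt <- sort(boot)  # infinities last
  pick <- function(q) srt[min(max(1L, ceiling(q * reps)), reps)]
  ci <- c(pick(adj[1]), pick(adj[2]))
  structure(list(ratio = est, ci = ci, prop_infinite = prop_inf,
                 reps = reps, z0 = z0, accel = a, conf = conf),
            class = "bootstrap_ratio_result")
}

#' @export
print.bootstrap_ratio_result <- function(x, ...) {
  cat("<bootstrap_ratio_result> sample-size ratio ", signif(x$ratio, 4),
      ", ", round(100 * x$conf), "% BCa CI [", signif(x$ci[1], 4), ", ",
      signif(x$ci[2], 4), "] (", x$reps, " replicates",
      if (x$prop_infinite > 0)
        paste0(", ", signif(100 * x$prop_infinite, 3), "% infinite"),
      ")\n", sep = "")
  invisible(x)
}

#' Group difference in atrophy rate adjusted for age and gender
#'
#' Ordinary least squares of rate on a group indicator with age and gender
#' as covariates; reports the group coefficient with its normal-theory CI.
#'
#' @param rates numeric vector of annualised rates.
#' @param group factor or indicator (patient vs control).
#' @param age numeric covariate (years).
#' @param gender factor or indicator covariate.
#' @param conf confidence level.
#' @return object of class `adjusted_difference`: `difference`, `ci`,
#'   `p_value`, `se`, `n`.
#' @export
adjusted_group_difference <- function(rates, group, age, gender,
                                      conf = 0.95) {
  df <- data.frame(rate = rates, group = factor(group), age = age,
                   gender = factor(gender))
  if (nrow(df) < 6) stop("need at least p + 2 = 6 observations")
  X <- stats::model.matrix(~ group + age + gender, df)
  if (qr(X)$rank < ncol(X)) stop("rank error: collinear design")
  fit <- stats::lm(rate ~ group + age + gender, df)
  co <- summary(fit)$coefficients
  i <- grep("^group", rownames(co))[1]
  tcrit <- stats::qt(1 - (1 - conf) / 2, fit$df.residual)
  structure(list(difference = co[i, 1],
                 ci = co[i, 1] + c(-1, 1) * tcrit * co[i, 2],
                 se = co[i, 2], p_value = co[i, 4], n = nrow(df),
                 conf = conf, fit = fit),
            class = "adjusted_difference")
}

#' @export
print.adjusted_difference <- function(x, ...) {
  cat("<adjusted_difference> ", signif(x$difference, 4), " %/yr, ",
      round(100 * x$conf), "% CI [", signif(x$ci[1], 4), ", ",
      signif(x$ci[2], 4), "], p = ", format.pval(x$p_value, digits = 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Load a group-summary table
#'
#' Reads a CSV of per-group rate summaries (columns `interval_months`,
#' `method`, `group`, `mean`, `sd`, `n`, plus any reference columns) such
#' as the cohort summary shipped in `inst/extdata/cohort_summary.csv`.
#'
#' @param path CSV path; default is the shipped cohort summary.
#' @return a data.frame.
#' @export
load_group_summaries <- function(path = system.file("extdata",
                                                    "cohort_summary.csv",
                                                    package = "gmatrophy")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
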