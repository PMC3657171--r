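#' Simulate a cohort of annualised atrophy rates
#'
#' Draws per-subject annualised rates Gaussian within each group, with an
#' optional paired second method correlated at `correlation` (bivariate
#' normal).  Age is drawn N(69.5, 7.1) years and gender Bernoulli with the
#' group's male fraction, mirroring a typical elderly AD/control cohort;
#' scan intervals are N(365, 14) days (N(180, 7) if `interval_months` is
#' 6).
#'
#' @param groups list of group specs; each a list with `label`, `mean`,
#'   `sd`, `n`, and optionally `mean_b`, `sd_b` (second-method moments,
#'   defaulting to the first method's), `male_frac` (default 0.4).
#' @param correlation between-method correlation in `[-1, 1]`, or `NULL`
#'   for a single method.
#' @param methods method labels (length 2 used when `correlation` given).
#' @param interval_months nominal interval, 6 or 12.
#' @param seed integer seed.
#' @return data.frame with columns `subject_id`, `group`, `method`,
#'   `rate_pct_per_yr`, `age`, `gender`, `interval_days` (long format; one
#'   row per subject and method).
#' @export
simulate_cohort <- function(groups, correlation = NULL,
                            methods = c("jacobian_gm", "seg_subtract"),
                            interval_months = 12, seed = 1L) {
  if (!is.null(correlation) && abs(correlation) > 1)
    stop("parameter error: |correlation| > 1")
  set.seed(seed)
  rows <- list()
  sid <- 0L
  for (g in groups) {
    if (g$sd < 0 || (!is.null(g$sd_b) && g$sd_b < 0)) stop("SDs must be >= 0")
    if (g$n < 2) stop("n must be >= 2")
    mb <- if (is.null(g$mean_b)) g$mean else g$mean_b
    sb <- if (is.null(g$sd_b)) g$sd else g$sd_b
    mf <- if (is.null(g$male_frac)) 0.4 else g$male_frac
    z1 <- stats::rnorm(g$n)
    ra <- g$mean + g$sd * z1
    age <- stats::rnorm(g$n, 69.5, 7.1)
    gender <- ifelse(stats::runif(g$n) < mf, "M", "F")
    iv_mean <- if (interval_months == 6) 180 else 365
    iv_sd <- if (interval_months == 6) 7 else 14
    interval <- round(stats::rnorm(g$n, iv_mean, iv_sd))
    ids <- sprintf("s%04d", sid + seq_len(g$n))
    sid <- sid + g$n
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = ids, group = g$label, method = methods[1],
      rate_pct_per_yr = ra, age = age, gender = gender,
      interval_days = interval)
    if (!is.null(correlation)) {
      z2 <- correlation * z1 +
        sqrt(1 - correlation^2) * stats::rnorm(g$n)
      rb <- mb + sb * z2
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids, group = g$label, method = methods[2],
        rate_pct_per_yr = rb, age = age, gender = gender,
        interval_days = interval)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a long cohort table to paired wide format
#'
#' @param cohort data.frame from [simulate_cohort()] with two methods.
#' @param methods the two method labels to pair (defaults to the first two
#'   present).
#' @return data.frame with `subject_id`, `group`, `age`, `gender`,
#'   `rate_a`, `rate_b` (suitable for [bootstrap_ratio_ci()] and
#'   [pitman_sd_ratio()]).
#' @export
cohort_pairs <- function(cohort, methods = NULL) {
  if (is.null(methods)) methods <- unique(cohort$method)[1:2]
  a <- cohort[cohort$method == methods[1], ]
  b <- cohort[cohort$method == methods[2], ]
  b <- b[match(a$subject_id, b$subject_id), ]
  data.frame(subject_id = a$subject_id, group = a$group, age = a$age,
             gender = a$gender, rate_a = a$rate_pct_per_yr,
             rate_b = b$rate_pct_per_yr)
}
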