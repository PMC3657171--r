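test_that("annualisation follows 365.25-day years", {
  expect_equal(annualize(1, 365.25), 1)
  expect_equal(annualize(1, 182.625), 2)
  expect_equal(annualize(0.9, 180), 0.9 * 365.25 / 180)  # 1.82625
  expect_equal(annualize(0.9, 180), 1.82625)
  expect_error(annualize(1, 0), "interval")
})

test_that("treated-group mean follows the fractional-effect rule", {
  # aging-adjusted: move a fraction e from the patient towards the control
  expect_equal(treatment_mean(2.01, 0.46, 0.2, aging = TRUE), 1.70)
  expect_equal(2.01 - treatment_mean(2.01, 0.46, 0.2, aging = TRUE), 0.31)
  # full effect: treated rate equals the control rate / zero
  expect_equal(treatment_mean(2.01, 0.46, 1, aging = TRUE), 0.46)
  expect_equal(treatment_mean(2.01, effect = 1, aging = FALSE), 0)
  expect_error(treatment_mean(2.01, effect = 0.2, aging = TRUE),
               "control")
})

test_that("sample sizes per arm reproduce the published 1-year values", {
  jac <- group_summary("AD", 37, 2.01, 0.96)
  ctl <- group_summary("control", 19, 0.46, 0.27)
  expect_equal(sample_size_per_arm(jac, design = trial_design())$n_per_arm,
               120)
  expect_equal(sample_size_per_arm(jac, ctl,
                                   trial_design(aging = TRUE))$n_per_arm,
               202)
  bbsi <- group_summary("AD", 37, 1.99, 0.91)
  expect_equal(sample_size_per_arm(bbsi,
                                   design = trial_design())$n_per_arm, 110)
  siena <- group_summary("AD", 37, 2.72, 1.25)
  expect_equal(sample_size_per_arm(siena,
                                   design = trial_design())$n_per_arm, 111)
  sctl <- group_summary("control", 19, 0.67, 0.82)
  expect_equal(sample_size_per_arm(siena, sctl,
                                   trial_design(aging = TRUE))$n_per_arm,
               196)
})

test_that("sample size is scale-invariant and monotone", {
  d <- trial_design()
  base <- sample_size_per_arm(group_summary("p", 30, 2, 1),
                              design = d)$n_raw
  for (k in c(0.5, 2, 7.3)) {
    scaled <- sample_size_per_arm(group_summary("p", 30, 2 * k, 1 * k),
                                  design = d)$n_raw
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  # monotone: increases with sigma^2, decreases with effect and separation
  expect_gt(sample_size_per_arm(group_summary("p", 30, 2, 1.5),
                                design = d)$n_raw, base)
  expect_lt(sample_size_per_arm(group_summary("p", 30, 2, 1),
                                design = trial_design(effect = 0.3))$n_raw,
            base)
  expect_lt(sample_size_per_arm(group_summary("p", 30, 3, 1),
                                design = d)$n_raw, base)
})

test_that("effect and power rescaling match the published extrapolations", {
  jac <- group_summary("AD", 37, 2.01, 0.96)
  ctl <- group_summary("control", 19, 0.46, 0.27)
  no_aging <- sample_size_per_arm(jac, design = trial_design())
  aging <- sample_size_per_arm(jac, ctl, trial_design(aging = TRUE))
  expect_equal(rescale_design(no_aging, effect = 0.25)$n_per_arm, 77)
  expect_equal(rescale_design(aging, effect = 0.25)$n_per_arm, 130)
  expect_equal(round(power_multiplier(0.90, 0.80), 3), 0.747)
  # round trip on the raw scale is the identity
  r1 <- rescale_design(no_aging, effect = 0.25, from = "raw")
  r2 <- rescale_design(r1, effect = 0.20, from = "raw")
  expect_equal(r2$n_raw, no_aging$n_raw, tolerance = 1e-12)
})

test_that("published SD ratios follow from the printed SDs", {
  tab <- load_group_summaries()
  j12 <- tab[tab$interval_months == 12 & tab$method == "jacobian", ]
  s12 <- tab[tab$interval_months == 12 & tab$method == "seg_subtract_all", ]
  expect_equal(round(j12$control_sd / s12$control_sd, 2), 0.12)
  expect_equal(round(j12$patient_sd / s12$patient_sd, 2), 0.34)
})

test_that("Pitman's test behaves on constructed pairs", {
  set.seed(1)
  x <- rnorm(30, 2, 1)
  # identical pair: ratio 1, degenerate correlation guarded, p = 1
  p0 <- pitman_sd_ratio(x, x)
  expect_equal(p0$ratio, 1)
  expect_true(p0$degenerate)
  expect_equal(p0$p_value, 1)
  # y = 2x: ratio exactly 0.5 and decisively significant for n >= 12
  p2 <- pitman_sd_ratio(x[1:12], 2 * x[1:12])
  expect_equal(p2$ratio, 0.5)
  expect_lt(p2$p_value, 0.05)
  expect_error(pitman_sd_ratio(x, rep(1, 30)), "zero SD")
})

test_that("Pitman CI covers a known SD ratio at roughly nominal rate", {
  # paired Gaussian cohort: SDs 0.96 vs 2.86 (ratio 0.336), n = 37,
  # between-method correlation 0.5
  mc <- pitman_mc(2000L)
  expect_lt(abs(mc$mean_ratio - mc$true_ratio), 0.02)
  expect_gte(mc$coverage, 0.92)
  expect_lte(mc$coverage, 0.98)
})

test_that("BCa bootstrap ratio is deterministic and sane", {
  groups <- list(
    list(label = "control", mean = 0.46, sd = 0.27, n = 19,
         mean_b = 0.92, sd_b = 2.21),
    list(label = "AD", mean = 2.01, sd = 0.96, n = 37,
         mean_b = 2.37, sd_b = 2.86))
  coh <- simulate_cohort(groups, correlation = 0.5, seed = 42)
  pairs <- cohort_pairs(coh)
  b1 <- bootstrap_ratio_ci(pairs, "AD", trial_design(aging = TRUE),
                           reps = 2000, seed = 7)
  b2 <- bootstrap_ratio_ci(pairs, "AD", trial_design(aging = TRUE),
                           reps = 2000, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_lt(b1$ratio, 1)  # the lower-variance method needs fewer subjects
  # identical methods: ratio and interval collapse to 1
  pid <- pairs; pid$rate_b <- pid$rate_a
  bid <- bootstrap_ratio_ci(pid, "AD", trial_design(aging = TRUE),
                            reps = 1000, seed = 3)
  expect_equal(bid$ratio, 1)
  expect_equal(bid$ci, c(1, 1))
})

test_that("variance advantage yields a ratio CI excluding 1 in most draws", {
  wins <- 0L
  for (s in 1:10) {
    coh <- simulate_cohort(list(
      list(label = "control", mean = 0.46, sd = 0.27, n = 19,
           mean_b = 0.92, sd_b = 2.21),
      list(label = "AD", mean = 2.01, sd = 0.96, n = 37,
           mean_b = 2.37, sd_b = 2.86)),
      correlation = 0.5, seed = 100 + s)
    b <- bootstrap_ratio_ci(cohort_pairs(coh), "AD",
                            trial_design(aging = TRUE), reps = 1000,
                            seed = s)
    if (b$ratio < 1 && b$ci[2] < 1) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("adjusted group difference recovers an injected effect", {
  # identical rates: difference exactly 0
  df0 <- data.frame(g = rep(c("a", "b"), each = 10))
  r0 <- suppressWarnings(
    adjusted_group_difference(rep(1.5, 20), df0$g,
                              age = rnorm(20, 70, 5),
                              gender = rep(c("M", "F"), 10)))
  expect_equal(r0$difference, 0, tolerance = 1e-12)
  set.seed(9)
  n <- 56
  group <- rep(c("control", "AD"), c(19, 37))
  age <- rnorm(n, 69.5, 7.1)
  gender <- sample(c("M", "F"), n, TRUE)
  rates <- ifelse(group == "AD", 2.0, 0.46) + rnorm(n, 0, 0.8)
  fit <- adjusted_group_difference(rates,
                                   factor(group,
                                          levels = c("control", "AD")),
                                   age, gender)
  expect_lt(abs(fit$difference - 1.54), 2 * fit$se)
  # collinear design errors out
  expect_error(adjusted_group_difference(rates, group,
                                         age = as.numeric(group == "AD"),
                                         gender = gender), "rank")
})

test_that("simulated cohorts match their specification", {
  coh <- simulate_cohort(list(list(label = "AD", mean = 2.01, sd = 0.96,
                                   n = 10000)), seed = 1)
  expect_lt(abs(mean(coh$rate_pct_per_yr) - 2.01), 0.03)
  expect_lt(abs(sd(coh$rate_pct_per_yr) - 0.96), 0.03)
  # zero SD: all rates equal the mean
  c0 <- simulate_cohort(list(list(label = "c", mean = 0.5, sd = 0, n = 5)),
                        seed = 2)
  expect_true(all(c0$rate_pct_per_yr == 0.5))
  expect_error(simulate_cohort(list(list(label = "a", mean = 1, sd = 1,
                                         n = 5)), correlation = 1.2),
               "correlation")
  # determinism
  c1 <- simulate_cohort(list(list(label = "AD", mean = 2, sd = 1, n = 20)),
                        correlation = 0.5, seed = 11)
  c2 <- simulate_cohort(list(list(label = "AD", mean = 2, sd = 1, n = 20)),
                        correlation = 0.5, seed = 11)
  expect_identical(c1, c2)
})

test_that("closed-form sample size agrees with a simulated cohort", {
  coh <- simulate_cohort(list(
    list(label = "control", mean = 0.46, sd = 0.27, n = 4000),
    list(label = "AD", mean = 2.01, sd = 0.96, n = 8000)), seed = 3)
  pat <- coh[coh$group == "AD", ]
  ctl <- coh[coh$group == "control", ]
  est <- sample_size_per_arm(
    group_summary("AD", nrow(pat), mean(pat$rate_pct_per_yr),
                  sd(pat$rate_pct_per_yr)),
    group_summary("control", nrow(ctl), mean(ctl$rate_pct_per_yr),
                  sd(ctl$rate_pct_per_yr)),
    trial_design(aging = TRUE))
  closed <- sample_size_per_arm(group_summary("AD", 37, 2.01, 0.96),
                                group_summary("control", 19, 0.46, 0.27),
                                trial_design(aging = TRUE))
  expect_lt(abs(est$n_raw - closed$n_raw) / closed$n_raw, 0.15)
})
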