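test_that("median curve handles singleton, odd-count and simulated bins", {
  c1 <- fit_median_curve(data.frame(ga_week = 8,
                                    concentration_pg_ml = 100))
  expect_equal(curve_value(c1, 8), 100)

  c2 <- fit_median_curve(data.frame(ga_week = 9,
                                    concentration_pg_ml = c(80, 100, 120)))
  expect_equal(curve_value(c2, 9), 100)

  # ~500 unaffected samples in the week-8 bin alone
  cfg <- cohort_config(n_subjects = 2700, dropout_prob = 1, seed = 31)
  co <- generate_cohort(cfg)
  dat <- merge(co$samples, co$subjects, by = "subject_id")
  un <- dat[dat$outcome == "unaffected", ]
  curve <- fit_median_curve(un)
  expect_equal(curve_value(curve, 8),
               oracle_median(un$concentration_pg_ml[un$ga_week == 8]))
  expect_equal(curve_value(curve, 8), 119, tolerance = 0.05)
})

test_that("weeks without samples raise a lookup error naming the week", {
  curve <- fit_median_curve(data.frame(ga_week = 8,
                                       concentration_pg_ml = 100))
  expect_error(curve_value(curve, 17), "17")
  expect_equal(curve_value(curve, 17, fallback = TRUE), 100)
})

test_that("small bins merge into the nearest neighbour", {
  s <- data.frame(ga_week = c(rep(8, 10), 9, rep(16, 10)),
                  concentration_pg_ml = c(rep(100, 10), 500, rep(200, 10)))
  curve <- fit_median_curve(s, min_count = 3)
  # the lone week-9 sample joins the week-8 bin, not week 16
  expect_equal(sum(curve$n), 21)
  expect_equal(curve_value(curve, 9), curve_value(curve, 8))
  expect_equal(curve_value(curve, 16), 200)
})

test_that("MoM conversion divides by the week median and is scale-equivariant", {
  curve <- fit_median_curve(data.frame(ga_week = 8,
                                       concentration_pg_ml = 119))
  s <- data.frame(subject_id = "S1", ga_week = 8,
                  concentration_pg_ml = 42)
  expect_equal(to_mom(s, curve)$mom, 42 / 119)
  expect_equal(to_mom(transform(s, concentration_pg_ml = 119), curve)$mom,
               1.0)
  expect_error(
    to_mom(transform(s, concentration_pg_ml = -1), curve), "positive")

  # multiplying every concentration by c leaves all MoMs unchanged
  cfg <- cohort_config(n_subjects = 200, seed = 5)
  co <- generate_cohort(cfg)
  dat <- merge(co$samples, co$subjects, by = "subject_id")
  un <- dat[dat$outcome == "unaffected", ]
  m1 <- to_mom(un, fit_median_curve(un))$mom
  un2 <- transform(un, concentration_pg_ml = concentration_pg_ml * 7.3)
  m2 <- to_mom(un2, fit_median_curve(un2))$mom
  expect_equal(m1, m2)
})

test_that("null covariate effects are recovered as near-zero coefficients", {
  eff <- list(bmi = 0, age = 0, smoking = 0, parity = 0,
              ethnicity = c(0, 0, 0))
  cfg <- cohort_config(n_subjects = 800, covariate_effects = eff, seed = 6)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(fit_mom_pipeline(co$subjects, co$samples))
  bmi_term <- fit$cov_model$terms$bmi
  expect_lt(abs(bmi_term$beta), 3 * bmi_term$se)
  age_term <- fit$cov_model$terms$age
  expect_lt(abs(age_term$beta), 3 * age_term$se)
})

test_that("a known BMI effect is recovered within 25% at n = 2000", {
  eff <- list(bmi = 0.02, age = 0, smoking = 0, parity = 0,
              ethnicity = c(0, 0, 0))
  cfg <- cohort_config(n_subjects = 2000, covariate_effects = eff,
                       seed = 7)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(fit_mom_pipeline(co$subjects, co$samples))
  expect_equal(fit$cov_model$terms$bmi$beta, 0.02, tolerance = 0.25)
})

test_that("covariate adjustment recenters but does not rescale", {
  cfg <- cohort_config(n_subjects = 400, seed = 9)
  co <- generate_cohort(cfg)
  dat <- merge(co$samples, co$subjects, by = "subject_id")
  un <- dat[dat$outcome == "unaffected", ]
  un <- to_mom(un, fit_median_curve(un))
  model <- suppressWarnings(fit_covariate_adjustment(un))
  adj <- apply_covariate_adjustment(model, un)
  expect_equal(mean(log(adj$mom_cov_adj)), mean(log(adj$mom)),
               tolerance = 1e-10)
})

test_that("constant covariates yield zero coefficients with a warning", {
  co <- build_fixed_cohort(conc = c(90, 100, 110, 120, 130),
                           blood_group = "O")
  dat <- merge(co$samples, co$subjects, by = "subject_id")
  dat$trimester <- 1
  dat <- to_mom(dat, fit_median_curve(dat))
  ws <- capture_warnings(model <- fit_covariate_adjustment(dat))
  expect_true(length(ws) > 0 && all(grepl("constant", ws)))
  expect_equal(model$terms$bmi$beta, 0)
})

test_that("blood-group factors recover the generator multipliers within 10% at n = 2000", {
  cfg <- cohort_config(n_subjects = 2000, seed = 42)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(fit_mom_pipeline(co$subjects, co$samples))
  f1 <- fit$bg_factors[fit$bg_factors$trimester == 1, ]
  est <- setNames(f1$factor, f1$blood_group)
  truth <- cfg$group_serum_multipliers[, 1]
  expect_equal(unname(est[names(truth)]), unname(truth), tolerance = 0.10)
  # characteristic first-trimester ordering: B highest, AB lowest
  expect_equal(names(which.max(est)), "B")
  expect_equal(names(which.min(est)), "AB")
})

test_that("identically distributed groups give factors near 1", {
  g <- default_group_multipliers(); g[, ] <- 1
  cfg <- cohort_config(n_subjects = 1500, group_serum_multipliers = g,
                       seed = 10)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(fit_mom_pipeline(co$subjects, co$samples))
  expect_equal(fit$bg_factors$factor,
               rep(1, nrow(fit$bg_factors)), tolerance = 0.1)
})

test_that("undersized strata fall back to factor 1.0 with a warning", {
  moms <- data.frame(mom_cov_adj = c(rep(1.2, 10), 0.7),
                     blood_group = c(rep("O", 10), "AB"),
                     trimester = 1)
  ws <- capture_warnings(f <- fit_blood_group_factors(moms, min_count = 5))
  expect_true(any(grepl("AB", ws)))
  expect_equal(f$factor[f$blood_group == "AB"], 1.0)
  expect_equal(f$factor[f$blood_group == "O"], 1.2)
})

test_that("blood-group adjustment divides by the stratum factor", {
  moms <- data.frame(mom_cov_adj = c(0.58, 1.0),
                     blood_group = c("AB", "O"), trimester = 1)
  f <- suppressWarnings(
    fit_blood_group_factors(moms, min_count = 1))
  out <- adjust_for_blood_group(moms, f)
  expect_equal(out$mom_abo_adj, c(1.0, 1.0))
  expect_error(
    adjust_for_blood_group(
      data.frame(mom_cov_adj = 1, blood_group = "Z", trimester = 1), f),
    "Z")
})

test_that("after full adjustment each group's unaffected median is 1 (odd counts)", {
  set.seed(77)
  conc <- exp(log(119) + rnorm(45, 0, 0.3))
  co <- build_fixed_cohort(conc,
                           blood_group = rep(c("O", "A", "B", "AB"),
                                             c(15, 13, 10, 7)))
  fit <- suppressWarnings(
    fit_mom_pipeline(co$subjects, co$samples, min_count_group = 1))
  m <- fit$moms
  for (g in blood_groups())
    expect_equal(median(m$mom_abo_adj[m$blood_group == g]), 1.0)
})

test_that("pipeline preserves record counts", {
  cfg <- cohort_config(n_subjects = 300, seed = 13)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(fit_mom_pipeline(co$subjects, co$samples))
  expect_equal(nrow(fit$moms), nrow(co$samples))
  expect_setequal(fit$moms$subject_id, co$samples$subject_id)
})

test_that("change rate is the exact two-point slope", {
  expect_equal(change_rate(119, 212, 8, 26), 93 / 18)
  expect_equal(change_rate(5, 5, 8, 26), 0)
  expect_equal(change_rate(212, 119, 8, 26),
               -change_rate(119, 212, 8, 26))
  expect_error(change_rate(1, 2, 8, 8), "W1 = W2")
})

test_that("median_slope matches change_rate on two points and fits lines exactly", {
  two <- median_slope(c(8, 26), c(119, 212))
  expect_equal(two$slope, change_rate(119, 212, 8, 26))
  col <- median_slope(c(8, 18, 26), c(10, 30, 46))
  expect_equal(col$residuals, rep(0, 3))
  expect_error(median_slope(8, 119), "two distinct")
})

test_that("group B has the steepest median slope across trimesters", {
  cfg <- cohort_config(n_subjects = 4000, dropout_prob = 0, seed = 15)
  co <- generate_cohort(cfg)
  dat <- merge(co$samples, co$subjects, by = "subject_id")
  un <- dat[dat$outcome == "unaffected", ]
  slope_of <- function(g) {
    sub <- un[un$blood_group == g, ]
    meds <- tapply(sub$concentration_pg_ml, sub$trimester, median)
    median_slope(cfg$window_midweeks[as.integer(names(meds))],
                 as.numeric(meds))$slope
  }
  expect_gt(slope_of("B"), slope_of("A"))
  expect_gt(slope_of("B"), slope_of("O"))
})
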