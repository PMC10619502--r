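test_that("noiseless synthetic data returns the planted coefficients", {
  spec <- cohort_spec(n_young = 30, n_old = 30, slope_young = 0.3,
                      slope_old = 0.9, beta_sex = 0.5, beta_bmi = 0.1,
                      noise_sd = 1e-10, seed = 10)
  co <- generate_cohort(spec)
  m <- fit_interaction_model(co$table, "psqi", "lc_activity", "age_group",
                             c("sex", "bmi"))
  expect_equal(m$tests$estimate[m$tests$term == "interaction"], 0.6,
               tolerance = 1e-7)
  expect_equal(unname(m$coefficients["sexM", 1]), 0.5, tolerance = 1e-7)
  expect_equal(unname(m$coefficients["bmi", 1]), 0.1, tolerance = 1e-7)
})

test_that("interaction estimates are unbiased over replicates", {
  est <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_spec(n_young = 250, n_old = 250,
                                      slope_young = 0, slope_old = 0.8,
                                      seed = 1000 + s))
    m <- fit_interaction_model(co$table, "psqi", "lc_activity", "age_group",
                               c("sex", "bmi"))
    m$tests$estimate[m$tests$term == "interaction"]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), 3 * mc_se)
})

test_that("collinear covariates raise an error naming the design column", {
  co <- generate_cohort(cohort_spec(seed = 11))
  co$table$bmi_copy <- co$table$bmi
  expect_error(fit_interaction_model(co$table, "psqi", "lc_activity",
                                     "age_group", c("bmi", "bmi_copy")),
               "collinear")
  expect_error(fit_interaction_model(co$table, "psqi", "lc_activity", "sex",
                                     character(), family = "gaussian"),
               NA)
  co$table$three <- sample(c("a", "b", "c"), 52, replace = TRUE)
  expect_error(fit_interaction_model(co$table, "psqi", "lc_activity", "three"),
               "binary")
})

test_that("simple slopes are level-invariant and collapse when the interaction is zero", {
  spec <- cohort_spec(n_young = 40, n_old = 40, slope_young = 0.5,
                      slope_old = 0.5, noise_sd = 1e-10, seed = 12)
  co <- generate_cohort(spec)
  m <- fit_interaction_model(co$table, "psqi", "lc_activity", "age_group",
                             c("sex", "bmi"))
  expect_equal(simple_slopes(m, "young")$slope, simple_slopes(m, "old")$slope,
               tolerance = 1e-10)
  # relevel the moderator: per-group slopes must not move
  t2 <- generate_cohort(cohort_spec(n_young = 40, n_old = 40,
                                    slope_young = 0.1, slope_old = 0.9,
                                    seed = 13))$table
  m1 <- fit_interaction_model(t2, "psqi", "lc_activity", "age_group",
                              c("sex", "bmi"))
  t2$age_group <- relevel(t2$age_group, "old")
  m2 <- fit_interaction_model(t2, "psqi", "lc_activity", "age_group",
                              c("sex", "bmi"))
  for (g in c("young", "old")) {
    expect_equal(simple_slopes(m1, g)$slope, simple_slopes(m2, g)$slope,
                 tolerance = 1e-10)
    expect_equal(simple_slopes(m1, g)$p, simple_slopes(m2, g)$p,
                 tolerance = 1e-10)
  }
  expect_error(simple_slopes(m1, "middle"), "unknown group")
})

test_that("planted group slopes are recovered across seeds", {
  hits <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(n_young = 500, n_old = 500,
                                      slope_young = 0, slope_old = 0.5,
                                      seed = 2000 + s))
    m <- fit_interaction_model(co$table, "psqi", "lc_activity", "age_group",
                               c("sex", "bmi"))
    s_old <- simple_slopes(m, "old")$slope
    s_old >= 0.4 && s_old <= 0.6
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tested-term p-values are invariant to covariate rescaling", {
  co <- generate_cohort(cohort_spec(slope_old = 0.6, seed = 14))
  m1 <- fit_interaction_model(co$table, "psqi", "lc_activity", "age_group",
                              c("sex", "bmi", "tst"))
  t2 <- co$table
  t2$bmi <- t2$bmi * 10 - 3
  t2$tst <- t2$tst / 60 + 2
  m2 <- fit_interaction_model(t2, "psqi", "lc_activity", "age_group",
                              c("sex", "bmi", "tst"))
  expect_equal(m1$tests$p, m2$tests$p, tolerance = 1e-8)
  expect_equal(m1$tests$partial_R2, m2$tests$partial_R2, tolerance = 1e-8)
})

test_that("BH step-up matches hand-evaluated examples", {
  p <- c(0.005, 0.01, 0.03, 0.2, 0.5, 0.9)
  res <- bh_fdr(p, 0.05)
  expect_equal(res$rejected, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$critical_p, 0.01)
  res1 <- bh_fdr(rep(1, 5), 0.05)
  expect_false(any(res1$rejected))
  expect_equal(res1$critical_p, 0)
  expect_true(bh_fdr(0.04, 0.05)$rejected)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjusted p-values match stats::p.adjust", {
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(2:12, 1))
    res <- bh_fdr(p, 0.05)
    expect_equal(res$adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("Pearson correlation handles exact and simulated cases", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(2, 20)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), ">= 3")
  set.seed(16)
  rs <- vapply(1:100, function(i) {
    z <- matrix(rnorm(2 * 10000), ncol = 2)
    y <- -0.5 * z[, 1] + sqrt(1 - 0.25) * z[, 2]
    pearson_correlation(z[, 1], y)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) + 0.5), 0.02)
})

test_that("sensitivity analysis inverts its own power function", {
  s <- sensitivity_min_effect(52, alpha = 0.05, power = 0.8, sides = 1,
                              n_covariates = 4)
  pw <- lcsleep:::regression_power(s$min_detectable_r, 52, 0.05, 1, 4)
  expect_equal(pw, 0.8, tolerance = 1e-6)
  s2 <- sensitivity_min_effect(52, alpha = 0.05, power = 0.8, sides = 2,
                               n_covariates = 4)
  expect_gt(s2$min_detectable_r, s$min_detectable_r)
  # power -> alpha limit: any nonzero effect is "detectable"
  s0 <- sensitivity_min_effect(52, alpha = 0.05, power = 0.05, sides = 1,
                               n_covariates = 4)
  expect_lt(s0$min_detectable_r, 0.01)
  expect_error(sensitivity_min_effect(5, n_covariates = 4), "df")
})

test_that("the primary report carries six models and honours FDR settings", {
  co <- generate_cohort(cohort_spec(slope_old = 1.5, seed = 17))
  rep_ <- run_primary_models(co$table)
  expect_length(rep_$models, 6)
  expect_equal(nrow(rep_$summary), 6)
  expect_equal(rep_$summary$outcome[1], "psqi")
  # TST enters only the energy models
  expect_true("tst" %in% rep_$models$swe$covariates)
  expect_false("tst" %in% rep_$models$psqi$covariates)
  broken <- co$table[setdiff(names(co$table), "swe")]
  expect_error(run_primary_models(broken), "swe")
})
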