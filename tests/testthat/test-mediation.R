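old_cohort <- function(..., n_old = 400) {
  spec <- cohort_spec(n_young = 2, n_old = n_old, ..., seed = 20)
  subset(generate_cohort(spec)$table, age_group == "old")
}

test_that("a null mediator path gives a PIE compatible with zero", {
  d <- old_cohort(a = 0, b = 0.5, c_prime = 0.7)
  md <- mediation_analysis(d, "psqi", "lc_activity", "rem_theta_energy",
                           c("sex", "bmi"), n_boot = 400, seed = 21,
                           transform = "sqrt", interaction = FALSE)
  pie_row <- md$percent[md$percent$effect == "PIE%", ]
  expect_true(pie_row$ci_lo <= 0 && 0 <= pie_row$ci_hi)
  expect_lt(abs(pie_row$estimate), 15)
})

test_that("without interaction the PIE is the product of coefficients", {
  d <- old_cohort(a = 0.5, b = 0.4, c_prime = 0.3)
  md <- mediation_analysis(d, "psqi", "lc_activity", "rem_theta_energy",
                           c("sex", "bmi"), n_boot = 200, seed = 22,
                           transform = "sqrt", interaction = FALSE)
  ab <- md$effects[["a"]] * md$effects[["b"]] * (md$x1 - md$x0)
  expect_equal(md$effects[["PIE"]], ab, tolerance = 1e-6)
  expect_equal(md$effects[["TE"]],
               md$effects[["CDE"]] + md$effects[["PIE"]], tolerance = 1e-6)
})

test_that("planted full mediation decomposes to ~100% indirect", {
  d <- old_cohort(a = 1, b = 0.8, c_prime = 0, n_old = 2000)
  md <- mediation_analysis(d, "psqi", "lc_activity", "rem_theta_energy",
                           c("sex", "bmi"), n_boot = 200, seed = 23,
                           transform = "sqrt")
  pie <- md$percent$estimate[md$percent$effect == "PIE%"]
  cde <- md$percent$estimate[md$percent$effect == "CDE%"]
  expect_gt(pie, 90); expect_lt(pie, 110)
  expect_gt(cde, -10); expect_lt(cde, 10)
})

test_that("guard rails: bootstrap size, variance, stability, transform", {
  d <- old_cohort(a = 0.4, b = 0.4)
  expect_error(mediation_analysis(d, "psqi", "lc_activity", "rem_theta_energy",
                                  n_boot = 100, seed = 1), ">= 200")
  expect_error(mediation_analysis(d, "psqi", "lc_activity", "rem_theta_energy",
                                  n_boot = 200), "seed")
  d$flat <- 1
  expect_error(mediation_analysis(d, "psqi", "lc_activity", "flat",
                                  n_boot = 200, seed = 1), "variance")
  d$negm <- -abs(rnorm(nrow(d)))
  expect_error(mediation_analysis(d, "psqi", "lc_activity", "negm",
                                  n_boot = 200, seed = 1, transform = "sqrt"),
               "nonnegative")
  # a null total effect is flagged unstable rather than silently reported
  set.seed(24)
  d0 <- data.frame(y = rnorm(300), x = rnorm(300), m = rnorm(300))
  expect_warning(md <- mediation_analysis(d0, "y", "x", "m", n_boot = 200,
                                          seed = 25, x0 = 0, x1 = 0),
                 "unstable")
  expect_true(md$unstable)
})

test_that("the sqrt transform analyzes the mediator on its generating scale", {
  d <- old_cohort(a = 0.5, b = 0.4, c_prime = 0.2)
  raw <- mediation_analysis(d, "psqi", "lc_activity", "rem_theta_energy",
                            c("sex", "bmi"), n_boot = 200, seed = 26,
                            transform = "none", interaction = FALSE)
  sq <- mediation_analysis(d, "psqi", "lc_activity", "rem_theta_energy",
                           c("sex", "bmi"), n_boot = 200, seed = 26,
                           transform = "sqrt", interaction = FALSE)
  # the sqrt-scale a path matches the planted coefficient; the raw-scale
  # path is on the squared scale and roughly 2*m0 larger
  expect_equal(sq$effects[["a"]], 0.5, tolerance = 0.15)
  expect_gt(raw$effects[["a"]] / sq$effects[["a"]], 30)
})
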