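#' Specification of a synthetic two-group cohort
#'
#' Describes a cross-sectional cohort of younger and older participants
#' with an LC-activity-by-age-group interaction planted on the PSQI-like
#' subjective sleep quality score, and a mediation structure in which REM
#' theta energy (through its square root) can mediate the LC activity ->
#' sleep quality association. Default group sizes match the study design
#' the package emulates (33 younger, 19 older); all planted effects
#' default to zero.
#'
#' The mediator path `a` (LC activity -> sqrt REM theta) is applied in the
#' older group only: this both plants the group-specific interaction on
#' REM theta energy and mirrors a mediation confined to the older
#' subsample. The mediator is generated on the square-root scale and
#' returned squared, so downstream square-root transforms are exercised.
#'
#' @param n_young,n_old group sizes (positive).
#' @param slope_young,slope_old direct regression slopes of the outcome on
#'   LC activity per age group (on top of `c_prime`).
#' @param c_prime direct LC-activity effect common to both groups.
#' @param a exposure -> mediator path (older group; sqrt-theta units per
#'   unit LC activity).
#' @param b mediator -> outcome path (per unit sqrt-theta).
#' @param gamma exposure-by-mediator interaction on the outcome.
#' @param beta_sex,beta_bmi,beta_tst covariate effects on the outcome.
#' @param beta_group additive older-group shift of the outcome.
#' @param noise_sd residual SD of outcome and mediator (> 0).
#' @param seed integer seed (part of the spec: the generator is a pure
#'   function of the spec).
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 33L, n_old = 19L,
                        slope_young = 0, slope_old = 0, c_prime = 0,
                        a = 0, b = 0, gamma = 0,
                        beta_sex = 0.5, beta_bmi = 0.1, beta_tst = 0,
                        beta_group = 1, noise_sd = 1, seed = 1L) {
  if (n_young <= 0 || n_old <= 0) {
    stop_fmt("cohort_spec: group sizes must be positive")
  }
  if (!is_scalar_num(noise_sd) || noise_sd <= 0) {
    stop_fmt("cohort_spec: noise_sd must be > 0")
  }
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 slope_young = slope_young, slope_old = slope_old,
                 c_prime = c_prime, a = a, b = b, gamma = gamma,
                 beta_sex = beta_sex, beta_bmi = beta_bmi,
                 beta_tst = beta_tst, beta_group = beta_group,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table with known ground truth
#'
#' One row per participant. LC activity is standard normal; sex, BMI and
#' TST follow plausible group-specific distributions (73–85% women, BMI
#' within the screening bounds, TST around 7 h). The mediator scale
#' (sqrt of REM theta energy) is `m0 + a * lc_activity * I(old) + noise`;
#' REM theta energy is its square. The outcome (PSQI-like score, kept
#' continuous so noiseless recovery is exact) is
#'
#' `psqi = p0 + beta_group I(old) + (c_prime + slope_g) X + b (M - m0)
#'        + gamma X (M - m0) + beta_sex I(male) + beta_bmi (BMI - 24)
#'        + beta_tst (TST - 420) + noise`
#'
#' Other sleep outcomes (SOL, efficiency, REM%, SWE, REM latency, REM
#' arousals) carry no planted LC-activity effect.
#'
#' @param spec a [cohort_spec()]; its `seed` drives all randomness.
#' @return list with `table` (data frame) and `truth` (every generating
#'   coefficient plus `m0`, `p0`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_young + spec$n_old
  m0 <- 30
  p0 <- 5
  with_seed(spec$seed, {
    age_group <- factor(rep(c("young", "old"), c(spec$n_young, spec$n_old)),
                        levels = c("young", "old"))
    old <- as.numeric(age_group == "old")
    # ~80% women in both groups, matching the study's sex imbalance
    sex <- factor(ifelse(runif(n) < 0.8, "F", "M"), levels = c("F", "M"))
    bmi <- ifelse(old == 1, rnorm(n, 24.5, 2.0), rnorm(n, 22.5, 1.8))
    bmi <- pmin(pmax(bmi, 18.5), 30)
    tst <- rnorm(n, 420, 35)
    lc_activity <- rnorm(n)
    # older group tends to higher LC contrast in this 50-70 y range
    lc_contrast <- rnorm(n, 0.15 + 0.02 * old, 0.03)
    sqrt_theta <- m0 + spec$a * lc_activity * old + rnorm(n, sd = spec$noise_sd)
    slope <- spec$c_prime + ifelse(old == 1, spec$slope_old, spec$slope_young)
    psqi <- p0 + spec$beta_group * old + slope * lc_activity +
      spec$b * (sqrt_theta - m0) +
      spec$gamma * lc_activity * (sqrt_theta - m0) +
      spec$beta_sex * as.numeric(sex == "M") +
      spec$beta_bmi * (bmi - 24) +
      spec$beta_tst * (tst - 420) +
      rnorm(n, sd = spec$noise_sd)
    table <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      age_group = age_group, sex = sex, bmi = bmi, tst = tst,
      lc_activity = lc_activity, lc_contrast = lc_contrast,
      psqi = psqi,
      sol = pmax(rnorm(n, 18, 8), 1),
      sleep_efficiency = pmin(rnorm(n, 88 - 4 * old, 5), 100),
      rem_percentage = pmax(rnorm(n, 20, 4), 5),
      swe = pmax(rnorm(n, 5000 - 1200 * old, 1200), 500),
      rem_theta_energy = sqrt_theta^2,
      rem_latency = pmax(rnorm(n, 80, 25), 20),
      rem_arousals = rpois(n, 5)
    )
    truth <- list(m0 = m0, p0 = p0,
                  slope_young = spec$c_prime + spec$slope_young,
                  slope_old = spec$c_prime + spec$slope_old,
                  interaction = spec$slope_old - spec$slope_young,
                  a = spec$a, b = spec$b, c_prime = spec$c_prime,
                  gamma = spec$gamma,
                  beta_sex = spec$beta_sex, beta_bmi = spec$beta_bmi,
                  beta_tst = spec$beta_tst, beta_group = spec$beta_group,
                  noise_sd = spec$noise_sd)
    list(table = table, truth = truth)
  })
}
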