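#' Moderated regression with per-group simple slopes and partial R²
#'
#' Fits `outcome ~ predictor + moderator + predictor:moderator +
#' covariates` with a binary moderator. The moderator is internally coded
#' -1/2, +1/2 (first, second factor level), so the predictor main effect
#' is the groups' average slope and the interaction coefficient is the
#' slope difference; per-group simple slopes are linear contrasts of the
#' fit and are invariant to which level is the reference. Each tested
#' term's F statistic (t² for 1-df terms) is converted to a partial R²
#' via `F·df1 / (F·df1 + df2)`.
#'
#' The cross-sectional design has one observation per participant, so a
#' participant random intercept is not identifiable (it is confounded with
#' the residual); the model is a fixed-effects lm/glm.
#'
#' @param table cohort data frame.
#' @param outcome,predictor,moderator column names; the moderator must
#'   have exactly two levels.
#' @param covariates character vector of covariate column names.
#' @param family `"gaussian"` (identity-link lm, default) or
#'   `"gamma-log"` (log-link Gamma glm for right-skewed positive
#'   outcomes).
#' @return an `lc_model_result`: coefficient table, per-term tests with
#'   partial R², per-group simple slopes, `n`, `family`, and the
#'   underlying fit.
#' @export
fit_interaction_model <- function(table, outcome, predictor, moderator,
                                  covariates = character(),
                                  family = c("gaussian", "gamma-log")) {
  family <- match.arg(family)
  needed <- c(outcome, predictor, moderator, covariates)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop_fmt("fit_interaction_model: missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  dat <- table[stats::complete.cases(table[needed]), needed, drop = FALSE]
  if (nrow(dat) < 10L) {
    stop_fmt("fit_interaction_model: need >= 10 complete rows, got %d", nrow(dat))
  }
  mod <- dat[[moderator]]
  if (!is.factor(mod)) mod <- factor(mod)
  if (nlevels(droplevels(mod)) != 2L) {
    stop_fmt("fit_interaction_model: moderator `%s` must be binary", moderator)
  }
  mod <- droplevels(mod)
  levels_ <- levels(mod)
  dat$.mod <- ifelse(mod == levels_[2], 0.5, -0.5)
  dat$.x <- dat[[predictor]]
  rhs <- c(".x", ".mod", ".x:.mod", covariates)
  fml <- stats::reformulate(rhs, response = outcome)
  # collinearity check on the design
  mm <- stats::model.matrix(fml, dat)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop_fmt("fit_interaction_model: perfectly collinear column(s): %s",
             paste(aliased, collapse = ", "))
  }
  fit <- if (family == "gaussian") {
    stats::lm(fml, data = dat)
  } else {
    stats::glm(fml, data = dat, family = stats::Gamma(link = "log"))
  }
  cf <- summary(fit)$coefficients
  df2 <- stats::df.residual(fit)
  term_names <- c(predictor = ".x", moderator = ".mod", interaction = ".x:.mod")
  tests <- do.call(rbind, lapply(names(term_names), function(lbl) {
    row <- cf[term_names[[lbl]], ]
    Fval <- unname(row[3])^2
    data.frame(term = lbl, estimate = unname(row[1]), se = unname(row[2]),
               F = Fval, df1 = 1, df2 = df2,
               p = unname(row[4]),
               partial_R2 = Fval / (Fval + df2))
  }))
  V <- stats::vcov(fit)
  b <- stats::coef(fit)
  slope_for <- function(code) {
    ct <- setNames(numeric(length(b)), names(b))
    ct[".x"] <- 1
    ct[".x:.mod"] <- code
    est <- sum(ct * b)
    se <- sqrt(drop(t(ct) %*% V %*% ct))
    tval <- est / se
    data.frame(slope = est, se = se, t = tval,
               p = 2 * stats::pt(-abs(tval), df2))
  }
  slopes <- rbind(slope_for(-0.5), slope_for(0.5))
  slopes <- cbind(group = levels_, slopes)
  rownames(tests) <- rownames(slopes) <- NULL
  structure(list(outcome = outcome, predictor = predictor,
                 moderator = moderator, moderator_levels = levels_,
                 covariates = covariates, family = family,
                 coefficients = cf, tests = tests, slopes = slopes,
                 n = nrow(dat), fit = fit),
            class = "lc_model_result")
}

#' @export
print.lc_model_result <- function(x, ...) {
  cat(sprintf("<lc_model_result> %s ~ %s * %s (+ %s), family %s, n = %d\n",
              x$outcome, x$predictor, x$moderator,
              if (length(x$covariates)) paste(x$covariates, collapse = " + ") else "none",
              x$family, x$n))
  print(x$tests, digits = 4)
  cat("simple slopes:\n")
  print(x$slopes, digits = 4)
  invisible(x)
}

#' Per-group simple slope from a moderated model
#'
#' @param model an `lc_model_result` from [fit_interaction_model()].
#' @param group a level of the model's moderator.
#' @return one-row data frame with `slope`, `se`, `t`, `p`.
#' @export
simple_slopes <- function(model, group) {
  stopifnot(inherits(model, "lc_model_result"))
  if (!group %in% model$moderator_levels) {
    stop_fmt("simple_slopes: unknown group level '%s' (have: %s)", group,
             paste(model$moderator_levels, collapse = ", "))
  }
  model$slopes[model$slopes$group == group, , drop = FALSE]
}

PRIMARY_OUTCOMES <- c("psqi", "sol", "sleep_efficiency", "rem_percentage",
                      "swe", "rem_theta_energy")
ENERGY_OUTCOMES <- c("swe", "rem_theta_energy")

#' Run the six primary moderated models with FDR correction
#'
#' Fits the six primary interaction models — subjective sleep quality
#' (PSQI), sleep onset latency, sleep efficiency, REM percentage, SWE and
#' REM theta energy, each regressed on LC activity moderated by age group
#' with sex and BMI as covariates (plus TST for the two cumulative energy
#' outcomes) — collects the interaction p-values and applies
#' Benjamini-Hochberg FDR across the six.
#'
#' @param table cohort data frame with the documented column names.
#' @param predictor predictor column (default `"lc_activity"`).
#' @param q FDR level (default 0.05).
#' @param family model family passed to [fit_interaction_model()].
#' @param fdr_on which p-value family enters the FDR step:
#'   `"interaction"` (default) or `"predictor"` main effects.
#' @return an `lc_primary_report`: per-model results, the FDR summary
#'   table, and the [bh_fdr()] output.
#' @export
run_primary_models <- function(table, predictor = "lc_activity", q = 0.05,
                               family = "gaussian",
                               fdr_on = c("interaction", "predictor")) {
  fdr_on <- match.arg(fdr_on)
  missing_cols <- setdiff(c(PRIMARY_OUTCOMES, predictor, "age_group", "sex", "bmi", "tst"),
                          names(table))
  if (length(missing_cols)) {
    stop_fmt("run_primary_models: missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  models <- lapply(PRIMARY_OUTCOMES, function(out) {
    covs <- c("sex", "bmi", if (out %in% ENERGY_OUTCOMES) "tst")
    fit_interaction_model(table, out, predictor, "age_group", covs,
                          family = family)
  })
  names(models) <- PRIMARY_OUTCOMES
  pvals <- vapply(models, function(m) m$tests$p[m$tests$term == fdr_on],
                  numeric(1))
  fdr <- bh_fdr(pvals, q)
  summary_df <- data.frame(outcome = PRIMARY_OUTCOMES,
                           p = unname(pvals),
                           p_adjusted = fdr$adjusted,
                           rejected = fdr$rejected)
  structure(list(models = models, summary = summary_df, fdr = fdr,
                 q = q, fdr_on = fdr_on, family = family),
            class = "lc_primary_report")
}

#' @export
print.lc_primary_report <- function(x, ...) {
  cat(sprintf("<lc_primary_report> 6 models, FDR on %s p-values at q = %g (critical p = %.4g)\n",
              x$fdr_on, x$q, x$fdr$critical_p))
  print(x$summary, digits = 4)
  invisible(x)
}
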