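# Counterfactual effect decomposition from fitted mediator and outcome
# linear models, for an exposure contrast x0 -> x1 and CDE reference m*.
#   mediator: E[M|x,c] = b0 + b1 x + b2'c
#   outcome:  E[Y|x,m,c] = t0 + t1 x + t2 m + t3 x m + t4'c
#   CDE(m*) = (t1 + t3 m*) (x1 - x0)
#   PNDE    = (t1 + t3 (b0 + b1 x0 + b2'cbar)) (x1 - x0)
#   TNIE    = (t2 + t3 x1) b1 (x1 - x0)
#   PIE     = (t2 + t3 x0) b1 (x1 - x0)
#   TE      = PNDE + TNIE
mediation_point <- function(dat, outcome, exposure, mediator, covariates,
                            x0, x1, interaction) {
  m_fml <- stats::reformulate(c(exposure, covariates), response = mediator)
  y_rhs <- c(exposure, mediator,
             if (interaction) paste0(exposure, ":", mediator), covariates)
  y_fml <- stats::reformulate(y_rhs, response = outcome)
  m_fit <- stats::lm(m_fml, data = dat)
  y_fit <- stats::lm(y_fml, data = dat)
  bm <- stats::coef(m_fit)
  by <- stats::coef(y_fit)
  b1 <- bm[[exposure]]
  t1 <- by[[exposure]]
  t2 <- by[[mediator]]
  t3 <- if (interaction) {
    nm <- intersect(c(paste0(exposure, ":", mediator),
                      paste0(mediator, ":", exposure)), names(by))
    by[[nm[1]]]
  } else 0
  # covariate-adjusted mediator mean at x0: with a linear mediator model
  # and intercept, mean prediction at exposure = x0 and observed
  # covariates is mean(M) shifted along the exposure slope
  m_star <- mean(dat[[mediator]])
  m_at_x0 <- m_star + b1 * (x0 - mean(dat[[exposure]]))
  d <- x1 - x0
  cde <- (t1 + t3 * m_star) * d
  pnde <- (t1 + t3 * m_at_x0) * d
  tnie <- (t2 + t3 * x1) * b1 * d
  pie <- (t2 + t3 * x0) * b1 * d
  te <- pnde + tnie
  c(CDE = cde, PNDE = pnde, TNIE = tnie, PIE = pie, TE = te,
    a = b1, b = t2, m_star = m_star)
}

#' Counterfactual mediation analysis with bootstrap intervals
#'
#' Linear-model mediation in the counterfactual framework: a mediator
#' model `M ~ X + C` and an outcome model `Y ~ X + M + X:M + C` (the
#' exposure-by-mediator interaction can be dropped). Reports the
#' controlled direct effect — evaluated at the covariate-adjusted
#' mediator mean — and the pure (natural) indirect effect, each as a
#' percentage of the total effect, with nonparametric case-resampling
#' percentile bootstrap SE, CI and p-values. Without interaction the pure
#' indirect effect reduces to the product of coefficients a·b times the
#' exposure contrast.
#'
#' @param table data frame of complete cases (rows with missing values in
#'   the used columns are dropped; >= 10 must remain).
#' @param outcome,exposure,mediator,covariates column names.
#' @param n_boot bootstrap replicates (>= 200).
#' @param seed integer seed for the bootstrap (mandatory).
#' @param transform optional mediator transform: `"none"` or `"sqrt"`
#'   (cumulative energy mediators are analyzed on the square-root scale
#'   to meet the linear-model assumptions).
#' @param interaction include the exposure-by-mediator interaction in the
#'   outcome model (default TRUE).
#' @param x0,x1 exposure contrast; defaults to mean and mean + 1 SD of
#'   the observed exposure. Percentages are invariant to the contrast
#'   width when there is no interaction.
#' @return a `mediation_result` with `effects` (point estimates),
#'   `percent` (CDE%% and PIE%% of total effect with bootstrap SE/CI/p),
#'   `total_effect`, `unstable` flag (total effect near zero), `n_boot`,
#'   `seed`.
#' @export
mediation_analysis <- function(table, outcome, exposure, mediator,
                               covariates = character(), n_boot = 1000L,
                               seed, transform = c("none", "sqrt"),
                               interaction = TRUE, x0 = NULL, x1 = NULL) {
  transform <- match.arg(transform)
  if (missing(seed)) stop_fmt("mediation_analysis: `seed` is mandatory")
  if (n_boot < 200L) stop_fmt("mediation_analysis: n_boot must be >= 200")
  cols <- c(outcome, exposure, mediator, covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop_fmt("mediation_analysis: missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  dat <- table[stats::complete.cases(table[cols]), cols, drop = FALSE]
  if (nrow(dat) < 10L) {
    stop_fmt("mediation_analysis: need >= 10 complete cases, got %d", nrow(dat))
  }
  if (transform == "sqrt") {
    if (any(dat[[mediator]] < 0)) {
      stop_fmt("mediation_analysis: sqrt transform needs a nonnegative mediator")
    }
    dat[[mediator]] <- sqrt(dat[[mediator]])
  }
  # dummy-encode factor/character covariates once, so bootstrap resamples
  # that happen to use a single level degrade to a rank-deficient (NA)
  # dummy coefficient instead of erroring inside lm
  if (length(covariates)) {
    is_cat <- vapply(dat[covariates], function(v) is.factor(v) || is.character(v),
                     logical(1))
    if (any(is_cat)) {
      mm <- stats::model.matrix(stats::reformulate(covariates), dat)[, -1, drop = FALSE]
      colnames(mm) <- make.names(colnames(mm))
      dat <- cbind(dat[c(outcome, exposure, mediator)], as.data.frame(mm))
      covariates <- colnames(mm)
    }
  }
  if (stats::sd(dat[[mediator]]) < 1e-12) {
    stop_fmt("mediation_analysis: mediator `%s` has (near) zero variance", mediator)
  }
  x0 <- x0 %||% mean(dat[[exposure]])
  x1 <- x1 %||% (x0 + stats::sd(dat[[exposure]]))
  est <- mediation_point(dat, outcome, exposure, mediator, covariates,
                         x0, x1, interaction)
  te <- est[["TE"]]
  unstable <- abs(te) < 1e-8 * max(1, stats::sd(dat[[outcome]]))
  if (unstable) {
    warn_fmt("mediation_analysis: total effect ~ 0; percentages of total effect are unstable")
  }
  n <- nrow(dat)
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mediation_point(dat[idx, , drop = FALSE], outcome, exposure, mediator,
                      covariates, x0, x1, interaction)
    }, numeric(length(est))))
  })
  pct <- function(effect) 100 * effect / te
  boot_p <- function(v) {
    # two-sided percentile bootstrap p for H0: effect = 0
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  }
  summarize <- function(name) {
    point <- pct(est[[name]])
    bv <- 100 * boot[, name] / boot[, "TE"]
    bv <- bv[is.finite(bv)]   # degenerate (near-zero TE) resamples dropped
    if (length(bv) < 2L) {
      return(data.frame(effect = paste0(name, "%"), estimate = point,
                        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = boot_p(boot[, name])))
    }
    data.frame(effect = paste0(name, "%"), estimate = point,
               se = stats::sd(bv),
               ci_lo = unname(stats::quantile(bv, 0.025)),
               ci_hi = unname(stats::quantile(bv, 0.975)),
               p = boot_p(boot[, name]))
  }
  percent <- rbind(summarize("CDE"), summarize("PIE"))
  rownames(percent) <- NULL
  structure(list(effects = est, percent = percent, total_effect = te,
                 unstable = unstable, n = n, n_boot = n_boot, seed = seed,
                 transform = transform, interaction = interaction,
                 x0 = x0, x1 = x1),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, %d bootstraps, total effect = %.4g%s\n",
              x$n, x$n_boot, x$total_effect,
              if (x$unstable) " (UNSTABLE: near-zero total effect)" else ""))
  print(x$percent, digits = 4)
  invisible(x)
}
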