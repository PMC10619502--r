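#' Benjamini-Hochberg step-up FDR procedure
#'
#' Standard step-up rule: with ordered p-values p(1) <= ... <= p(m),
#' find the largest k with p(k) <= k·q/m and reject the k smallest; the
#' critical p is p(k) (0 when nothing is rejected). Adjusted p-values are
#' the usual monotone `min(m·p(k)/k)` over ranks >= k.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @param q FDR level in (0, 1).
#' @return list with `rejected` (logical, input order), `critical_p`,
#'   `adjusted` (input order) and `q`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) stop_fmt("bh_fdr: empty p-value list")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_fmt("bh_fdr: p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop_fmt("bh_fdr: q must lie in (0, 1)")
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  thresh <- seq_len(m) * q / m
  k <- max(c(0L, which(ps <= thresh)))
  critical_p <- if (k == 0L) 0 else ps[k]
  rejected_sorted <- seq_len(m) <= k
  adj_sorted <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  rejected <- adjusted <- vector(length = m)
  rejected[ord] <- rejected_sorted
  adjusted[ord] <- adj_sorted
  list(rejected = as.logical(rejected), critical_p = critical_p,
       adjusted = as.numeric(adjusted), q = q)
}

#' Pearson correlation with a two-sided t test
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_fmt("pearson_correlation: need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_fmt("pearson_correlation: zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Power of the t test of one predictor in multiple regression at partial
# correlation r, sample size n, residual df = n - n_covariates - 2,
# noncentrality sqrt(n) * f where f^2 = r^2 / (1 - r^2) (the G*Power
# convention for a single tested predictor).
regression_power <- function(r, n, alpha, sides, n_covariates) {
  df <- n - n_covariates - 2
  ncp <- sqrt(n * r^2 / (1 - r^2))
  if (sides == 1) {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(crit, df, ncp = ncp)) + stats::pt(-crit, df, ncp = ncp)
  }
}

#' Minimum detectable effect size for one predictor in multiple regression
#'
#' Analytic sensitivity analysis: numerically inverts the noncentral-t
#' power function of the test of a single predictor in a linear multiple
#' regression (df = n - n_covariates - 2) to find the smallest absolute
#' partial correlation reaching the target power at level `alpha`.
#'
#' @param n total sample size.
#' @param alpha type-I error rate.
#' @param power target power.
#' @param sides 1 (one-tailed) or 2.
#' @param n_covariates number of covariates beside the tested predictor.
#' @return a `sensitivity_result` with `min_detectable_r`,
#'   `min_detectable_R2` (= r²) and the achieved power at the solution.
#' @export
sensitivity_min_effect <- function(n, alpha = 0.05, power = 0.8, sides = 1,
                                   n_covariates = 4) {
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1)) {
    stop_fmt("sensitivity_min_effect: alpha and power must lie in (0, 1)")
  }
  if (!sides %in% c(1, 2)) stop_fmt("sensitivity_min_effect: sides must be 1 or 2")
  df <- n - n_covariates - 2
  if (df <= 0) stop_fmt("sensitivity_min_effect: residual df = %d <= 0", df)
  if (power <= regression_power(1e-12, n, alpha, sides, n_covariates)) {
    r <- 0
  } else {
    r <- stats::uniroot(function(r) regression_power(r, n, alpha, sides, n_covariates) - power,
                        interval = c(1e-12, 1 - 1e-9), tol = 1e-12)$root
  }
  structure(list(n = n, alpha = alpha, power = power, sides = sides,
                 n_covariates = n_covariates,
                 min_detectable_r = r, min_detectable_R2 = r^2,
                 achieved_power = regression_power(max(r, 1e-12), n, alpha,
                                                   sides, n_covariates)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> n = %d, alpha = %g (%d-sided), power = %g, %d covariates\n  min |r| = %.4f  (R^2 = %.4f)\n",
              x$n, x$alpha, x$sides, x$power, x$n_covariates,
              x$min_detectable_r, x$min_detectable_R2))
  invisible(x)
}
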