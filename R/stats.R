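#' Normalise the in-light cross section to the dark reference
#'
#' `sigma_PSII' / sigma_PSII(dark)`, each record divided by its own
#' experiment's single dark-adapted reference fit.
#'
#' @param table an `experiment_table` from [pair_measurements()]
#' @return numeric vector, one value per record
#' @export
normalise_sigma <- function(table) {
  sref <- table$dark_reference$induction$sigma_hat
  if (!is.finite(sref) || sref <= 0)
    frrf_stop("frrf_division_degenerate", "dark reference sigma is not positive")
  table$records$sigma_p / sref
}

#' Ordinary least-squares regression of one series on another
#'
#' Closed-form simple linear regression: `slope = cov(x, y) / var(x)`,
#' `intercept = mean(y) - slope * mean(x)`, with the two-sided p-value of
#' the slope from its t statistic on `n - 2` degrees of freedom. Used for
#' the cross-measurement relationships (normalised sigma_PSII' vs Y(NPQ);
#' Y(PSII) vs tau1).
#'
#' @param x,y numeric vectors of equal length >= 3; non-finite pairs are
#'   dropped
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `slope_se`, `n`
#' @export
regress <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n)
    frrf_stop("frrf_invalid_argument", "regress needs >= 3 finite (x, y) pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    frrf_stop("frrf_degenerate_x", "x is constant: slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  se <- sqrt(ss_res / (n - 2) / sxx)
  tval <- if (se > 0) slope / se else Inf
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, slope_se = se, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope=%.4g intercept=%.4g R^2=%.3f p=%.3g n=%d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Pooled photoacclimation regressions over experiment tables
#'
#' Pools the records of one or more experiments (retaining a grouping
#' label so per-strain fits remain possible) and computes the two
#' cross-measurement regressions: normalised sigma_PSII' on Y(NPQ), and
#' Y(PSII) on tau1 (in-light).
#'
#' @param tables a single `experiment_table` or a list of them
#' @return list with `sigma_vs_npq` and `ypsii_vs_tau1`
#'   ([regress()] results) and `data` (the pooled data.frame)
#' @export
acclimation_regressions <- function(tables) {
  if (inherits(tables, "experiment_table")) tables <- list(tables)
  pooled <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(group = tb$strain_label,
               sigma_norm = normalise_sigma(tb),
               Y_NPQ = tb$records$Y_NPQ, Y_PSII = tb$records$Y_PSII,
               tau1_light = tb$records$tau1_light)
  }))
  list(sigma_vs_npq = regress(pooled$Y_NPQ, pooled$sigma_norm),
       ypsii_vs_tau1 = regress(pooled$tau1_light, pooled$Y_PSII),
       data = pooled)
}
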