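#' Fit control settings
#'
#' @param rel_tol relative tolerance on the residual-sum-of-squares change
#' @param max_iter maximum optimizer iterations
#' @param rho_max upper bound on fitted connectivity (guards the known
#'   sigma-rho ridge on noisy high-light transients)
#' @param sigma_factor upper bound on fitted sigma as a multiple of its
#'   half-rise initialization
#' @return a list of class `frrf_fit_control`
#' @export
fit_control <- function(rel_tol = 1e-10, max_iter = 500, rho_max = 0.8,
                        sigma_factor = 10) {
  structure(list(rel_tol = rel_tol, max_iter = max_iter, rho_max = rho_max,
                 sigma_factor = sigma_factor),
            class = "frrf_fit_control")
}

# Bounded least squares via PORT (nlminb) on the residual sum of squares,
# over one or more deterministic starts; keeps the lowest-rss solution.
ls_minimize <- function(starts, lower, upper, rss_fn, control) {
  best <- NULL
  for (p0 in if (is.list(starts)) starts else list(starts)) {
    fit <- stats::nlminb(pmin(pmax(p0, lower), upper), rss_fn,
                         lower = lower, upper = upper,
                         control = list(iter.max = control$max_iter,
                                        eval.max = 4 * control$max_iter,
                                        rel.tol = control$rel_tol,
                                        abs.tol = 0,
                                        x.tol = 1.5e-12))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  list(par = best$par, rss = best$objective,
       converged = best$convergence == 0 ||
         grepl("converge", best$message, ignore.case = TRUE),
       iterations = best$iterations)
}

#' Fit the single-turnover induction model
#'
#' Estimates `(F0, FM, sigma, rho)` by bounded nonlinear least squares on
#' a measured flashlet-train induction, with the forward model of
#' [simulate_induction()]. Initialization is fixed and documented:
#' `F0^0` = mean of the first two points, `FM^0` = maximum, `sigma^0`
#' from the flashlet index at which the rise reaches half amplitude
#' (`log(2) / (k_half * dose)`), `rho^0 = 0.3`; a second deterministic
#' start at `rho^0 = 0` guards the sigma-rho ridge. Bounds:
#' `rho` in `[0, rho_max]`, `sigma` in `(0, sigma_factor * sigma^0]`.
#'
#' Transients measured under actinic light start from a nonzero closed
#' fraction, where `(F0, rho, C_init)` lie on a near-flat likelihood
#' ridge. Two restricted variants support such fits (used by
#' [pair_measurements()], which fixes `rho` from the paired 1-s-dark fit
#' and `C_init` from the steady-state fluorescence): supplying `rho_fix`
#' removes `rho` from the free parameters, and `C_init` sets the closure
#' at which the model recursion starts. `FS_hat` always reports the
#' fitted fluorescence at the start of the train (the `F0`-analog of an
#' in-light curve, i.e. `FS`); it equals `F0_hat` when `C_init = 0`.
#'
#' A transient whose rise has not plateaued (high actinic light can
#' suppress the remaining variable fluorescence to small values) is
#' returned with `converged = FALSE` and flag `"non_saturating"` rather
#' than raising; a constant trace raises a `frrf_degenerate_input` error.
#'
#' @param transient an induction-phase [frrf_transient()]
#' @param train the [flashlet_train()] used for the measurement
#' @param control a [fit_control()]
#' @param rho_fix optional fixed connectivity (removes `rho` from the fit)
#' @param C_init closed fraction at the start of the train (default 0)
#' @return an object of class `induction_fit`: `F0_hat`, `FM_hat`,
#'   `sigma_hat`, `rho_hat`, `FS_hat`, `C_init`, `C_end` (model closure
#'   after the last flashlet), `rss`, `rss0` (at initialization),
#'   `converged`, `n_points`, `flags`
#' @export
fit_induction <- function(transient, train, control = fit_control(),
                          rho_fix = NULL, C_init = 0) {
  if (transient$phase != "induction")
    frrf_stop("frrf_invalid_argument", "fit_induction requires an induction-phase transient")
  stopifnot_scalar(C_init, "C_init", lower = 0, upper = 1, strict_upper = TRUE)
  y <- transient$fluorescence
  n <- length(y)
  if (n < 8L)
    frrf_stop("frrf_invalid_argument", "induction fit requires >= 8 points")
  amp <- max(y) - min(y)
  if (amp <= 0 || amp < 1e-9 * max(abs(y)))
    frrf_stop("frrf_degenerate_input", "constant fluorescence trace: no variable fluorescence")

  flags <- character(0)
  # saturation check: the last quartile must sit near the maximum, and its
  # slope must not be both statistically and practically positive (plain
  # tail differences are too noise-sensitive at small variable amplitude)
  tail_idx <- seq.int(ceiling(3 * n / 4), n)
  m <- length(tail_idx)
  sl <- stats::cov(tail_idx, y[tail_idx]) / stats::var(tail_idx)
  resid_sd <- stats::sd(y[tail_idx] - sl * tail_idx)
  sl_se <- resid_sd / (stats::sd(tail_idx) * sqrt(m - 1))
  still_rising <- is.finite(sl_se) && sl_se > 0 && sl / sl_se > 3 &&
    sl * m > 0.1 * amp
  saturated <- mean(y[tail_idx]) >= min(y) + 0.85 * amp && !still_rising
  if (!saturated) flags <- c(flags, "non_saturating")

  F0_0 <- mean(y[1:2])
  FM_0 <- max(y)
  k_half <- which(y >= min(y) + amp / 2)[1]
  sigma_0 <- log(2) / (max(k_half, 1) * train$dose_per_flashlet)
  dose <- train$dose_per_flashlet
  free_rho <- is.null(rho_fix)

  rss_fn <- function(p) {
    rho <- if (free_rho) p[4] else rho_fix
    C <- induction_closure(p[3], rho, dose, n, C_init)
    sum((p[1] + (p[2] - p[1]) * C * (1 - rho) / (1 - rho * C) - y)^2)
  }
  lower <- c(0, F0_0, 1e-12)
  upper <- c(FM_0, 2 * FM_0, control$sigma_factor * sigma_0)
  start1 <- c(if (C_init > 0) F0_0 / 2 else F0_0, FM_0, sigma_0)
  if (free_rho) {
    lower <- c(lower, 0); upper <- c(upper, control$rho_max)
    starts <- list(c(start1, 0.3), c(start1, 0))
  } else starts <- list(start1)
  rss0 <- rss_fn(starts[[1]])
  opt <- ls_minimize(starts, lower, upper, rss_fn, control)

  rho_hat <- if (free_rho) opt$par[4] else rho_fix
  C_path <- induction_closure(opt$par[3], rho_hat, dose, n, C_init)
  structure(list(F0_hat = opt$par[1], FM_hat = opt$par[2],
                 sigma_hat = opt$par[3], rho_hat = rho_hat,
                 FS_hat = closure_to_fluorescence(C_init, opt$par[1],
                                                  opt$par[2], rho_hat),
                 C_init = C_init, C_end = C_path[n],
                 rho_fixed = !free_rho,
                 rss = opt$rss, rss0 = rss0,
                 converged = opt$converged && saturated,
                 n_points = n, flags = flags,
                 measurement_id = transient$measurement_id),
            class = "induction_fit")
}

#' @export
print.induction_fit <- function(x, ...) {
  cat(sprintf(
    "<induction_fit> F0=%.4g FM=%.4g sigma=%.4g rho=%.3g%s rss=%.3g converged=%s%s\n",
    x$F0_hat, x$FM_hat, x$sigma_hat, x$rho_hat,
    if (x$rho_fixed) " (fixed)" else "", x$rss, x$converged,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Fit the biexponential PSII reopening (relaxation) model
#'
#' Estimates `(tau1, tau2, alpha1)` with `F0`, `FM` and `rho` fixed from
#' the paired induction fit, the initial closure `C0` taken from the last
#' induction point (the paired fit's `C_end`), and the closure decaying
#' toward `C_floor` (0 in darkness; the pre-flash steady-state closure
#' when measured under actinic light, where the background light keeps
#' re-closing centres):
#' `C(t) = C_floor + (C0 - C_floor) * (alpha1 * exp(-t/tau1) + alpha2 * exp(-t/tau2))`.
#'
#' Output is canonicalized so `tau1_hat <= tau2_hat`; if one amplitude
#' collapses below 1e-3 the decay is effectively single-phase, the second
#' lifetime is unidentifiable, and both lifetimes are reported equal
#' (flag `"single_phase"`).
#'
#' Initialization: `tau1^0` from the time at which the decaying amplitude
#' halves (`t_half / log(2)`), `tau2^0 = 10 * tau1^0`, `alpha1^0 = 0.7`.
#'
#' @param transient a relaxation-phase [frrf_transient()]
#' @param induction the paired [fit_induction()] result (must have
#'   converged)
#' @param control a [fit_control()]
#' @param C_floor closed fraction approached at long times
#' @return an object of class `relaxation_fit`: `tau1_hat`, `tau2_hat`,
#'   `alpha1_hat`, `alpha2_hat`, `C0`, `rss`, `rss0`, `converged`, `flags`
#' @export
fit_relaxation <- function(transient, induction, control = fit_control(),
                           C_floor = 0) {
  if (transient$phase != "relaxation")
    frrf_stop("frrf_invalid_argument", "fit_relaxation requires a relaxation-phase transient")
  if (!isTRUE(induction$converged))
    frrf_stop("frrf_invalid_argument", "paired induction fit has not converged")
  stopifnot_scalar(C_floor, "C_floor", lower = 0, upper = 1, strict_upper = TRUE)
  y <- transient$fluorescence
  t <- transient$times
  F0 <- induction$F0_hat; FM <- induction$FM_hat; rho <- induction$rho_hat
  amp <- max(y) - min(y)
  if (amp <= 0 || amp < 1e-9 * max(abs(y)))
    frrf_stop("frrf_degenerate_input", "constant fluorescence trace: no relaxation amplitude")
  C0 <- max(induction$C_end, C_floor + 1e-6)

  # initialization by exponential peeling of the normalized closure
  # decay: the tail slope gives tau2 and the slow amplitude; the early
  # residual gives tau1. Falls back to the half-decay heuristic.
  Cy <- closure_from_fluorescence(y, F0, FM, rho)
  A <- pmin(pmax((Cy - C_floor) / (C0 - C_floor), 1e-9), 1)
  below <- which(A <= 0.5)
  t_half <- if (length(below)) t[below[1]] else t[length(t)]
  tau1_0 <- max(t_half / log(2), 1)
  tau2_0 <- 10 * tau1_0
  a1_0 <- 0.7
  tail_i <- which(t > t[length(t)] / 4 & A > 1e-6)
  if (length(tail_i) >= 4) {
    cf <- stats::coef(stats::lm(log(A[tail_i]) ~ t[tail_i]))
    if (is.finite(cf[2]) && cf[2] < 0) {
      tau2_0 <- min(max(-1 / cf[2], tau1_0), 1e6)
      a2_0 <- min(max(exp(cf[1]), 0.05), 0.95)
      resid_early <- A - a2_0 * exp(-t / tau2_0)
      early_i <- which(t <= t[length(t)] / 4 & resid_early > 1e-6)
      if (length(early_i) >= 3) {
        cf1 <- stats::coef(stats::lm(log(resid_early[early_i]) ~ t[early_i]))
        if (is.finite(cf1[2]) && cf1[2] < 0)
          tau1_0 <- min(max(-1 / cf1[2], 1), tau2_0)
      }
      a1_0 <- 1 - a2_0
    }
  }

  # lifetimes optimized on the log scale (spans decades; conditions the
  # tau1-tau2 valley much better than the linear scale)
  rss_fn <- function(p) {
    C <- C_floor + (C0 - C_floor) *
      (p[3] * exp(-t / exp(p[1])) + (1 - p[3]) * exp(-t / exp(p[2])))
    sum((F0 + (FM - F0) * C * (1 - rho) / (1 - rho * C) - y)^2)
  }
  lower <- c(0, 0, 0)
  upper <- c(log(1e6), log(1e6), 1)
  starts <- list(c(log(tau1_0), log(tau2_0), a1_0),
                 c(log(tau1_0), log(max(3 * tau1_0, tau2_0)), 0.7),
                 c(log(tau1_0 / 2), log(5 * tau1_0), 0.5),
                 c(log(tau1_0), log(10 * tau1_0), 1))
  rss0 <- rss_fn(starts[[1]])
  opt <- ls_minimize(starts, lower, upper, rss_fn, control)
  # polish from the best solution (escapes premature stalls)
  opt <- ls_minimize(list(opt$par), lower, upper, rss_fn, control)

  tau1 <- exp(opt$par[1]); tau2 <- exp(opt$par[2]); a1 <- opt$par[3]
  if (tau1 > tau2) { tmp <- tau1; tau1 <- tau2; tau2 <- tmp; a1 <- 1 - a1 }
  flags <- character(0)
  if (min(a1, 1 - a1) < 1e-3) {
    dominant <- if (a1 >= 0.5) tau1 else tau2
    tau1 <- tau2 <- dominant
    flags <- c(flags, "single_phase")
  }
  structure(list(tau1_hat = tau1, tau2_hat = tau2,
                 alpha1_hat = a1, alpha2_hat = 1 - a1,
                 C0 = C0, C_floor = C_floor,
                 rss = opt$rss, rss0 = rss0, converged = opt$converged,
                 n_points = length(y), flags = flags,
                 measurement_id = transient$measurement_id),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "<relaxation_fit> tau1=%.4g us tau2=%.4g us alpha1=%.3g rss=%.3g converged=%s\n",
    x$tau1_hat, x$tau2_hat, x$alpha1_hat, x$rss, x$converged))
  invisible(x)
}
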