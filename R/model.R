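#' Map PSII closure to fluorescence yield
#'
#' Connectivity-corrected fluorescence of a PSII population with a fraction
#' `C` of closed reaction centres and excitonic connectivity `rho`:
#' `F = F0 + (FM - F0) * C * (1 - rho) / (1 - rho * C)`. Linear in `C` when
#' `rho = 0`; convex (sigmoidal induction) for `rho > 0`. Continuous and
#' nondecreasing in `C` on `[0, 1]`.
#'
#' @param C fraction of closed PSII centres, in `[0, 1]` (vectorised)
#' @param F0,FM minimal and maximal fluorescence, instrument units
#' @param rho excitonic connectivity, in `[0, 1)`
#' @return fluorescence, instrument units
#' @export
closure_to_fluorescence <- function(C, F0, FM, rho) {
  if (any(C < 0 | C > 1, na.rm = TRUE))
    frrf_stop("frrf_invalid_argument", "C must lie in [0, 1]")
  if (any(rho * C >= 1))
    frrf_stop("frrf_domain_error", "rho * C >= 1: connectivity mapping undefined")
  F0 + (FM - F0) * C * (1 - rho) / (1 - rho * C)
}

#' Invert the closure-to-fluorescence mapping
#'
#' @param F fluorescence, instrument units, in `[F0, FM]`
#' @inheritParams closure_to_fluorescence
#' @return closed fraction `C` in `[0, 1]`
#' @export
closure_from_fluorescence <- function(F, F0, FM, rho) {
  y <- (F - F0) / (FM - F0)
  y <- pmin(pmax(y, 0), 1)
  y / (1 - rho + rho * y)
}

#' Simulate a single-turnover fluorescence induction
#'
#' Per-flashlet closure recursion: each flashlet delivers an integrated
#' photon dose `E` (photons A^-2) that closes open centres at the
#' connectivity-accelerated rate `dC/dE = sigma * (1 - C) / (1 - rho * C)`;
#' the recursion advances `C` by the exact flow of this equation over the
#' flashlet dose (`C+ = 1 - (1 - C) * exp(-sigma * E)` when `rho = 0`,
#' implicit solve otherwise), so the result is invariant to how the dose
#' is subdivided within a flashlet. Optionally a fraction
#' `exp(-(flashlet_duration + gap_duration)/tau1)` of the attained
#' closure relaxes between flashlets (off by default: the default train
#' spans ~88 us, well under tau1 ~ 500 us, which is the single-turnover
#' assumption). Fluorescence at flashlet k is [closure_to_fluorescence()]
#' of the closure after flashlet k.
#'
#' @param state a [photophys_state()]
#' @param train a [flashlet_train()]
#' @param C_init initial closed fraction, in `[0, 1)` (0 when dark-adapted
#'   or after 1 s of darkness; the steady-state closure under actinic light
#'   otherwise)
#' @param relax_between_flashlets logical; apply tau1 reopening between
#'   flashlets (sensitivity analyses only)
#' @param light_context,actinic_par,measurement_id,timestamp_s metadata
#'   passed to [frrf_transient()]
#' @return an induction-phase [frrf_transient()] with
#'   `train$n_flashlets` points; attribute `"closure"` carries the closed
#'   fraction after each flashlet
#' @export
simulate_induction <- function(state, train, C_init = 0,
                               relax_between_flashlets = FALSE,
                               light_context = "dark_adapted",
                               actinic_par = 0, measurement_id = "m0",
                               timestamp_s = 0) {
  stopifnot_scalar(C_init, "C_init", lower = 0, upper = 1, strict_upper = TRUE)
  C <- induction_closure(state$sigma, state$rho, train$dose_per_flashlet,
                         train$n_flashlets, C_init,
                         if (relax_between_flashlets)
                           exp(-(train$flashlet_duration + train$gap_duration) / state$tau1)
                         else 1)
  tr <- frrf_transient(flashlet_times(train),
                       closure_to_fluorescence(C, state$F0, state$FM, state$rho),
                       phase = "induction", light_context = light_context,
                       actinic_par = actinic_par,
                       measurement_id = measurement_id,
                       timestamp_s = timestamp_s)
  attr(tr, "closure") <- C
  tr
}

# Advance closure by the exact flow of dC/dE = sigma (1-C)/(1-rho C)
# over one flashlet of dose E. Separating variables gives the implicit
# relation -(1-rho) log(1-C) + rho C = const + sigma E, solved by Newton
# (the rho = 0 case is closed form).
flashlet_step <- function(C, sE, rho) {
  if (rho == 0) return(1 - (1 - C) * exp(-sE))
  target <- -(1 - rho) * log(1 - C) + rho * C + sE
  # Newton iterations on g(x) = -(1-rho) log(1-x) + rho x - target,
  # g'(x) = (1 - rho x)/(1 - x) > 0; start from the rho = 0 flow
  x <- 1 - (1 - C) * exp(-sE)
  for (i in 1:50) {
    gx <- -(1 - rho) * log(1 - x) + rho * x - target
    step <- gx * (1 - x) / (1 - rho * x)
    x_new <- min(max(x - step, C), 1 - 1e-15)
    if (abs(x_new - x) < 1e-14) { x <- x_new; break }
    x <- x_new
  }
  x
}

# Closure after each of n flashlets; `retain` multiplies C between
# flashlets (1 = no inter-flashlet relaxation).
induction_closure <- function(sigma, rho, dose, n, C_init, retain = 1) {
  C <- numeric(n)
  c_cur <- C_init
  sE <- sigma * dose
  for (k in seq_len(n)) {
    c_cur <- flashlet_step(c_cur, sE, rho)
    C[k] <- c_cur
    c_cur <- c_cur * retain
  }
  C
}

#' Simulate PSII reopening (relaxation) after a single turnover
#'
#' Biexponential decay of the closed fraction,
#' `C(t) = C0 * (alpha1 * exp(-t/tau1) + alpha2 * exp(-t/tau2))`, mapped to
#' fluorescence with [closure_to_fluorescence()]; decreases monotonically
#' toward `F0`.
#'
#' @param state a [photophys_state()]
#' @param C0 closed fraction at the start of relaxation, in `(0, 1]`
#' @param times sampling times, us from relaxation start, strictly
#'   increasing, `times[1] >= 0`
#' @inheritParams simulate_induction
#' @return a relaxation-phase [frrf_transient()]
#' @export
simulate_relaxation <- function(state, C0, times,
                                light_context = "dark_adapted",
                                actinic_par = 0, measurement_id = "m0",
                                timestamp_s = 0) {
  stopifnot_scalar(C0, "C0", lower = 0, upper = 1, strict_lower = TRUE)
  if (any(diff(times) <= 0) || times[1] < 0)
    frrf_stop("frrf_invalid_argument", "times must be strictly increasing and >= 0")
  C <- C0 * (state$alpha1 * exp(-times / state$tau1) +
             state$alpha2 * exp(-times / state$tau2))
  frrf_transient(times,
                 closure_to_fluorescence(C, state$F0, state$FM, state$rho),
                 phase = "relaxation", light_context = light_context,
                 actinic_par = actinic_par, measurement_id = measurement_id,
                 timestamp_s = timestamp_s)
}

#' Calibrate the per-flashlet photon dose
#'
#' Chooses `dose_per_flashlet` so that, for a reference cross section and
#' `rho = 0`, the cumulative closure reaches `target_closure` after
#' `target_flashlet` flashlets (the operational criterion that the
#' fluorescence rise saturates within around 30 of 40 flashlets). Under
#' the flow recursion the `rho = 0` closure after k flashlets is
#' `1 - exp(-sigma * dose * k)`, so
#' `dose = -log(1 - target_closure) / (sigma_ref * target_flashlet)`.
#'
#' @param sigma_ref reference cross section, A^2 quantum^-1
#' @param target_flashlet flashlet index at which saturation is required
#' @param target_closure closed fraction to reach there, in `(0, 1)`
#' @return dose per flashlet, photons A^-2
#' @export
calibrate_dose <- function(sigma_ref = 400, target_flashlet = 30,
                           target_closure = 0.98) {
  stopifnot_scalar(sigma_ref, "sigma_ref", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(target_flashlet, "target_flashlet", lower = 1)
  stopifnot_scalar(target_closure, "target_closure", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  -log(1 - target_closure) / (sigma_ref * target_flashlet)
}

#' Default relaxation sampling grid
#'
#' Log-spaced sampling times covering both reopening phases (tau1 ~ 500 us,
#' tau2 ~ 5000 us) out to several slow lifetimes.
#'
#' @param n number of samples
#' @param t_min,t_max first and last sample, us
#' @return strictly increasing numeric vector, us
#' @export
relaxation_times <- function(n = 48, t_min = 20, t_max = 30000) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}
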