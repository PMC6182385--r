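#' Synthetic experiment generator configuration
#'
#' Ground-truth physiology and noise model for synthetic FRRf
#' experiments. Defaults encode the emulated photoacclimation dynamics:
#' dark-adapted `Fv/Fm = 0.6` (so the dark non-regulated dissipation
#' `Y(NO) = F0/FM = 0.4`), `sigma_PSII = 400` A^2, connectivity 0.3,
#' reopening lifetimes `tau1 = 500` us rising toward 1800 us with
#' excitation pressure, `tau2 = 5000` us; time-dependent Y(NPQ) induction
#' above a PAR threshold of 305 umol photons m^-2 s^-1 with slow,
#' incomplete dark reversal; a linear decline of normalised sigma_PSII'
#' with Y(NPQ) of slope -0.65; an optional light-history upregulation that
#' halves tau1 after sustained supra-threshold exposure (relaxing once PAR
#' returns to the growth irradiance); and a DTT treatment mode that
#' disables Y(NPQ) induction altogether.
#'
#' @param seed integer seed for the single pseudo-random stream of the
#'   experiment
#' @param F0_dark,FM_dark dark-adapted minimal/maximal fluorescence
#' @param sigma_dark dark-adapted sigma_PSII, A^2 quantum^-1
#' @param rho_dark excitonic connectivity (held constant by the generator)
#' @param tau1_base,tau1_max fast reopening lifetime in darkness and its
#'   ceiling under full excitation pressure, us
#' @param tau2 slow reopening lifetime, us
#' @param alpha1 amplitude fraction of the fast reopening phase
#' @param npq_par_threshold PAR above which Y(NPQ) induction ramps,
#'   umol photons m^-2 s^-1
#' @param npq_rate Y(NPQ) induction rate above threshold, s^-1
#' @param npq_relax_rate Y(NPQ) dark relaxation rate, s^-1 (slow: reversal
#'   within a 900 s recovery stays incomplete)
#' @param sigma_slope d(normalised sigma')/d(Y(NPQ)), dimensionless
#' @param upregulation logical; enable the tau1-halving light-history
#'   response
#' @param upreg_factor multiplier applied to tau1 once upregulation is
#'   active
#' @param upreg_exposure_s cumulative supra-threshold exposure required to
#'   activate upregulation, s
#' @param growth_par growth irradiance at or below which the upregulation
#'   history resets, umol photons m^-2 s^-1
#' @param dtt_mode logical; force `npq_rate = 0` (xanthophyll-cycle
#'   inhibition)
#' @param noise_cv multiplicative Gaussian noise, coefficient of variation
#' @return object of class `generator_config`
#' @export
generator_config <- function(seed = 1L, F0_dark = 0.2, FM_dark = 0.5,
                             sigma_dark = 400, rho_dark = 0.3,
                             tau1_base = 500, tau1_max = 1800, tau2 = 5000,
                             alpha1 = 0.7,
                             npq_par_threshold = 305, npq_rate = 0.003,
                             npq_relax_rate = 5e-4, sigma_slope = -0.65,
                             upregulation = TRUE, upreg_factor = 0.5,
                             upreg_exposure_s = 35, growth_par = 74,
                             dtt_mode = FALSE, noise_cv = 0.01) {
  stopifnot_scalar(F0_dark, "F0_dark", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(FM_dark, "FM_dark", lower = F0_dark, strict_lower = TRUE)
  stopifnot_scalar(npq_rate, "npq_rate", lower = 0)
  stopifnot_scalar(npq_relax_rate, "npq_relax_rate", lower = 0)
  stopifnot_scalar(noise_cv, "noise_cv", lower = 0)
  if (abs(sigma_slope) > 1)
    frrf_stop("frrf_invalid_argument", "|sigma_slope| must be <= 1")
  structure(list(seed = as.integer(seed), F0_dark = F0_dark,
                 FM_dark = FM_dark, sigma_dark = sigma_dark,
                 rho_dark = rho_dark, tau1_base = tau1_base,
                 tau1_max = tau1_max, tau2 = tau2, alpha1 = alpha1,
                 npq_par_threshold = npq_par_threshold,
                 npq_rate = if (dtt_mode) 0 else npq_rate,
                 npq_relax_rate = npq_relax_rate,
                 sigma_slope = sigma_slope, upregulation = upregulation,
                 upreg_factor = upreg_factor,
                 upreg_exposure_s = upreg_exposure_s,
                 growth_par = growth_par, dtt_mode = dtt_mode,
                 noise_cv = noise_cv),
            class = "generator_config")
}

# PAR as a step function of protocol time (t = 0 is the dark reference
# measurement; light step k spans its window after step_offset_s)
sequence_par_at <- function(sequence, t) {
  steps <- sequence$steps
  ends <- sequence$step_offset_s + cumsum(steps$duration_s)
  starts <- c(sequence$step_offset_s, ends[-length(ends)])
  par <- numeric(length(t))
  for (i in seq_len(nrow(steps)))
    par[t >= starts[i] & t < ends[i]] <- steps$par[i]
  par
}

#' Ground-truth physiological trajectory under a light sequence
#'
#' Integrates the generator's photoacclimation dynamics over the protocol
#' clock (forward Euler, 1 s steps) and evaluates the ground-truth
#' photophysiological state at every measurement slot of the schedule:
#'
#' * `Y(NPQ)` ramps as `dY/dt = npq_rate * (1 - Y)` while
#'   `PAR > npq_par_threshold`, and decays as
#'   `dY/dt = -npq_relax_rate * Y` otherwise. The reportable value is
#'   additionally capped at 95% of the instantaneous quenching headroom
#'   `FS/FM' = f0 + (1 - f0) * Cy` that the yield algebra admits
#'   (Y(NPQ) = FS/FM' - FS/FM can never exceed FS/FM').
#' * `sigma' = sigma_dark * (1 + sigma_slope * Y(NPQ))`.
#' * `tau1` under light rises from `tau1_base` toward `tau1_max` with the
#'   instantaneous excitation pressure (closed fraction); once cumulative
#'   supra-threshold exposure passes `upreg_exposure_s` and
#'   `upregulation` is on, tau1 is multiplied by `upreg_factor`
#'   (accelerated reopening), the history resetting whenever PAR falls to
#'   `growth_par` or below. tau1 measured after 1 s darkness is always
#'   `tau1_base`.
#' * The closed fraction under light solves the steady-state balance of
#'   the excitation rate `PAR_A * sigma'` against the amplitude-weighted
#'   reopening rate `alpha1/tau1 + alpha2/tau2`.
#' * Quenching scales both F0 and FM by `s = 1 - Y(NPQ) / (FS/FM')`, so
#'   the rendered fluorescences reproduce the intended Y(NPQ) exactly
#'   through the Klughammer-Schreiber algebra.
#'
#' @param config a [generator_config()]
#' @param sequence a [light_sequence()]
#' @return data.frame with one row per measurement slot and context
#'   (`dark_adapted`, `actinic`, `dark_1s`): ground-truth state columns
#'   (`F0_base`, `FM_top`, `sigma`, `rho`, `tau1`, `tau2`, `alpha1`,
#'   `C_init`), `FS_truth`, `Y_NPQ_truth`, `quench_scale`, `upreg_active`
#' @export
state_trajectory <- function(config, sequence) {
  sched <- measurement_schedule(sequence)
  t_end <- max(sched$timestamp_s) + 2
  dt <- 1
  tgrid <- seq(0, t_end, by = dt)
  par_t <- sequence_par_at(sequence, tgrid)

  Y <- numeric(length(tgrid))     # unclamped NPQ driver
  H <- numeric(length(tgrid))     # cumulative supra-threshold exposure, s
  for (i in seq_along(tgrid)[-1]) {
    above <- par_t[i - 1] > config$npq_par_threshold
    dY <- if (above) config$npq_rate * (1 - Y[i - 1])
          else -config$npq_relax_rate * Y[i - 1]
    Y[i] <- min(max(Y[i - 1] + dt * dY, 0), 1)
    H[i] <- if (par_t[i - 1] <= config$growth_par) 0
            else H[i - 1] + dt * above
  }

  f0 <- config$F0_dark / config$FM_dark
  rows <- vector("list", nrow(sched))
  for (k in seq_len(nrow(sched))) {
    t_k <- sched$timestamp_s[k]
    par_k <- sched$par[k]
    i_k <- which.min(abs(tgrid - t_k))
    y_ode <- Y[i_k]
    upreg <- config$upregulation && H[i_k] >= config$upreg_exposure_s

    # jointly solve closure, sigma' and the headroom-capped Y(NPQ)
    y_eff <- min(y_ode, 0.95 * f0)
    C <- 0.5
    for (it in 1:200) {
      sig <- config$sigma_dark * (1 + config$sigma_slope * y_eff)
      tau1 <- (config$tau1_base +
                 (config$tau1_max - config$tau1_base) * C) *
              if (upreg) config$upreg_factor else 1
      k_ex <- par_to_photons(par_k) * sig                  # s^-1
      k_open <- 1e6 * (config$alpha1 / tau1 + (1 - config$alpha1) / config$tau2)
      C_new <- if (k_ex <= 0) 0 else k_ex / (k_ex + k_open)
      Cy <- C_new * (1 - config$rho_dark) / (1 - config$rho_dark * C_new)
      headroom <- f0 + (1 - f0) * Cy
      y_new <- min(y_ode, 0.95 * headroom)
      if (abs(C_new - C) < 1e-12 && abs(y_new - y_eff) < 1e-12) {
        C <- C_new; y_eff <- y_new; break
      }
      C <- C_new; y_eff <- y_new
    }
    s <- 1 - y_eff / headroom
    FS <- closure_to_fluorescence(C, s * config$F0_dark, s * config$FM_dark,
                                  config$rho_dark)
    ctx <- if (sched$step_index[k] == 0L) "dark_adapted" else "actinic"
    base <- data.frame(measurement_id = sched$measurement_id[k],
                       step_index = sched$step_index[k],
                       par = par_k, rho = config$rho_dark,
                       tau2 = config$tau2, alpha1 = config$alpha1,
                       Y_NPQ_truth = y_eff, quench_scale = s,
                       upreg_active = upreg, stringsAsFactors = FALSE)
    rows[[k]] <- rbind(
      cbind(base, data.frame(timestamp_s = t_k, light_context = ctx,
                             F0_base = s * config$F0_dark,
                             FM_top = s * config$FM_dark, sigma = sig,
                             tau1 = tau1, C_init = C, FS_truth = FS)),
      if (ctx == "actinic")
        cbind(base, data.frame(timestamp_s = t_k + 1,
                               light_context = "dark_1s",
                               F0_base = s * config$F0_dark,
                               FM_top = s * config$FM_dark, sigma = sig,
                               tau1 = config$tau1_base, C_init = 0,
                               FS_truth = s * config$F0_dark)))
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth
}

#' Render a ground-truth trajectory into noisy flashlet transients
#'
#' For every measurement slot of the trajectory, simulates the flashlet
#' induction (starting from the steady-state closure under light, from 0
#' in dark contexts) and the subsequent relaxation (toward the steady
#' state under light, toward full reopening in dark contexts), then
#' applies multiplicative Gaussian noise (`CV = noise_cv`) drawn from a
#' single stream seeded with `config$seed`.
#'
#' @param truth output of [state_trajectory()]
#' @param train a [flashlet_train()]
#' @param config the [generator_config()] used
#' @return list of [frrf_transient()] (induction and relaxation per slot)
#' @export
render_transients <- function(truth, train, config) {
  set.seed(config$seed)
  rel_t <- relaxation_times()
  out <- vector("list", 2L * nrow(truth))
  for (k in seq_len(nrow(truth))) {
    row <- truth[k, ]
    state <- photophys_state(F0 = row$F0_base, FM = row$FM_top,
                             sigma = row$sigma, rho = row$rho,
                             tau1 = row$tau1, tau2 = row$tau2,
                             alpha1 = row$alpha1)
    ctx <- row$light_context
    par_k <- if (ctx == "actinic") row$par else 0
    ind <- simulate_induction(state, train, C_init = min(row$C_init, 0.999),
                              light_context = ctx, actinic_par = par_k,
                              measurement_id = row$measurement_id,
                              timestamp_s = row$timestamp_s)
    C_end <- utils::tail(attr(ind, "closure"), 1)
    # relaxation decays back to the pre-flash steady state (C_init under
    # actinic light, 0 in darkness)
    C_ss <- if (ctx == "actinic") row$C_init else 0
    C_rel <- C_ss + (C_end - C_ss) *
      (row$alpha1 * exp(-rel_t / row$tau1) +
         (1 - row$alpha1) * exp(-rel_t / row$tau2))
    rel <- frrf_transient(rel_t,
                          closure_to_fluorescence(C_rel, row$F0_base,
                                                  row$FM_top, row$rho),
                          phase = "relaxation", light_context = ctx,
                          actinic_par = par_k,
                          measurement_id = row$measurement_id,
                          timestamp_s = row$timestamp_s)
    if (config$noise_cv > 0) {
      ind$fluorescence <- pmax(ind$fluorescence *
        (1 + stats::rnorm(length(ind$fluorescence), 0, config$noise_cv)), 0)
      rel$fluorescence <- pmax(rel$fluorescence *
        (1 + stats::rnorm(length(rel$fluorescence), 0, config$noise_cv)), 0)
    }
    out[[2 * k - 1]] <- ind
    out[[2 * k]] <- rel
  }
  out
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: [state_trajectory()] then [render_transients()].
#'
#' @param config a [generator_config()]
#' @param sequence a [light_sequence()]
#' @param train a [flashlet_train()]; by default its dose is calibrated
#'   with [calibrate_dose()] against the dark-adapted cross section
#' @return list with `truth`, `transients`, `sequence`, `train`, `config`
#' @export
simulate_experiment <- function(config = generator_config(),
                                sequence = default_rlc_sequence(),
                                train = NULL) {
  if (is.null(train))
    train <- flashlet_train(dose_per_flashlet =
                              calibrate_dose(config$sigma_dark, 30, 0.98))
  truth <- state_trajectory(config, sequence)
  transients <- render_transients(truth, train, config)
  list(truth = truth, transients = transients, sequence = sequence,
       train = train, config = config)
}
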