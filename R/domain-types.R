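#' Flashlet train (single-turnover excitation protocol)
#'
#' Describes the excitation protocol of one FRRf induction measurement: a
#' train of `n_flashlets` sub-saturating flashlets of `flashlet_duration`
#' microseconds separated by `gap_duration` microseconds of darkness, each
#' delivering an integrated photon dose of `dose_per_flashlet` photons per
#' square Angstrom. The default train (40 flashlets of 1.2 us separated by
#' 1.0 us) cumulatively induces a single photochemical turnover of PSII.
#'
#' @param n_flashlets number of flashlets (>= 1)
#' @param flashlet_duration flashlet length, us (> 0)
#' @param gap_duration dark interval between flashlets, us (>= 0)
#' @param dose_per_flashlet integrated photon dose per flashlet,
#'   photons A^-2 (> 0)
#' @param wavelength_nm excitation wavelength, metadata only
#' @return an object of class `flashlet_train`
#' @seealso [calibrate_dose()] to choose `dose_per_flashlet` so the
#'   fluorescence rise saturates at a target flashlet.
#' @export
flashlet_train <- function(n_flashlets = 40L, flashlet_duration = 1.2,
                           gap_duration = 1.0,
                           dose_per_flashlet = 3.0e-4,
                           wavelength_nm = 455) {
  stopifnot_scalar(n_flashlets, "n_flashlets", lower = 1)
  stopifnot_scalar(flashlet_duration, "flashlet_duration", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(gap_duration, "gap_duration", lower = 0)
  stopifnot_scalar(dose_per_flashlet, "dose_per_flashlet", lower = 0,
                   strict_lower = TRUE)
  structure(list(n_flashlets = as.integer(n_flashlets),
                 flashlet_duration = flashlet_duration,
                 gap_duration = gap_duration,
                 dose_per_flashlet = dose_per_flashlet,
                 wavelength_nm = wavelength_nm),
            class = "flashlet_train")
}

#' Flashlet timestamps
#'
#' Time of the k-th flashlet (end of its excitation period), us from the
#' start of the train: `k * (flashlet_duration + gap_duration)`.
#'
#' @param train a [flashlet_train()]
#' @return strictly increasing numeric vector of length `n_flashlets`, us
#' @export
flashlet_times <- function(train) {
  seq_len(train$n_flashlets) * (train$flashlet_duration + train$gap_duration)
}

#' @export
print.flashlet_train <- function(x, ...) {
  cat(sprintf(
    "<flashlet_train> %d flashlets x %.3g us (+%.3g us gap), dose %.3g photons/A^2, %g nm\n",
    x$n_flashlets, x$flashlet_duration, x$gap_duration,
    x$dose_per_flashlet, x$wavelength_nm))
  invisible(x)
}

#' Photophysiological state of one PSII measurement
#'
#' Ground-truth or fitted biophysical parameters of a single FRRf
#' measurement. `F0`/`FM` are the minimal/maximal fluorescence yields
#' (arbitrary instrument units), `sigma` the effective absorption cross
#' section for PSII photochemistry (A^2 quantum^-1; sigma_PSII dark-adapted,
#' sigma_PSII' under actinic light), `rho` the coefficient of excitonic
#' connectivity between PSII units, and `tau1 < tau2` (us) the rapid and
#' slow lifetimes of the biexponential QA- reoxidation (PSII reopening)
#' with amplitude fractions `alpha1 + alpha2 = 1`.
#'
#' @param F0,FM minimal and maximal fluorescence, instrument units,
#'   `0 <= F0 < FM`
#' @param sigma effective absorption cross section, A^2 quantum^-1 (> 0)
#' @param rho excitonic connectivity, in `[0, 1)`
#' @param tau1,tau2 fast and slow reopening lifetimes, us, `0 < tau1 <= tau2`
#' @param alpha1 fraction of the fast reopening phase, in `[0, 1]`;
#'   `alpha2 = 1 - alpha1`
#' @return an object of class `photophys_state`
#' @export
photophys_state <- function(F0 = 0.2, FM = 0.5, sigma = 400, rho = 0.3,
                            tau1 = 500, tau2 = 5000, alpha1 = 0.7) {
  stopifnot_scalar(F0, "F0", lower = 0)
  stopifnot_scalar(FM, "FM", lower = F0, strict_lower = TRUE)
  stopifnot_scalar(sigma, "sigma", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(rho, "rho", lower = 0, upper = 1, strict_upper = TRUE)
  stopifnot_scalar(tau1, "tau1", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(tau2, "tau2", lower = tau1)
  stopifnot_scalar(alpha1, "alpha1", lower = 0, upper = 1)
  structure(list(F0 = F0, FM = FM, sigma = sigma, rho = rho,
                 tau1 = tau1, tau2 = tau2,
                 alpha1 = alpha1, alpha2 = 1 - alpha1),
            class = "photophys_state")
}

#' @export
print.photophys_state <- function(x, ...) {
  cat(sprintf(
    "<photophys_state> F0=%.4g FM=%.4g sigma=%.4g A^2 rho=%.3g tau1=%.4g us tau2=%.4g us alpha1=%.3g\n",
    x$F0, x$FM, x$sigma, x$rho, x$tau1, x$tau2, x$alpha1))
  invisible(x)
}

LIGHT_CONTEXTS <- c("dark_adapted", "actinic", "dark_1s")
TRANSIENT_PHASES <- c("induction", "relaxation")

#' One FRRf transient (induction or relaxation time series)
#'
#' @param times us from measurement start, strictly increasing, length >= 4
#' @param fluorescence instrument units, >= 0, same length as `times`
#' @param phase `"induction"` or `"relaxation"`
#' @param light_context `"dark_adapted"`, `"actinic"` (measured in the
#'   presence of background actinic light) or `"dark_1s"` (measured after
#'   1 s of darkness immediately following actinic light)
#' @param actinic_par background actinic PAR, umol photons m^-2 s^-1
#'   (0 for dark contexts)
#' @param measurement_id opaque label pairing the induction and relaxation
#'   curves of one measurement
#' @param timestamp_s seconds since experiment start
#' @return an object of class `frrf_transient`
#' @export
frrf_transient <- function(times, fluorescence, phase,
                           light_context = "dark_adapted", actinic_par = 0,
                           measurement_id = "m0", timestamp_s = 0) {
  phase <- match.arg(phase, TRANSIENT_PHASES)
  light_context <- match.arg(light_context, LIGHT_CONTEXTS)
  if (length(times) != length(fluorescence) || length(times) < 4L)
    frrf_stop("frrf_invalid_argument",
              "times and fluorescence must have equal length >= 4")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    frrf_stop("frrf_invalid_argument", "times must be finite and strictly increasing")
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0))
    frrf_stop("frrf_invalid_argument", "fluorescence must be finite and >= 0")
  if (light_context != "actinic" && actinic_par != 0)
    frrf_stop("frrf_invalid_argument", "actinic_par must be 0 for dark contexts")
  structure(list(times = as.numeric(times),
                 fluorescence = as.numeric(fluorescence),
                 phase = phase, light_context = light_context,
                 actinic_par = actinic_par,
                 measurement_id = as.character(measurement_id),
                 timestamp_s = timestamp_s),
            class = "frrf_transient")
}

#' @export
print.frrf_transient <- function(x, ...) {
  cat(sprintf("<frrf_transient> %s/%s id=%s t=%gs PAR=%g, %d points, F in [%.4g, %.4g]\n",
              x$phase, x$light_context, x$measurement_id, x$timestamp_s,
              x$actinic_par, length(x$times),
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}
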