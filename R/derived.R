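#' Estimate minimal fluorescence under actinic light (F0')
#'
#' `F0' = F0'1s * (1 - (FM'1s - FM')/FM'1s)`, which simplifies to
#' `F0'1s * FM' / FM'1s`: the minimal fluorescence measured after 1 s of
#' darkness (PSII reopened, quenching essentially unrelaxed), scaled back
#' to the in-light quenching level.
#'
#' @param F0p_1s minimal fluorescence after 1 s darkness (F0'1s)
#' @param FMp_1s maximal fluorescence after 1 s darkness (FM'1s), > 0
#' @param FMp maximal fluorescence under actinic light (FM')
#' @return list with `F0p` and `flags` (flag `"fmprime_exceeds_1s"` when
#'   `FM' > FM'1s`, which yields `F0' > F0'1s`; physically odd but retained
#'   as the formula dictates)
#' @export
estimate_F0prime <- function(F0p_1s, FMp_1s, FMp) {
  stopifnot_scalar(FMp_1s, "FMp_1s", lower = 0, strict_lower = TRUE)
  flags <- character(0)
  if (FMp > FMp_1s) flags <- "fmprime_exceeds_1s"
  list(F0p = F0p_1s * FMp / FMp_1s, flags = flags)
}

#' Partition the PSII excitation between photochemistry and dissipation
#'
#' From steady-state (`FS`) and maximal (`FM'`) fluorescence under actinic
#' light, the dark-adapted maximal fluorescence (`FM`) and estimated `F0'`:
#' \itemize{
#'   \item `qP = (FM' - FS) / (FM' - F0')` (photochemical quenching;
#'     `1 - qP` is the excitation pressure, the fraction of
#'     instantaneously closed PSII centres)
#'   \item `Y(PSII) = (FM' - FS) / FM'` (photochemistry)
#'   \item `Y(NPQ) = FS/FM' - FS/FM` (regulated dissipation)
#'   \item `Y(NO) = FS/FM` (non-regulated dissipation)
#' }
#' The three yields telescope to `Y(PSII) + Y(NPQ) + Y(NO) = 1` exactly.
#' Out-of-range values are never clipped in stored results; violations of
#' `0 <= F0' <= FS <= FM' <= FM` are reported through `flags`.
#'
#' @param FS steady-state fluorescence under actinic light
#' @param FMp maximal fluorescence under actinic light (FM')
#' @param FM_ref dark-adapted maximal fluorescence (FM)
#' @param F0p estimated minimal fluorescence under light (F0')
#' @return object of class `yield_partition`: `F0p`, `qP`,
#'   `excitation_pressure`, `Y_PSII`, `Y_NPQ`, `Y_NO`, `flags`
#' @export
yield_partition <- function(FS, FMp, FM_ref, F0p) {
  if (FMp == F0p || FMp == 0 || FM_ref == 0)
    frrf_stop("frrf_division_degenerate",
              "degenerate denominators: FM' = F0', FM' = 0 or FM = 0")
  flags <- character(0)
  if (F0p < 0 || F0p > FS) flags <- c(flags, "f0p_out_of_range")
  if (FS > FMp) flags <- c(flags, "fs_exceeds_fmp")
  if (FMp > FM_ref) flags <- c(flags, "fmp_exceeds_fm")
  qP <- (FMp - FS) / (FMp - F0p)
  structure(list(F0p = F0p, qP = qP, excitation_pressure = 1 - qP,
                 Y_PSII = (FMp - FS) / FMp,
                 Y_NPQ = FS / FMp - FS / FM_ref,
                 Y_NO = FS / FM_ref,
                 flags = flags),
            class = "yield_partition")
}

#' @export
print.yield_partition <- function(x, ...) {
  cat(sprintf("<yield_partition> qP=%.3f Y(PSII)=%.3f Y(NPQ)=%.3f Y(NO)=%.3f%s\n",
              x$qP, x$Y_PSII, x$Y_NPQ, x$Y_NO,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Absolute electron transport rate per PSII
#'
#' `ETR = E_A * sigma_PSII' * Y(PSII) / (Fv/Fm)` in electrons PSII^-1 s^-1,
#' where `E_A` is the actinic PAR converted to photons A^-2 s^-1
#' (1 umol photons m^-2 s^-1 = 6.022140e-3 photons A^-2 s^-1) and
#' `Fv/Fm = (FM - F0)/FM` is the dark-adapted maximal quantum yield of the
#' biological replicate. The PSII-per-chlorophyll factor n_PSII is
#' deliberately excluded; ETR is per PSII, not per chlorophyll.
#'
#' @param par actinic PAR, umol photons m^-2 s^-1
#' @param sigma_p effective absorption cross section under actinic light
#'   (sigma_PSII'), A^2 quantum^-1
#' @param Y_PSII quantum yield of PSII photochemistry
#' @param F0_ref,FM_ref dark-adapted minimal/maximal fluorescence of the
#'   replicate (`FM_ref > F0_ref >= 0`)
#' @return ETR, electrons PSII^-1 s^-1
#' @export
compute_etr <- function(par, sigma_p, Y_PSII, F0_ref, FM_ref) {
  if (FM_ref == F0_ref)
    frrf_stop("frrf_division_degenerate", "FM = F0: Fv/Fm undefined")
  par_to_photons(par) * sigma_p * Y_PSII / ((FM_ref - F0_ref) / FM_ref)
}
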