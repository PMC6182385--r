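#' Light sequence (experimental design)
#'
#' Ordered actinic light steps of one experiment. Two designs are
#' supported: `"nonsequential_rlc"` (a rapid light curve whose 30 s steps
#' revisit light levels out of monotone order) and `"induction_recovery"`
#' (a long actinic induction segment followed by a dark recovery segment).
#'
#' The protocol clock starts at the dark-adapted reference measurement
#' (t = 0), which occupies the first `step_offset_s` seconds; light step k
#' then spans the following `duration_s` windows, with the paired FRRf
#' measurements applied at the end of each step (in the light, and again
#' after 1 s of darkness).
#'
#' @param par vector of step PAR values, umol photons m^-2 s^-1
#' @param duration_s step durations, s (recycled)
#' @param design `"nonsequential_rlc"` or `"induction_recovery"`
#' @param dark_adapt_s dark adaptation before the reference measurement, s
#' @param step_offset_s protocol time at which the first light step
#'   begins, s
#' @param meas_interval_s measurement spacing within long
#'   induction-recovery segments, s
#' @return object of class `light_sequence`
#' @export
light_sequence <- function(par, duration_s = 30,
                           design = c("nonsequential_rlc", "induction_recovery"),
                           dark_adapt_s = 120, step_offset_s = 30,
                           meas_interval_s = 60) {
  design <- match.arg(design)
  if (any(par < 0) || any(duration_s <= 0))
    frrf_stop("frrf_invalid_argument", "PAR must be >= 0 and durations > 0")
  duration_s <- rep_len(duration_s, length(par))
  if (design == "induction_recovery" && length(par) != 2L)
    frrf_stop("frrf_invalid_argument",
              "induction_recovery has exactly two segments (light, dark)")
  structure(list(steps = data.frame(par = par, duration_s = duration_s),
                 design = design, dark_adapt_s = dark_adapt_s,
                 step_offset_s = step_offset_s,
                 meas_interval_s = meas_interval_s),
            class = "light_sequence")
}

#' @export
print.light_sequence <- function(x, ...) {
  cat(sprintf("<light_sequence> %s, %d steps, %g s total (dark adapt %g s)\n",
              x$design, nrow(x$steps), sum(x$steps$duration_s), x$dark_adapt_s))
  print(x$steps)
  invisible(x)
}

#' The canonical non-sequential rapid light curve
#'
#' Nine 30 s light steps preceded by the dark-adapted reference
#' measurement: PAR rises over three steps to 114, supersaturates at 300
#' and 470 (the 470 step ending 180 s into the protocol), is lowered back
#' to 300, re-increased to 470 and on to 540 (ending at 270 s), and
#' finally returns to the growth irradiance of 74 umol photons m^-2 s^-1.
#' Revisited levels (300, 470, 74) are what make the design non-sequential
#' and allow first-visit vs revisit comparisons of ETR at the same PAR.
#'
#' The PAR of the two earliest (sub-saturating) steps is not pinned by the
#' design and may be overridden.
#'
#' @param low_steps PAR of the first two ramp steps
#' @param duration_s step duration, s
#' @param dark_adapt_s dark adaptation, s
#' @return a `"nonsequential_rlc"` [light_sequence()]
#' @export
default_rlc_sequence <- function(low_steps = c(34, 74), duration_s = 30,
                                 dark_adapt_s = 120) {
  light_sequence(c(low_steps, 114, 300, 470, 300, 470, 540, 74),
                 duration_s = duration_s, design = "nonsequential_rlc",
                 dark_adapt_s = dark_adapt_s, step_offset_s = duration_s)
}

#' Induction-recovery design
#'
#' A single actinic induction segment (default 1200 s) followed by a dark
#' recovery segment (default 900 s), measured every `meas_interval_s`
#' seconds. The standard treatments use 300 and 600 umol photons m^-2 s^-1
#' as comparatively lower and higher light stress.
#'
#' @param par induction-phase PAR, umol photons m^-2 s^-1
#' @param induction_s induction duration, s
#' @param recovery_s dark recovery duration, s
#' @param meas_interval_s measurement spacing, s
#' @param dark_adapt_s dark adaptation, s
#' @return an `"induction_recovery"` [light_sequence()]
#' @export
induction_recovery_sequence <- function(par = 300, induction_s = 1200,
                                        recovery_s = 900,
                                        meas_interval_s = 60,
                                        dark_adapt_s = 120) {
  light_sequence(c(par, 0), duration_s = c(induction_s, recovery_s),
                 design = "induction_recovery", dark_adapt_s = dark_adapt_s,
                 step_offset_s = 0, meas_interval_s = meas_interval_s)
}

#' Measurement schedule of a light sequence
#'
#' Expands a [light_sequence()] into the ordered list of measurement
#' slots: the dark-adapted reference at t = 0, then one slot at the end of
#' each RLC step (or every `meas_interval_s` within induction-recovery
#' segments), each followed 1 s later by its paired dark measurement.
#'
#' @param sequence a [light_sequence()]
#' @return data.frame with `step_index` (0 = dark reference),
#'   `timestamp_s` (the in-light measurement time), `par` and
#'   `measurement_id`
#' @export
measurement_schedule <- function(sequence) {
  steps <- sequence$steps
  if (sequence$design == "nonsequential_rlc") {
    ends <- sequence$step_offset_s + cumsum(steps$duration_s)
    sched <- data.frame(step_index = seq_len(nrow(steps)),
                        timestamp_s = ends, par = steps$par)
  } else {
    seg_start <- sequence$step_offset_s + c(0, steps$duration_s[1])
    slots <- lapply(1:2, function(i) {
      tt <- seq(sequence$meas_interval_s, steps$duration_s[i],
                by = sequence$meas_interval_s)
      data.frame(timestamp_s = seg_start[i] + tt, par = steps$par[i])
    })
    sched <- do.call(rbind, slots)
    sched <- cbind(step_index = seq_len(nrow(sched)), sched)
  }
  sched <- rbind(data.frame(step_index = 0L, timestamp_s = 0, par = 0), sched)
  sched$measurement_id <- sprintf("s%03d", sched$step_index)
  sched
}

# group a flat list of frrf_transient by measurement id + light context
group_measurements <- function(transients) {
  ids <- vapply(transients, function(x)
    paste(x$measurement_id, x$light_context, sep = "|"), "")
  out <- list()
  for (id in unique(ids)) {
    group <- transients[ids == id]
    phases <- vapply(group, `[[`, "", "phase")
    ind <- group[phases == "induction"]
    rel <- group[phases == "relaxation"]
    if (length(ind) != 1L) next
    out[[id]] <- list(induction_tr = ind[[1]],
                      relaxation_tr = if (length(rel) == 1L) rel[[1]] else NULL)
  }
  out
}

# plain per-measurement fits (induction with C_init = 0, relaxation with
# floor 0): the generic `fit` route; the pipeline refines in-light fits
fit_all_measurements <- function(transients, train, control = fit_control()) {
  groups <- group_measurements(transients)
  lapply(groups, function(g) {
    ifit <- tryCatch(fit_induction(g$induction_tr, train, control),
                     frrf_error = function(e) NULL)
    rfit <- if (!is.null(ifit) && isTRUE(ifit$converged) &&
                !is.null(g$relaxation_tr))
      tryCatch(fit_relaxation(g$relaxation_tr, ifit, control),
               frrf_error = function(e) NULL)
    else NULL
    list(transient = g$induction_tr, induction = ifit, relaxation = rfit)
  })
}

#' Pair in-light and post-illumination measurements into an experiment table
#'
#' Fits every transient (induction then relaxation, per measurement),
#' pairs each in-light measurement with the nearest dark measurement
#' taken within `(0, pair_window_s]` seconds after it (the 1-s-dark
#' measurement applied immediately after each light step), computes the
#' derived quantities (`F0'`, `qP`, yield partition, ETR) per step against
#' the experiment's single dark-adapted reference, and returns the ordered
#' record table. Unmatched or unconverged measurements are retained with
#' quality flags, never dropped silently. Pairing keys on timestamps and
#' measurement ids, so the input order is irrelevant.
#'
#' @param transients list of [frrf_transient()] (one induction and one
#'   relaxation per measurement id/context)
#' @param train the [flashlet_train()] used
#' @param control a [fit_control()]
#' @param etr_sigma which cross-section estimate enters ETR: the in-light
#'   fit (default) or the 1-s-dark fit
#' @param pair_window_s pairing window after the in-light measurement, s
#' @param strain_label,treatment metadata carried into the table
#' @return object of class `experiment_table`: `records` (one row per
#'   light step), `dark_reference` (dark-adapted fits), metadata
#' @export
pair_measurements <- function(transients, train = flashlet_train(),
                              control = fit_control(),
                              etr_sigma = c("in_light", "dark_1s"),
                              pair_window_s = 5,
                              strain_label = "synthetic",
                              treatment = c("control", "dtt")) {
  etr_sigma <- match.arg(etr_sigma)
  treatment <- match.arg(treatment)
  if (length(transients) == 0L)
    frrf_stop("frrf_protocol_mismatch", "no transients supplied")
  groups <- group_measurements(transients)
  ctx <- vapply(groups, function(g) g$induction_tr$light_context, "")

  # plain induction fits everywhere first
  ifits <- lapply(groups, function(g)
    tryCatch(fit_induction(g$induction_tr, train, control),
             frrf_error = function(e) NULL))

  dark_ref_idx <- which(ctx == "dark_adapted")
  if (length(dark_ref_idx) != 1L)
    frrf_stop("frrf_protocol_mismatch",
              "expected exactly one dark-adapted reference measurement, found %d",
              length(dark_ref_idx))
  ref_fit <- ifits[[dark_ref_idx]]
  if (is.null(ref_fit) || !isTRUE(ref_fit$converged))
    frrf_stop("frrf_protocol_mismatch", "dark-adapted reference fit failed")
  ref_relax <- if (!is.null(groups[[dark_ref_idx]]$relaxation_tr))
    tryCatch(fit_relaxation(groups[[dark_ref_idx]]$relaxation_tr, ref_fit,
                            control),
             frrf_error = function(e) NULL)
  F0_ref <- ref_fit$F0_hat
  FM_ref <- ref_fit$FM_hat
  sigma_ref <- ref_fit$sigma_hat

  light_idx <- which(ctx == "actinic")
  dark1s_idx <- which(ctx == "dark_1s")
  dark1s_t <- vapply(dark1s_idx, function(i) groups[[i]]$induction_tr$timestamp_s, 0)
  dark1s_used <- logical(length(dark1s_idx))

  light_idx <- light_idx[order(vapply(light_idx, function(i)
    groups[[i]]$induction_tr$timestamp_s, 0))]
  rows <- vector("list", length(light_idx))
  for (i in seq_along(light_idx)) {
    li <- light_idx[i]
    ltr <- groups[[li]]$induction_tr
    lfit <- ifits[[li]]
    t_i <- ltr$timestamp_s
    flags <- character(0)
    r <- list(step_index = i, measurement_id = ltr$measurement_id,
              timestamp_s = t_i, par = ltr$actinic_par,
              FS = NA_real_, FMp = NA_real_, sigma_p = NA_real_,
              rho_p = NA_real_, tau1_light = NA_real_,
              F0p_1s = NA_real_, FMp_1s = NA_real_, sigma_p_1s = NA_real_,
              rho_p_1s = NA_real_, tau1_dark1s = NA_real_,
              F0_ref = F0_ref, FM_ref = FM_ref, sigma_ref = sigma_ref,
              F0p = NA_real_, qP = NA_real_, excitation_pressure = NA_real_,
              Y_PSII = NA_real_, Y_NPQ = NA_real_, Y_NO = NA_real_,
              ETR = NA_real_)
    if (!is.null(lfit)) {
      r$FS <- lfit$FS_hat
      r$FMp <- lfit$FM_hat
      r$sigma_p <- lfit$sigma_hat
      r$rho_p <- lfit$rho_hat
      if (!isTRUE(lfit$converged)) flags <- c(flags, "light_fit_unconverged")
      flags <- c(flags, lfit$flags)
    } else flags <- c(flags, "light_fit_failed")

    # pair with the nearest later dark_1s measurement
    dfit <- NULL; d_i <- NULL
    dt <- dark1s_t - t_i
    cand <- which(dt > 0 & dt <= pair_window_s & !dark1s_used)
    if (length(cand)) {
      j <- cand[which.min(dt[cand])]
      dark1s_used[j] <- TRUE
      d_i <- dark1s_idx[j]
      dfit <- ifits[[d_i]]
      if (!is.null(dfit)) {
        r$F0p_1s <- dfit$F0_hat
        r$FMp_1s <- dfit$FM_hat
        r$sigma_p_1s <- dfit$sigma_hat
        r$rho_p_1s <- dfit$rho_hat
        if (!isTRUE(dfit$converged)) flags <- c(flags, "dark1s_fit_unconverged")
      } else flags <- c(flags, "dark1s_fit_failed")
      if (!is.null(dfit) && isTRUE(dfit$converged) &&
          !is.null(groups[[d_i]]$relaxation_tr)) {
        drel <- tryCatch(fit_relaxation(groups[[d_i]]$relaxation_tr, dfit,
                                        control),
                         frrf_error = function(e) NULL)
        if (!is.null(drel)) r$tau1_dark1s <- drel$tau1_hat
      }
    } else flags <- c(flags, "missing_dark_1s")

    # refine the in-light fit: under actinic light (F0, rho, C_init) sit
    # on a near-flat ridge, so fix rho from the paired 1-s-dark fit and
    # the starting closure from FS via the F0' estimate, leaving
    # (F0, FM', sigma') free
    C_init_est <- 0
    if (!is.null(lfit) && !is.null(dfit) && isTRUE(dfit$converged) &&
        r$par > 0) {
      f0p_pre <- r$F0p_1s * r$FMp / r$FMp_1s
      C_init_est <- closure_from_fluorescence(r$FS, f0p_pre, r$FMp,
                                              dfit$rho_hat)
      C_init_est <- min(max(C_init_est, 0), 0.95)
      refit <- tryCatch(fit_induction(ltr, train, control,
                                      rho_fix = dfit$rho_hat,
                                      C_init = C_init_est),
                        frrf_error = function(e) NULL)
      if (!is.null(refit) && isTRUE(refit$converged)) {
        lfit <- refit
        r$FS <- lfit$FS_hat
        r$FMp <- lfit$FM_hat
        r$sigma_p <- lfit$sigma_hat
        r$rho_p <- lfit$rho_hat
        flags <- c(flags, "inlight_refined")
      }
    }
    if (!is.null(lfit) && isTRUE(lfit$converged) &&
        !is.null(groups[[li]]$relaxation_tr)) {
      lrel <- tryCatch(fit_relaxation(groups[[li]]$relaxation_tr, lfit,
                                      control, C_floor = lfit$C_init),
                       frrf_error = function(e) NULL)
      if (!is.null(lrel)) r$tau1_light <- lrel$tau1_hat
    }

    if (is.finite(r$FS) && is.finite(r$FMp) && is.finite(r$F0p_1s) &&
        is.finite(r$FMp_1s)) {
      f0p <- estimate_F0prime(r$F0p_1s, r$FMp_1s, r$FMp)
      flags <- c(flags, f0p$flags)
      yp <- tryCatch(yield_partition(r$FS, r$FMp, FM_ref, f0p$F0p),
                     frrf_division_degenerate = function(e) NULL)
      if (!is.null(yp)) {
        flags <- c(flags, yp$flags)
        r[c("F0p", "qP", "excitation_pressure", "Y_PSII", "Y_NPQ", "Y_NO")] <-
          yp[c("F0p", "qP", "excitation_pressure", "Y_PSII", "Y_NPQ", "Y_NO")]
        sig <- if (etr_sigma == "in_light") r$sigma_p else r$sigma_p_1s
        r$ETR <- compute_etr(r$par, sig, yp$Y_PSII, F0_ref, FM_ref)
      } else flags <- c(flags, "division_degenerate")
    } else flags <- c(flags, "derived_unavailable")
    r$flags <- paste(unique(flags), collapse = ";")
    rows[[i]] <- as.data.frame(r, stringsAsFactors = FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows) else data.frame()
  structure(list(records = records,
                 dark_reference = list(induction = ref_fit,
                                       relaxation = ref_relax),
                 strain_label = strain_label, treatment = treatment,
                 etr_sigma = etr_sigma),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf("<experiment_table> %s, %s, %d light steps; dark ref: F0=%.4g FM=%.4g sigma=%.4g\n",
              x$strain_label, x$treatment, nrow(x$records),
              x$dark_reference$induction$F0_hat,
              x$dark_reference$induction$FM_hat,
              x$dark_reference$induction$sigma_hat))
  invisible(x)
}

#' First-visit vs revisit ETR at repeated light levels
#'
#' For every PAR value visited more than once in a non-sequential rapid
#' light curve, compares the ETR measured at the first visit with the ETR
#' at the revisit (second visit, in step order). A ratio above 1 reveals
#' upregulation of electron transport driven by the immediate light
#' history; static physiology gives a ratio of 1 within fit noise.
#'
#' @param table an [pair_measurements()] `experiment_table`
#' @return data.frame with `par`, `first_visit_ETR`, `revisit_ETR`,
#'   `ratio` (revisit / first) and `n_visits`; attribute `"visits"` holds
#'   all visit ETRs per PAR
#' @export
upregulation_index <- function(table) {
  rec <- table$records
  rec <- rec[rec$par > 0 & is.finite(rec$ETR), , drop = FALSE]
  visits <- split(rec[order(rec$step_index), ], rec$par[order(rec$step_index)])
  visits <- visits[vapply(visits, nrow, 0L) >= 2L]
  if (!length(visits))
    frrf_stop("frrf_no_revisit", "no PAR level is visited more than once")
  out <- do.call(rbind, lapply(visits, function(v)
    data.frame(par = v$par[1], first_visit_ETR = v$ETR[1],
               revisit_ETR = v$ETR[2], ratio = v$ETR[2] / v$ETR[1],
               n_visits = nrow(v))))
  out <- out[order(out$par), ]
  rownames(out) <- NULL
  attr(out, "visits") <- lapply(visits, function(v) v$ETR)
  out
}
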