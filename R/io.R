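TRANSIENT_COLUMNS <- c("measurement_id", "timestamp_s", "light_context",
                       "actinic_par", "phase", "time_us", "fluorescence")

provenance_header <- function(config = NULL, seed = NULL) {
  version <- tryCatch(as.character(utils::packageVersion("frrfit")),
                      error = function(e) "dev")
  lines <- c(sprintf("# frrfit version: %s", version))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config)) lines <- c(lines, sprintf("# config sha: %s",
                                                  config_hash(config)))
  lines
}

#' Hash a configuration object
#'
#' MD5 digest of the canonical JSON serialization; recorded in all output
#' provenance headers so runs can be matched to their configuration.
#'
#' @param config any jsonlite-serializable object
#' @return hex digest string
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write FRRf transients to the delimited interchange format
#'
#' One row per sample point, columns `measurement_id, timestamp_s,
#' light_context, actinic_par, phase, time_us, fluorescence`; preceded by
#' `#` provenance header lines (package version, seed, config hash).
#'
#' @param transients list of [frrf_transient()]
#' @param path output CSV path
#' @param config,seed optional provenance
#' @return `path`, invisibly
#' @export
write_transients <- function(transients, path, config = NULL, seed = NULL) {
  tab <- do.call(rbind, lapply(transients, function(tr)
    data.frame(measurement_id = tr$measurement_id,
               timestamp_s = tr$timestamp_s,
               light_context = tr$light_context,
               actinic_par = tr$actinic_par, phase = tr$phase,
               time_us = tr$times, fluorescence = tr$fluorescence)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, seed), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read FRRf transients from the delimited interchange format
#'
#' Validates the column contract and per-measurement time ordering;
#' malformed content is reported with file line numbers.
#'
#' @param path CSV path as written by [write_transients()] (or exported
#'   from instrument software and munged into the same columns)
#' @return list of [frrf_transient()]
#' @export
read_transients <- function(path) {
  if (!file.exists(path))
    frrf_stop("frrf_format_error", "file not found: %s", path)
  raw <- readLines(path)
  skip <- 0L
  while (skip < length(raw) && startsWith(raw[skip + 1L], "#")) skip <- skip + 1L
  tab <- tryCatch(
    utils::read.csv(text = raw[(skip + 1L):length(raw)],
                    stringsAsFactors = FALSE),
    error = function(e) frrf_stop("frrf_format_error",
                                  "cannot parse %s: %s", path, conditionMessage(e)))
  missing <- setdiff(TRANSIENT_COLUMNS, names(tab))
  if (length(missing))
    frrf_stop("frrf_format_error", "missing column(s): %s",
              paste(missing, collapse = ", "))
  header_line <- skip + 1L
  bad_num <- which(!is.finite(suppressWarnings(as.numeric(tab$fluorescence))) |
                     !is.finite(suppressWarnings(as.numeric(tab$time_us))))
  if (length(bad_num))
    frrf_stop("frrf_format_error", "non-numeric time/fluorescence at line(s) %s",
              paste(utils::head(bad_num + header_line, 5), collapse = ", "))
  key <- paste(tab$measurement_id, tab$light_context, tab$phase, sep = "|")
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    sub <- tab[idx, ]
    if (any(diff(sub$time_us) <= 0))
      frrf_stop("frrf_format_error",
                "times not strictly increasing within measurement %s (near line %d)",
                k, idx[which(diff(sub$time_us) <= 0)[1] + 1L] + header_line)
    out[[k]] <- frrf_transient(sub$time_us, sub$fluorescence,
                               phase = sub$phase[1],
                               light_context = sub$light_context[1],
                               actinic_par = sub$actinic_par[1],
                               measurement_id = sub$measurement_id[1],
                               timestamp_s = sub$timestamp_s[1])
  }
  unname(out)
}

#' Write an experiment table as tidy per-step CSV
#'
#' @param table an `experiment_table`
#' @param path output CSV path
#' @param config,seed optional provenance
#' @return `path`, invisibly
#' @export
write_records <- function(table, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_header(config, seed),
               sprintf("# strain: %s; treatment: %s; dark ref F0=%.8g FM=%.8g sigma=%.8g",
                       table$strain_label, table$treatment,
                       table$dark_reference$induction$F0_hat,
                       table$dark_reference$induction$FM_hat,
                       table$dark_reference$induction$sigma_hat)), con)
  utils::write.csv(table$records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The complete, schema-checked configuration consumed by the command
#' line: protocol (design and light steps), flashlet train, generator
#' parameters, fit tolerances and the experiment seed.
#'
#' @return nested list of class `run_config`
#' @export
default_run_config <- function() {
  seq <- default_rlc_sequence()
  structure(list(
    design = seq$design,
    steps = list(par = seq$steps$par, duration_s = seq$steps$duration_s),
    dark_adapt_s = seq$dark_adapt_s,
    step_offset_s = seq$step_offset_s,
    meas_interval_s = seq$meas_interval_s,
    train = list(n_flashlets = 40L, flashlet_duration = 1.2,
                 gap_duration = 1.0, dose_per_flashlet = NA,
                 wavelength_nm = 455),
    generator = unclass(generator_config())[setdiff(names(generator_config()), "seed")],
    fit = list(rel_tol = 1e-10, max_iter = 500, rho_max = 0.8,
               sigma_factor = 10),
    treatment = "control",
    seed = 1L), class = "run_config")
}

validate_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    frrf_stop("frrf_format_error", "unknown key(s) in %s: %s", where,
              paste(unknown, collapse = ", "))
}

#' Read and validate a run configuration JSON file
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_run_config()].
#'
#' @param path JSON file
#' @return a validated `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    frrf_stop("frrf_format_error", "config file not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  def <- default_run_config()
  validate_keys(cfg, names(def), "config")
  for (section in c("steps", "train", "generator", "fit"))
    if (!is.null(cfg[[section]]))
      validate_keys(cfg[[section]], names(def[[section]]), section)
  out <- utils::modifyList(unclass(def), cfg)
  if (!out$design %in% c("nonsequential_rlc", "induction_recovery"))
    frrf_stop("frrf_format_error", "unknown design: %s", out$design)
  if (!out$treatment %in% c("control", "dtt"))
    frrf_stop("frrf_format_error", "unknown treatment: %s", out$treatment)
  structure(out, class = "run_config")
}

#' Write a run configuration to JSON
#'
#' @param config a `run_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA), path)
  invisible(path)
}

# materialize domain objects from a run_config
config_objects <- function(cfg) {
  sequence <- light_sequence(cfg$steps$par, cfg$steps$duration_s,
                             design = cfg$design,
                             dark_adapt_s = cfg$dark_adapt_s,
                             step_offset_s = cfg$step_offset_s,
                             meas_interval_s = cfg$meas_interval_s)
  gen <- do.call(generator_config,
                 c(list(seed = cfg$seed),
                   cfg$generator[names(cfg$generator) != "seed"],
                   if (cfg$treatment == "dtt") list(dtt_mode = TRUE)))
  dose <- cfg$train$dose_per_flashlet
  if (is.null(dose) || !is.finite(dose))
    dose <- calibrate_dose(gen$sigma_dark, 30, 0.98)
  train <- flashlet_train(cfg$train$n_flashlets, cfg$train$flashlet_duration,
                          cfg$train$gap_duration, dose,
                          cfg$train$wavelength_nm)
  control <- do.call(fit_control, cfg$fit)
  list(sequence = sequence, generator = gen, train = train,
       control = control, treatment = cfg$treatment)
}
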