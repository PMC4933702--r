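#' Resolved run configuration
#'
#' Bundles every tunable of the pipeline — kinetic constants, binding
#' window, repeat-number range and seed — into a single serializable
#' object. The defaults reproduce the model's reference setup:
#' `beta = 0.0366`, 2x slowdown, window codons 53-72, repeat range 40-53.
#'
#' @param k_on Effective first-order on-rate, s^-1.
#' @param tau_a Fast-codon time, seconds.
#' @param slowdown_s Proline slowdown factor.
#' @param window_first,window_last Binding-window codon bounds.
#' @param n_cag_min,n_cag_max Repeat-number range for curve/correlation.
#' @param seed Integer seed for all stochastic stages.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(k_on = 0.0366, tau_a = 1, slowdown_s = 2,
                       window_first = 53L, window_last = 72L,
                       n_cag_min = 40L, n_cag_max = 53L, seed = 1L) {
  params <- kinetic_params(k_on, tau_a, slowdown_s)   # validates
  window <- binding_window(window_first, window_last) # validates
  structure(
    list(
      k_on = k_on, tau_a = tau_a, slowdown_s = slowdown_s,
      window_first = window$first_codon, window_last = window$last_codon,
      n_cag_min = as.integer(n_cag_min), n_cag_max = as.integer(n_cag_max),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

config_params <- function(config) {
  kinetic_params(config$k_on, config$tau_a, config$slowdown_s)
}

config_window <- function(config) {
  binding_window(config$window_first, config$window_last)
}

#' Serialize / deserialize a run configuration
#'
#' JSON round trip: `read_run_config(write_run_config(cfg, path))` is
#' identical to `cfg`, so every run is reproducible from its emitted
#' configuration alone.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `write_run_config`: `path`, invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    k_on = as.numeric(x$k_on), tau_a = as.numeric(x$tau_a),
    slowdown_s = as.numeric(x$slowdown_s),
    window_first = x$window_first, window_last = x$window_last,
    n_cag_min = x$n_cag_min, n_cag_max = x$n_cag_max, seed = x$seed
  )
}

finish_run <- function(config, outdir) {
  write_run_config(config, file.path(outdir, "run_config.json"))
}

#' Run the misprocessing-curve stage
#'
#' Computes the f_mp curve over the configured repeat range, writes it as
#' `curve.csv` (with a JSON parameter sidecar), writes the f_mp vs N_CAG
#' correlation as `summary.json`, and records the resolved configuration
#' as `run_config.json`.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the `curve` and the `correlation`.
#' @export
run_curve <- function(config = run_config(), outdir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  curve <- misprocessing_curve(config$n_cag_min, config$n_cag_max,
                               config_params(config), config_window(config))
  cor_res <- correlate_fmp_vs_ncag(config$n_cag_min, config$n_cag_max,
                                   config_params(config), config_window(config))
  write_curve_csv(curve, file.path(outdir, "curve.csv"))
  jsonlite::write_json(
    list(r = cor_res$r, r_squared = cor_res$r_squared,
         p_value = cor_res$p_value, n = cor_res$n,
         slope = cor_res$slope, intercept = cor_res$intercept),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  finish_run(config, outdir)
  invisible(list(curve = curve, correlation = cor_res))
}

#' Run the onset-correlation stage
#'
#' @param config A `run_config`.
#' @param onset Onset data frame or path to an onset CSV.
#' @param outdir Output directory.
#' @param aggregate Passed to [correlate_onset_vs_fmp()].
#' @return Invisibly, the `correlation_result`.
#' @export
run_correlate <- function(config = run_config(), onset, outdir = ".",
                          aggregate = c("none", "mean")) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(onset)) onset <- read_onset_csv(onset)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- correlate_onset_vs_fmp(onset, config_params(config),
                                config_window(config), aggregate)
  jsonlite::write_json(
    list(r = res$r, r_squared = res$r_squared, p_value = res$p_value,
         n = res$n, slope = res$slope, intercept = res$intercept),
    file.path(outdir, "onset_correlation.json"), auto_unbox = TRUE, digits = NA
  )
  finish_run(config, outdir)
  invisible(res)
}

#' Run the Monte-Carlo validation stage
#'
#' @param config A `run_config`; its `seed` drives the simulation.
#' @param n_ribosomes Replicate count.
#' @param dwell_model `"fixed"` or `"exponential"`.
#' @param n_cag Repeat number to simulate (default: the configured
#'   minimum).
#' @param outdir Output directory.
#' @return Invisibly, the comparison tibble from [compare_to_analytic()].
#' @export
run_simulate <- function(config = run_config(), n_ribosomes = 10000L,
                         dwell_model = c("fixed", "exponential"),
                         n_cag = NULL, outdir = ".") {
  stopifnot(inherits(config, "run_config"))
  dwell_model <- match.arg(dwell_model)
  if (is.null(n_cag)) n_cag <- config$n_cag_min
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rep_tbl <- compare_to_analytic(n_cag, n_ribosomes, config$seed, dwell_model,
                                 config_params(config), config_window(config))
  jsonlite::write_json(as.list(rep_tbl), file.path(outdir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA)
  finish_run(config, outdir)
  invisible(rep_tbl)
}

#' Run the effective-on-rate stage
#'
#' Either give `concentration` directly, or give a `chaperones` table (or
#' CSV path) from which the cytosolic/nuclear median concentration is
#' taken.
#'
#' @param rate Bimolecular rate constant, M^-1 s^-1.
#' @param concentration Factor concentration, molar (optional).
#' @param chaperones Chaperone table or CSV path (optional).
#' @param compartments Compartment filter for the median.
#' @param outdir Output directory.
#' @return Invisibly, the effective rate (s^-1).
#' @export
run_kon <- function(rate = 3.3e5, concentration = NULL, chaperones = NULL,
                    compartments = c("cytosolic", "nuclear"), outdir = ".") {
  if (is.null(concentration)) {
    if (is.null(chaperones)) {
      stop("Give either `concentration` or `chaperones`.", call. = FALSE)
    }
    if (is.character(chaperones)) chaperones <- read_chaperone_csv(chaperones)
    concentration <- median_cytoplasmic_concentration(chaperones, compartments)
  }
  kon <- effective_kon(rate, concentration)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(rate_m1s1 = rate, concentration_molar = concentration,
         k_on_s1 = kon),
    file.path(outdir, "kon.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(kon)
}

#' Run the slowdown sensitivity stage
#'
#' @param config A `run_config`.
#' @param s_values Slowdown factors to scan.
#' @param outdir Output directory.
#' @return Invisibly, the scan tibble.
#' @export
run_sensitivity <- function(config = run_config(), s_values = 2:6,
                            outdir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scan <- sensitivity_scan(s_values, config$n_cag_min, config$n_cag_max,
                           config_params(config), config_window(config))
  readr::write_csv(scan, file.path(outdir, "sensitivity.csv"))
  finish_run(config, outdir)
  invisible(scan)
}

#' Run the synthetic-data stage
#'
#' Generates and writes `onset.csv` and `chaperones.csv` under `outdir`.
#'
#' @param config A `run_config`; its range and seed feed the generators.
#' @param outdir Output directory.
#' @param ... Further arguments to [generate_onset_dataset()].
#' @return Invisibly, a list with `onset` and `chaperones` tibbles.
#' @export
run_synth <- function(config = run_config(), outdir = ".", ...) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  onset <- generate_onset_dataset(
    n_cag_min = config$n_cag_min, n_cag_max = config$n_cag_max,
    seed = config$seed, ...
  )
  chap <- generate_chaperone_table(seed = config$seed)
  write_onset_csv(onset, file.path(outdir, "onset.csv"))
  write_chaperone_csv(chap, file.path(outdir, "chaperones.csv"))
  finish_run(config, outdir)
  invisible(list(onset = onset, chaperones = chap))
}
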