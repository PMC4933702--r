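#' Generate a synthetic age-of-onset dataset
#'
#' Emulates the clinical repeat-number/onset relationship: onset age
#' declines by `slope` years per added CAG repeat (default -3, the
#' roughly-3-years-per-repeat decline seen beyond the 35-repeat disease
#' threshold) from `base_age` at `n_cag_min`, with additive Gaussian noise
#' and truncation at 1 year to avoid nonphysical ages. An optional
#' exponential-decline mode (`age = exp_a + exp_b * exp(-exp_c * (n - 35))`)
#' mimics the curvature of observed repeat-length/onset curves; it is off
#' by default. Output is deterministic given `seed`.
#'
#' @param n_cag_min,n_cag_max Integer repeat-number range, `min >= 36`.
#' @param records_per_repeat Records per repeat number, >= 1.
#' @param base_age Mean onset age (years) at `n_cag_min` (linear mode).
#' @param slope Years of onset change per added repeat (linear mode).
#' @param noise_sd Standard deviation of additive age noise, years, >= 0.
#' @param seed Integer RNG seed.
#' @param decline `"linear"` (default) or `"exponential"`.
#' @param exp_a,exp_b,exp_c Exponential-mode parameters: asymptotic age,
#'   amplitude and per-repeat decay rate.
#' @return A tibble with columns `n_cag` (integer) and `onset_age_years`,
#'   carrying attribute `provenance = "synthetic"`.
#' @examples
#' generate_onset_dataset(40, 45, noise_sd = 0, base_age = 60)
#' @export
generate_onset_dataset <- function(n_cag_min = 40L, n_cag_max = 53L,
                                   records_per_repeat = 1L,
                                   base_age = 60, slope = -3,
                                   noise_sd = 3, seed = 1L,
                                   decline = c("linear", "exponential"),
                                   exp_a = 20, exp_b = 70, exp_c = 0.08) {
  decline <- match.arg(decline)
  if (!is.numeric(n_cag_min) || !is.numeric(n_cag_max) ||
      length(n_cag_min) != 1L || length(n_cag_max) != 1L ||
      is.na(n_cag_min) || is.na(n_cag_max) ||
      n_cag_min != as.integer(n_cag_min) || n_cag_max != as.integer(n_cag_max) ||
      n_cag_min < 36 || n_cag_min > n_cag_max) {
    stop("Need integer bounds with 36 <= n_cag_min <= n_cag_max.",
         call. = FALSE)
  }
  if (!is.numeric(records_per_repeat) || length(records_per_repeat) != 1L ||
      is.na(records_per_repeat) || records_per_repeat < 1 ||
      records_per_repeat != as.integer(records_per_repeat)) {
    stop("`records_per_repeat` must be a single integer >= 1.", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number.", call. = FALSE)
  }
  n_vals <- seq.int(as.integer(n_cag_min), as.integer(n_cag_max))
  n_cag <- rep(n_vals, each = as.integer(records_per_repeat))
  mean_age <- switch(
    decline,
    linear = base_age + slope * (n_cag - n_cag_min),
    exponential = exp_a + exp_b * exp(-exp_c * (n_cag - 35))
  )
  set.seed(as.integer(seed))
  age <- mean_age + stats::rnorm(length(n_cag), mean = 0, sd = noise_sd)
  age <- pmax(age, 1)
  structure(
    tibble::tibble(n_cag = as.integer(n_cag), onset_age_years = age),
    provenance = "synthetic"
  )
}

#' Generate a synthetic chaperone concentration table
#'
#' Produces a table with the structure of a HeLa chaperone abundance
#' survey: one record per chaperone with a compartment label and a
#' positive molar concentration. Concentrations are log-normal; after
#' generation all concentrations are rescaled so the median over the
#' cytosolic plus nuclear subset equals `target_median` exactly (the
#' median is positively homogeneous, so a single multiplicative rescale
#' suffices). Defaults pin the 109-record cytosolic/nuclear subset and
#' its 1.11e-7 M median used to form the effective in-vivo on-rate. The
#' table is synthetic: record identities and the concentration spread are
#' generated, not measured.
#'
#' @param n_records Number of records, >= 1, default 109.
#' @param target_median Target median (molar) of the cytosolic/nuclear
#'   subset, > 0, default 1.11e-7.
#' @param dispersion Log-scale standard deviation of the concentrations.
#' @param compartment_mix Named numeric vector of compartment proportions;
#'   must give the cytosolic + nuclear subset nonzero mass.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `name`, `compartment` and
#'   `concentration_molar`, attribute `provenance = "synthetic"`.
#' @examples
#' tab <- generate_chaperone_table(seed = 7)
#' median_cytoplasmic_concentration(tab) # 1.11e-7 exactly
#' @export
generate_chaperone_table <- function(n_records = 109L,
                                     target_median = 1.11e-7,
                                     dispersion = 1,
                                     compartment_mix = c(cytosolic = 0.6,
                                                         nuclear = 0.4),
                                     seed = 1L) {
  if (!is.numeric(n_records) || length(n_records) != 1L || is.na(n_records) ||
      n_records < 1 || n_records != as.integer(n_records)) {
    stop("`n_records` must be a single integer >= 1.", call. = FALSE)
  }
  if (!is.numeric(target_median) || length(target_median) != 1L ||
      is.na(target_median) || target_median <= 0) {
    stop("`target_median` must be a single positive concentration.",
         call. = FALSE)
  }
  if (is.null(names(compartment_mix)) || any(compartment_mix < 0) ||
      sum(compartment_mix) <= 0) {
    stop("`compartment_mix` must be a named vector of non-negative ",
         "proportions.", call. = FALSE)
  }
  cyt_nuc <- c("cytosolic", "nuclear")
  if (sum(compartment_mix[names(compartment_mix) %in% cyt_nuc]) <= 0) {
    stop("`compartment_mix` must give cytosolic/nuclear records nonzero ",
         "probability: the target median is defined over that subset.",
         call. = FALSE)
  }
  n_records <- as.integer(n_records)
  set.seed(as.integer(seed))
  compartment <- sample(names(compartment_mix), n_records, replace = TRUE,
                        prob = compartment_mix / sum(compartment_mix))
  # Guarantee the defining subset is non-empty even at small n_records.
  if (!any(tolower(compartment) %in% cyt_nuc)) {
    compartment[1] <- "cytosolic"
  }
  conc <- stats::rlnorm(n_records, meanlog = log(target_median),
                        sdlog = dispersion)
  in_subset <- tolower(compartment) %in% cyt_nuc
  subset_median <- stats::median(conc[in_subset])
  conc <- conc * (target_median / subset_median)
  # For odd-sized subsets the median is a sample point: snap it so the
  # subset median equals the target exactly, not merely to rounding error.
  idx <- which(in_subset)
  if (length(idx) %% 2L == 1L) {
    mid <- idx[order(conc[idx])][(length(idx) + 1L) %/% 2L]
    conc[mid] <- target_median
  }
  structure(
    tibble::tibble(
      name = sprintf("CHAP%03d", seq_len(n_records)),
      compartment = compartment,
      concentration_molar = conc
    ),
    provenance = "synthetic"
  )
}

#' Write an onset dataset as CSV
#'
#' CSV dialect with header `n_cag,onset_age_years`.
#'
#' @param onset Data frame with the onset columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_onset_csv <- function(onset, path) {
  stopifnot(is.data.frame(onset))
  readr::write_csv(onset[, c("n_cag", "onset_age_years")], path)
  invisible(path)
}
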