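#' Effective in-vivo first-order association rate
#'
#' Converts a bimolecular association rate constant (M^-1 s^-1) into an
#' effective pseudo-first-order rate (s^-1) by multiplying by the
#' intracellular concentration of the binding factor. The model's default
#' `k_on = 0.0366 s^-1` arises from the DnaJ on-rate of 3.3e5 M^-1 s^-1
#' and the 1.11e-7 M median cytosolic/nuclear chaperone concentration in
#' HeLa cells; DnaJ is an order-of-magnitude stand-in since the actual
#' co-translationally acting factor is not identified, so all inputs are
#' exposed rather than hard-coded.
#'
#' @param rate Bimolecular rate constant, M^-1 s^-1, > 0.
#' @param concentration Factor concentration, molar, > 0.
#' @return Effective first-order rate, s^-1.
#' @examples
#' effective_kon(3.3e5, 1.11e-7) # 0.0366 s^-1 to 3 s.f.
#' @export
effective_kon <- function(rate, concentration) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("`rate` must be a single positive bimolecular rate (M^-1 s^-1).",
         call. = FALSE)
  }
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    stop("`concentration` must be a single positive molar concentration.",
         call. = FALSE)
  }
  rate * concentration
}

#' Median concentration of cytosolic/nuclear chaperones
#'
#' Takes the median concentration over the chaperone records whose
#' compartment matches the filter (case-insensitively). For even-sized
#' selections the median is the midpoint of the two central values
#' (`stats::median` convention).
#'
#' @param chaperones Data frame with columns `name`, `compartment` and
#'   `concentration_molar` (all concentrations > 0), as produced by
#'   [generate_chaperone_table()] or [read_chaperone_csv()].
#' @param compartments Character vector of compartment labels to keep;
#'   default cytosolic and nuclear.
#' @return Median concentration (molar) of the matching records.
#' @export
median_cytoplasmic_concentration <- function(chaperones,
                                             compartments = c("cytosolic", "nuclear")) {
  stopifnot(is.data.frame(chaperones))
  required <- c("compartment", "concentration_molar")
  missing_cols <- setdiff(required, names(chaperones))
  if (length(missing_cols) > 0) {
    stop("`chaperones` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(chaperones$concentration_molar <= 0, na.rm = TRUE)) {
    stop("All concentrations must be positive.", call. = FALSE)
  }
  keep <- tolower(chaperones$compartment) %in% tolower(compartments)
  if (!any(keep)) {
    stop("No chaperone records match compartment filter {",
         paste(compartments, collapse = ", "), "}.", call. = FALSE)
  }
  stats::median(chaperones$concentration_molar[keep])
}

#' Convert per-cell copy numbers to molar concentration
#'
#' `copies / (N_A * V)` with the cell volume in cubic micrometres
#' (1 um^3 = 1e-15 L). The default volume is the 2600 um^3 average HeLa
#' cell volume used for the chaperone abundance conversion.
#'
#' @param copies Copy number per cell, >= 0 (vectorized).
#' @param volume_um3 Cell volume in um^3, > 0.
#' @return Concentration in molar.
#' @examples
#' copies_to_concentration(1, 2600) # ~6.39e-13 M
#' @export
copies_to_concentration <- function(copies, volume_um3 = 2600) {
  if (!is.numeric(copies) || anyNA(copies) || any(copies < 0)) {
    stop("`copies` must be non-negative.", call. = FALSE)
  }
  if (!is.numeric(volume_um3) || length(volume_um3) != 1L ||
      is.na(volume_um3) || volume_um3 <= 0) {
    stop("`volume_um3` must be a single positive volume.", call. = FALSE)
  }
  avogadro <- 6.02214076e23
  copies / (avogadro * volume_um3 * 1e-15)
}

#' Read / write a chaperone concentration table
#'
#' CSV dialect with header `name,compartment,concentration_molar`.
#'
#' @param path File path.
#' @return `read_chaperone_csv`: a tibble; `write_chaperone_csv`: `path`,
#'   invisibly.
#' @export
read_chaperone_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(),
    compartment = readr::col_character(),
    concentration_molar = readr::col_double()
  ))
}

#' @rdname read_chaperone_csv
#' @param chaperones Data frame with the table columns.
#' @export
write_chaperone_csv <- function(chaperones, path) {
  stopifnot(is.data.frame(chaperones))
  readr::write_csv(
    chaperones[, c("name", "compartment", "concentration_molar")], path
  )
  invisible(path)
}
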