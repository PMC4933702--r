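#' Exon-1 codon layout for a given CAG-repeat number
#'
#' Builds the codon-position layout of the huntingtin exon-1 construct:
#' the 17-codon N17 localization signal (codons 1-17), the polyglutamine
#' tract of `n_cag` CAG repeats (codons 18 to 17 + `n_cag`), and the
#' 38-codon proline-rich region immediately downstream (codons
#' 18 + `n_cag` to 55 + `n_cag`). Positions are 1-based and region spans
#' are closed intervals, so for the reference repeat number `n_cag = 35`
#' the proline-rich region starts at codon 53.
#'
#' @param n_cag Integer CAG-repeat count, at least 1.
#' @return An object of class `htt_construct`: a list with elements
#'   `n17_len`, `n_cag`, `pro_region_len`, `polyq_start`, `polyq_end`,
#'   `pro_start`, `pro_end` and `length` (the last modeled codon).
#' @examples
#' build_construct(35) # proline-rich region spans codons 53..90
#' @export
build_construct <- function(n_cag) {
  if (length(n_cag) != 1L || !is.numeric(n_cag) || is.na(n_cag) ||
      n_cag < 1 || n_cag != as.integer(n_cag)) {
    stop("`n_cag` must be a single positive integer (>= 1).", call. = FALSE)
  }
  n_cag <- as.integer(n_cag)
  structure(
    list(
      n17_len = 17L,
      n_cag = n_cag,
      pro_region_len = 38L,
      polyq_start = 18L,
      polyq_end = 17L + n_cag,
      pro_start = 18L + n_cag,
      pro_end = 55L + n_cag,
      length = 55L + n_cag
    ),
    class = "htt_construct"
  )
}

#' @export
print.htt_construct <- function(x, ...) {
  cat("<htt_construct> exon-1 layout, N_CAG =", x$n_cag, "\n")
  cat("  N17   : codons 1..17\n")
  cat("  polyQ : codons ", x$polyq_start, "..", x$polyq_end, "\n", sep = "")
  cat("  polyP : codons ", x$pro_start, "..", x$pro_end, "\n", sep = "")
  invisible(x)
}

region_of <- function(construct, position) {
  dplyr::case_when(
    position <= construct$n17_len ~ "N17",
    position <= construct$polyq_end ~ "polyQ",
    TRUE ~ "polyP"
  )
}

#' Classify codons as fast- or slow-translating
#'
#' Every codon of the construct maps to exactly one dwell class: codons in
#' the proline-rich region are slow-translating ("SLOW"), all others (N17
#' and polyglutamine) are fast-translating ("FAST").
#'
#' @param construct An `htt_construct` from [build_construct()].
#' @param position Integer vector of 1-based codon positions, each within
#'   `1..construct$length`.
#' @return Character vector, `"FAST"` or `"SLOW"`, one entry per position.
#' @examples
#' classify_codon(build_construct(35), c(52, 53)) # "FAST" "SLOW"
#' @export
classify_codon <- function(construct, position) {
  stopifnot(inherits(construct, "htt_construct"))
  if (!is.numeric(position) || anyNA(position) ||
      any(position < 1 | position > construct$length) ||
      any(position != as.integer(position))) {
    stop("`position` must be integer codon indices within 1..",
         construct$length, ".", call. = FALSE)
  }
  ifelse(position >= construct$pro_start, "SLOW", "FAST")
}

#' Per-codon translation dwell-time schedule
#'
#' Converts an exon-1 layout into a per-codon dwell-time schedule under the
#' two-class elongation model: fast codons are decoded in time `tau_a`,
#' slow (proline-region) codons in `slowdown_s * tau_a`. The literature
#' places the proline slowdown between 2x and 6x the average codon time;
#' the model's default is the conservative 2x.
#'
#' @param construct An `htt_construct` from [build_construct()].
#' @param slowdown_s Dimensionless slowdown factor for slow codons, >= 1.
#' @param tau_a Fast-codon decoding time in seconds, > 0. The schedule also
#'   carries dwell times in units of `tau_a` so downstream kinetics can work
#'   with the dimensionless rate `beta = k_on * tau_a`.
#' @return A tibble of class `htt_schedule` with one row per codon and
#'   columns `codon_position`, `region` (N17/polyQ/polyP), `class`
#'   (FAST/SLOW), `dwell_tau_a` (units of `tau_a`) and `dwell_sec`.
#'   Attributes `n_cag`, `slowdown_s` and `tau_a` record the inputs.
#' @examples
#' sched <- build_schedule(build_construct(35), slowdown_s = 2)
#' sched$dwell_tau_a[53] # 2: first proline-region codon
#' @export
build_schedule <- function(construct, slowdown_s = 2, tau_a = 1) {
  stopifnot(inherits(construct, "htt_construct"))
  if (!is.numeric(slowdown_s) || length(slowdown_s) != 1L || is.na(slowdown_s) ||
      slowdown_s < 1) {
    stop("`slowdown_s` must be a single number >= 1.", call. = FALSE)
  }
  if (!is.numeric(tau_a) || length(tau_a) != 1L || is.na(tau_a) || tau_a <= 0) {
    stop("`tau_a` must be a single positive number (seconds).", call. = FALSE)
  }
  position <- seq_len(construct$length)
  cls <- classify_codon(construct, position)
  dwell <- ifelse(cls == "SLOW", slowdown_s, 1)
  out <- tibble::tibble(
    codon_position = position,
    region = region_of(construct, position),
    class = cls,
    dwell_tau_a = dwell,
    dwell_sec = dwell * tau_a
  )
  structure(
    out,
    n_cag = construct$n_cag,
    slowdown_s = slowdown_s,
    tau_a = tau_a,
    class = c("htt_schedule", class(out))
  )
}

#' Write a translation schedule as TSV
#'
#' @param schedule An `htt_schedule` from [build_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "htt_schedule"))
  readr::write_tsv(
    schedule[, c("codon_position", "region", "class", "dwell_tau_a")],
    path
  )
  invisible(path)
}
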