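#' Co-translational factor binding window
#'
#' The nascent-chain interval in which the co-translationally acting factor
#' (CAF) can associate with N17: the first-order on-rate is nonzero only
#' while the ribosome decodes codons `first_codon..last_codon` (closed
#' interval). Defaults to codons 53-72, the position at which the ribosome
#' first meets the proline-rich region in the reference Q35 construct,
#' extended over the ~20-residue span in which factors such as SRP bind
#' nascent chains with optimal affinity.
#'
#' @param first_codon First codon of the window (1-based), default 53.
#' @param last_codon Last codon of the window, inclusive, default 72.
#' @return An object of class `binding_window` with elements `first_codon`,
#'   `last_codon` and `width`.
#' @export
binding_window <- function(first_codon = 53L, last_codon = 72L) {
  if (!is.numeric(first_codon) || !is.numeric(last_codon) ||
      length(first_codon) != 1L || length(last_codon) != 1L ||
      is.na(first_codon) || is.na(last_codon) ||
      first_codon < 1 || first_codon != as.integer(first_codon) ||
      last_codon != as.integer(last_codon) || first_codon > last_codon) {
    stop("Window bounds must be integers with 1 <= first_codon <= last_codon.",
         call. = FALSE)
  }
  structure(
    list(
      first_codon = as.integer(first_codon),
      last_codon = as.integer(last_codon),
      width = as.integer(last_codon - first_codon + 1)
    ),
    class = "binding_window"
  )
}

#' Kinetic parameters of the binding model
#'
#' Bundles the rate and time constants of the misprocessing model: the
#' effective in-vivo first-order association rate `k_on` (per second), the
#' fast-codon decoding time `tau_a` (seconds) and the proline slowdown
#' factor `slowdown_s`. Binding is irreversible inside the window, so no
#' off-rate is exposed. The derived dimensionless per-codon rate is
#' `beta = k_on * tau_a`; with the defaults `beta = 0.0366`, the value that
#' the effective-rate estimate [effective_kon()] produces from the DnaJ
#' bimolecular rate and the median cytosolic/nuclear chaperone
#' concentration.
#'
#' @param k_on First-order association rate, per second, >= 0.
#' @param tau_a Fast-codon decoding time, seconds, > 0.
#' @param slowdown_s Slowdown factor for proline-region codons, >= 1.
#' @return An object of class `kinetic_params` with elements `k_on`,
#'   `tau_a`, `slowdown_s` and `beta`.
#' @export
kinetic_params <- function(k_on = 0.0366, tau_a = 1, slowdown_s = 2) {
  if (!is.numeric(k_on) || length(k_on) != 1L || is.na(k_on) || k_on < 0) {
    stop("`k_on` must be a single non-negative rate (per second).",
         call. = FALSE)
  }
  if (!is.numeric(tau_a) || length(tau_a) != 1L || is.na(tau_a) || tau_a <= 0) {
    stop("`tau_a` must be a single positive time (seconds).", call. = FALSE)
  }
  if (!is.numeric(slowdown_s) || length(slowdown_s) != 1L ||
      is.na(slowdown_s) || slowdown_s < 1) {
    stop("`slowdown_s` must be a single number >= 1.", call. = FALSE)
  }
  structure(
    list(k_on = k_on, tau_a = tau_a, slowdown_s = slowdown_s,
         beta = k_on * tau_a),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> k_on =", x$k_on, "s^-1, tau_a =", x$tau_a,
      "s, slowdown_s =", x$slowdown_s, "(beta =", x$beta, ")\n")
  invisible(x)
}

#' Time available for factor binding (tau_AFB)
#'
#' Sums the per-codon dwell times over the binding window: the total time
#' the ribosome-nascent-chain complex spends in the interval where factor
#' association is permitted. With the default window (codons 53-72) and a
#' 2x slowdown, tau_AFB falls from 40 tau_A at the reference repeat number
#' 35 by one tau_A per added repeat, reaching its minimum of 20 tau_A at
#' repeat number 55, where the window contains only fast codons.
#'
#' @param schedule An `htt_schedule` from [build_schedule()].
#' @param window A `binding_window`.
#' @return Total dwell time over the window, in units of `tau_a`.
#' @examples
#' tau_afb(build_schedule(build_construct(35)), binding_window()) # 40
#' @export
tau_afb <- function(schedule, window = binding_window()) {
  stopifnot(inherits(schedule, "htt_schedule"), inherits(window, "binding_window"))
  if (window$last_codon > nrow(schedule)) {
    stop("Binding window (codons ", window$first_codon, "-", window$last_codon,
         ") extends beyond the ", nrow(schedule), "-codon schedule.",
         call. = FALSE)
  }
  sum(schedule$dwell_tau_a[window$first_codon:window$last_codon])
}

# tau_AFB (tau_A units) for a vector of repeat numbers, via the schedule.
tau_afb_for_ncag <- function(n_cag, params, window) {
  vapply(n_cag, function(n) {
    sched <- build_schedule(build_construct(n), params$slowdown_s, params$tau_a)
    tau_afb(sched, window)
  }, numeric(1))
}

#' Amount of misprocessed huntingtin at a given tau_AFB
#'
#' First-order irreversible binding survival: of an amount `a0` that would
#' be misprocessed with no binding opportunity at all, the fraction that
#' escapes factor binding during an available time `tau_afb_value` is
#' `exp(-k_on * tau_afb_value)`.
#'
#' @param tau_afb_value Available binding time, seconds (or `tau_a` units
#'   if `k_on` is the dimensionless per-codon rate `beta`), >= 0.
#' @param k_on Association rate conjugate to the units of `tau_afb_value`.
#' @param a0 Amount misprocessed at `tau_afb_value = 0`, >= 0.
#' @return `a0 * exp(-k_on * tau_afb_value)`, vectorized over
#'   `tau_afb_value`.
#' @export
amount_misprocessed <- function(tau_afb_value, k_on, a0 = 1) {
  if (!is.numeric(tau_afb_value) || anyNA(tau_afb_value) ||
      any(tau_afb_value < 0)) {
    stop("`tau_afb_value` must be non-negative.", call. = FALSE)
  }
  if (!is.numeric(k_on) || length(k_on) != 1L || is.na(k_on) || k_on < 0) {
    stop("`k_on` must be a single non-negative rate.", call. = FALSE)
  }
  if (!is.numeric(a0) || length(a0) != 1L || is.na(a0) || a0 < 0) {
    stop("`a0` must be a single non-negative amount.", call. = FALSE)
  }
  a0 * exp(-k_on * tau_afb_value)
}

#' Relative misprocessed fraction f_mp
#'
#' The model's central quantity: the fraction of huntingtin misprocessed at
#' repeat number `n_cag` relative to the amount misprocessed at the disease
#' threshold repeat number 35,
#' \deqn{f_{mp}(N) = \exp[-k_{on}(\tau_{AFB}(N) - \tau_{AFB}(35))] - 1.}
#' The unknown zero-binding amount cancels, so f_mp depends only on the
#' dwell schedule, the window and `beta = k_on * tau_a`. f_mp is zero at
#' the reference, grows with each added repeat while the window still
#' contains slow codons, and plateaus once the window is all-fast (repeat
#' number >= 35 + window width with defaults). It is a relative fraction
#' and may exceed 1; it is not clamped.
#'
#' @param n_cag Integer vector of repeat numbers, each >= 35 (the model is
#'   defined relative to 35 and is not extrapolated below it).
#' @param params A `kinetic_params`.
#' @param window A `binding_window`.
#' @return Numeric vector of relative misprocessed fractions.
#' @examples
#' fraction_misprocessed(40) # exp(0.183) - 1
#' @export
fraction_misprocessed <- function(n_cag, params = kinetic_params(),
                                  window = binding_window()) {
  stopifnot(inherits(params, "kinetic_params"), inherits(window, "binding_window"))
  if (!is.numeric(n_cag) || length(n_cag) < 1L || anyNA(n_cag) ||
      any(n_cag != as.integer(n_cag))) {
    stop("`n_cag` must be integer repeat numbers.", call. = FALSE)
  }
  if (any(n_cag < 35)) {
    stop("`n_cag` must be >= 35: the model is defined relative to the ",
         "35-repeat reference and does not extrapolate below it.",
         call. = FALSE)
  }
  tau_ref <- tau_afb_for_ncag(35L, params, window)
  tau_n <- tau_afb_for_ncag(as.integer(n_cag), params, window)
  exp(-params$beta * (tau_n - tau_ref)) - 1
}

#' First-order (linearized) misprocessed fraction
#'
#' The leading term of the power-series expansion of f_mp: the argument
#' `x = -k_on * (tau_AFB(n_cag) - tau_AFB(35))` itself. For small `x` the
#' exponential is nearly linear and `x` approximates f_mp with error at
#' most `x^2 * exp(x) / 2`.
#'
#' @inheritParams fraction_misprocessed
#' @return Numeric vector of linearized fractions.
#' @export
linearized_fraction <- function(n_cag, params = kinetic_params(),
                                window = binding_window()) {
  stopifnot(inherits(params, "kinetic_params"), inherits(window, "binding_window"))
  if (!is.numeric(n_cag) || anyNA(n_cag) || any(n_cag != as.integer(n_cag))) {
    stop("`n_cag` must be integer repeat numbers.", call. = FALSE)
  }
  if (any(n_cag < 35)) {
    stop("`n_cag` must be >= 35.", call. = FALSE)
  }
  tau_ref <- tau_afb_for_ncag(35L, params, window)
  tau_n <- tau_afb_for_ncag(as.integer(n_cag), params, window)
  -params$beta * (tau_n - tau_ref)
}

#' Misprocessed-fraction curve over a repeat-number range
#'
#' Evaluates tau_AFB and f_mp for every integer repeat number in
#' `n_cag_min..n_cag_max`.
#'
#' @param n_cag_min,n_cag_max Integer range bounds, `35 <= min <= max`.
#' @inheritParams fraction_misprocessed
#' @return A tibble of class `misprocessing_curve` with columns `n_cag`,
#'   `tau_afb_tau_a` and `f_mp`; the kinetic parameters and window are
#'   attached as attributes `params` and `window`.
#' @examples
#' misprocessing_curve(40, 53)
#' @export
misprocessing_curve <- function(n_cag_min = 40L, n_cag_max = 53L,
                                params = kinetic_params(),
                                window = binding_window()) {
  if (!is.numeric(n_cag_min) || !is.numeric(n_cag_max) ||
      length(n_cag_min) != 1L || length(n_cag_max) != 1L ||
      is.na(n_cag_min) || is.na(n_cag_max) ||
      n_cag_min != as.integer(n_cag_min) || n_cag_max != as.integer(n_cag_max) ||
      n_cag_min < 35 || n_cag_min > n_cag_max) {
    stop("Need integer bounds with 35 <= n_cag_min <= n_cag_max.",
         call. = FALSE)
  }
  n <- seq.int(as.integer(n_cag_min), as.integer(n_cag_max))
  out <- tibble::tibble(
    n_cag = n,
    tau_afb_tau_a = tau_afb_for_ncag(n, params, window),
    f_mp = fraction_misprocessed(n, params, window)
  )
  structure(
    out,
    params = params,
    window = window,
    class = c("misprocessing_curve", class(out))
  )
}

#' Export a misprocessing curve as CSV with a JSON parameter sidecar
#'
#' Writes the curve as `<path>` (columns `n_cag`, `tau_afb_tau_a`, `f_mp`)
#' and the kinetic parameters plus window bounds as `<path>.json`.
#'
#' @param curve A `misprocessing_curve`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "misprocessing_curve"))
  readr::write_csv(tibble::as_tibble(curve), path)
  params <- attr(curve, "params")
  window <- attr(curve, "window")
  jsonlite::write_json(
    list(
      k_on = params$k_on, tau_a = params$tau_a,
      slowdown_s = params$slowdown_s, beta = params$beta,
      window_first_codon = window$first_codon,
      window_last_codon = window$last_codon
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
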