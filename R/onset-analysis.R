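#' Pearson correlation with least-squares line
#'
#' Product-moment correlation between two numeric vectors, with a
#' two-sided p-value from the exact Student-t tail
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom; the
#' sample sizes here are small, so no normal approximation is used) and
#' the ordinary-least-squares slope and intercept of `y` on `x`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param data Optionally, a data frame recorded alongside the statistics
#'   (used by `autoplot()`); not involved in the computation.
#' @return An object of class `correlation_result`: a list with `r`,
#'   `r_squared`, `p_value`, `n`, `slope`, `intercept` and `statistic`
#'   (the t value).
#' @examples
#' pearson(1:10, (1:10) * 2 + rnorm(10))
#' @export
pearson <- function(x, y, data = NULL) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("`x` and `y` must be numeric.", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (got ", length(x), " and ",
         length(y), ").", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("`x` and `y` must not contain missing values.", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) {
    stop("Need at least 3 observations for a correlation.", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Pearson correlation is undefined for zero-variance input.",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  structure(
    list(
      r = r, r_squared = r^2, p_value = p, n = n,
      slope = slope, intercept = intercept, statistic = tval,
      data = data
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> n =", x$n, "\n")
  cat(sprintf("  r = %.4f, R^2 = %.3f, p = %.3g\n", x$r, x$r_squared,
              x$p_value))
  cat(sprintf("  OLS: y = %.4g + %.4g x\n", x$intercept, x$slope))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation result
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `estimate` (r), `statistic`,
#'   `p.value`, `parameter` (df), `slope` and `intercept`. `glance()`: a
#'   one-row tibble with `r.squared`, `p.value` and `nobs`.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$r,
    statistic = x$statistic,
    p.value = x$p_value,
    parameter = x$n - 2L,
    slope = x$slope,
    intercept = x$intercept
  )
}

#' @rdname tidy.correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    p.value = x$p_value,
    nobs = x$n
  )
}

#' Correlation between the misprocessed fraction and repeat number
#'
#' Computes f_mp for every integer repeat number in the range and its
#' Pearson correlation with the repeat number. With default parameters
#' over repeat numbers 40-53 (the Lee et al. clinical range) the squared
#' correlation is 0.996 to 3 d.p.; over 39-50 (the Brinkman et al. range)
#' it is 0.997.
#'
#' @inheritParams misprocessing_curve
#' @return A `correlation_result`; its `data` field holds the curve.
#' @examples
#' glance(correlate_fmp_vs_ncag(40, 53))
#' @export
correlate_fmp_vs_ncag <- function(n_cag_min = 40L, n_cag_max = 53L,
                                  params = kinetic_params(),
                                  window = binding_window()) {
  curve <- misprocessing_curve(n_cag_min, n_cag_max, params, window)
  if (nrow(curve) < 3) {
    stop("Repeat-number range must contain at least 3 points.", call. = FALSE)
  }
  pearson(curve$n_cag, curve$f_mp, data = tibble::as_tibble(curve))
}

#' Correlation between age of symptom onset and the misprocessed fraction
#'
#' Maps each onset record's repeat number to its model f_mp, then
#' correlates onset age against f_mp. For datasets in which onset declines
#' with repeat number the correlation is strongly negative.
#'
#' @param onset Data frame with columns `n_cag` (integer, >= 36: the model
#'   correlation is restricted to the disease range) and `onset_age_years`
#'   (> 0); at least 3 records.
#' @param params A `kinetic_params`.
#' @param window A `binding_window`.
#' @param aggregate `"none"` (default): every record enters individually;
#'   `"mean"`: onset ages are averaged per repeat number first.
#' @return A `correlation_result` of `pearson(f_mp, onset_age)`; its
#'   `data` field holds the analyzed records with an `f_mp` column.
#' @export
correlate_onset_vs_fmp <- function(onset, params = kinetic_params(),
                                   window = binding_window(),
                                   aggregate = c("none", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(onset))
  required <- c("n_cag", "onset_age_years")
  missing_cols <- setdiff(required, names(onset))
  if (length(missing_cols) > 0) {
    stop("`onset` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(onset$n_cag < 36)) {
    stop("All `n_cag` must be >= 36 (disease-range records only).",
         call. = FALSE)
  }
  if (any(onset$onset_age_years <= 0)) {
    stop("All onset ages must be positive.", call. = FALSE)
  }
  if (nrow(onset) < 3) {
    stop("Need at least 3 onset records.", call. = FALSE)
  }
  dat <- tibble::as_tibble(onset)
  if (aggregate == "mean") {
    dat <- dat |>
      dplyr::group_by(.data$n_cag) |>
      dplyr::summarise(onset_age_years = mean(.data$onset_age_years),
                       .groups = "drop")
    if (nrow(dat) < 3) {
      stop("Fewer than 3 distinct repeat numbers after aggregation.",
           call. = FALSE)
    }
  }
  dat$f_mp <- fraction_misprocessed(as.integer(dat$n_cag), params, window)
  pearson(dat$f_mp, dat$onset_age_years, data = dat)
}

#' Slowdown-factor sensitivity of the f_mp vs repeat-number correlation
#'
#' Re-evaluates the f_mp vs N_CAG correlation for a set of proline
#' slowdown factors, holding `k_on` and `tau_a` fixed. The model's
#' correlation stays strong across the 2x-6x slowdown range reported for
#' proline translation.
#'
#' @param s_values Numeric vector of slowdown factors, each >= 1.
#' @inheritParams misprocessing_curve
#' @return A tibble with one row per slowdown factor and columns
#'   `slowdown_s`, `r`, `r_squared` and `p_value`.
#' @export
sensitivity_scan <- function(s_values = 2:6, n_cag_min = 40L, n_cag_max = 53L,
                             params = kinetic_params(),
                             window = binding_window()) {
  if (!is.numeric(s_values) || length(s_values) < 1L || anyNA(s_values) ||
      any(s_values < 1)) {
    stop("`s_values` must be slowdown factors >= 1.", call. = FALSE)
  }
  purrr::map_dfr(s_values, function(s) {
    p_s <- kinetic_params(k_on = params$k_on, tau_a = params$tau_a,
                          slowdown_s = s)
    res <- correlate_fmp_vs_ncag(n_cag_min, n_cag_max, p_s, window)
    tibble::tibble(slowdown_s = s, r = res$r, r_squared = res$r_squared,
                   p_value = res$p_value)
  })
}

#' Read an onset dataset from CSV
#'
#' CSV dialect with header `n_cag,onset_age_years`, one record per row.
#'
#' @param path File path.
#' @return A tibble with columns `n_cag` and `onset_age_years`.
#' @export
read_onset_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    n_cag = readr::col_integer(),
    onset_age_years = readr::col_double()
  ))
}
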