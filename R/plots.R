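#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a misprocessing curve
#'
#' f_mp against the CAG-repeat number, with the plateau region (window
#' fully fast-translating) shown by the flattening of the curve.
#'
#' @param object A `misprocessing_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.misprocessing_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$n_cag, y = .data$f_mp)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(N[CAG]),
      y = expression(f[mp]),
      title = "Relative misprocessed fraction vs CAG-repeat number"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a correlation result
#'
#' Scatter of the correlated variables with the least-squares line,
#' annotated with the Pearson R-squared. Requires the result to carry its
#' `data` (as results from [correlate_fmp_vs_ncag()] and
#' [correlate_onset_vs_fmp()] do).
#'
#' @param object A `correlation_result` with a non-`NULL` `data` field.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  dat <- object$data
  if (is.null(dat)) {
    stop("This correlation result carries no data to plot.", call. = FALSE)
  }
  if (all(c("f_mp", "onset_age_years") %in% names(dat))) {
    xvar <- "f_mp"; yvar <- "onset_age_years"
    xlab <- expression(f[mp]); ylab <- "Age of onset (years)"
  } else {
    xvar <- names(dat)[1]; yvar <- setdiff(names(dat), xvar)[length(setdiff(names(dat), xvar))]
    if (all(c("n_cag", "f_mp") %in% names(dat))) {
      xvar <- "n_cag"; yvar <- "f_mp"
    }
    xlab <- xvar; ylab <- yvar
  }
  lab <- sprintf("R² = %.3f, p = %.2g", object$r_squared, object$p_value)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab, subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot a translation dwell-time schedule
#'
#' Per-codon dwell times coloured by region, with the binding window
#' shaded.
#'
#' @param schedule An `htt_schedule`.
#' @param window Optional `binding_window` to shade.
#' @return A ggplot object.
#' @export
plot_schedule <- function(schedule, window = binding_window()) {
  stopifnot(inherits(schedule, "htt_schedule"))
  p <- ggplot2::ggplot(tibble::as_tibble(schedule),
                       ggplot2::aes(x = .data$codon_position,
                                    y = .data$dwell_tau_a,
                                    fill = .data$region))
  if (!is.null(window)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = window$first_codon - 0.5, xmax = window$last_codon + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    )
  }
  p +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(
      x = "Codon position",
      y = expression("Dwell time (" * tau[A] * ")"),
      fill = "Region"
    ) +
    ggplot2::theme_minimal()
}
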