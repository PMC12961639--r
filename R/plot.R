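#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stick plot of a centroided spectrum
#'
#' @param object An [spectrum()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ms_spectrum
#' @export
autoplot.ms_spectrum <- function(object, ...) {
  md <- attr(object, "metadata") %||% list()
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = md$title %||% NULL) +
    ggplot2::theme_minimal()
}

#' Stick plot of a simulated isotope pattern
#'
#' @param object An `isotope_pattern` from [simulate_pattern()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot isotope_pattern
#' @export
autoplot.isotope_pattern <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mz, y = .data$abundance)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z", y = "relative abundance (%)") +
    ggplot2::theme_minimal()
}

#' Mass-error plot of a formula candidate table
#'
#' Shows each candidate's signed ppm error, colored by isotopic
#' similarity when that score has been computed.
#'
#' @param cands Candidate tibble from [enumerate_formulas()] (optionally
#'   scored by [rank_by_isotopic_similarity()]).
#' @param top Show at most this many candidates (by current row order).
#' @return A ggplot object.
#' @export
plot_candidates <- function(cands, top = 30) {
  df <- utils::head(tibble::as_tibble(cands), top)
  df$formula <- factor(df$formula, levels = rev(df$formula))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm_error,
                                        y = .data$formula))
  p <- if ("isotopic_similarity" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$isotopic_similarity))
  } else {
    p + ggplot2::geom_point()
  }
  p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "mass error (ppm)", y = NULL) +
    ggplot2::theme_minimal()
}
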