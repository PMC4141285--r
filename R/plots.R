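#' Serial-position preference curves
#'
#' Plots the probability that an option is the final favorite against its
#' serial position, one panel per (inertia level, dynamics, sequence
#' length) cell, with one line per quality-variability level and the
#' dashed `1/L` random-choice baseline.
#'
#' @param results A `pcm_results` table.
#' @param lengths Optional subset of sequence lengths to show.
#'
#' @return A ggplot object.
#' @examples
#' res <- exact_design(factorial_design(lengths = c(6, 20), runs = 1))
#' plot_position_curves(res)
#' @export
plot_position_curves <- function(results, lengths = NULL) {
  results <- check_plot_input(results)
  if (!is.null(lengths)) {
    results <- dplyr::filter(results, .data$length %in% lengths)
    if (nrow(results) == 0L) stop("no rows at the requested lengths.", call. = FALSE)
  }
  results <- dplyr::mutate(
    results,
    spread_lab = factor(paste0("δ = ", .data$spread)),
    inertia_lab = paste0("π₁ = ", .data$pi1, ", c = ", .data$c),
    length_lab = paste0("L = ", .data$length))
  baselines <- dplyr::distinct(results, .data$inertia_lab, .data$length_lab,
                               .data$length) |>
    dplyr::mutate(baseline = 1 / .data$length)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$position, y = .data$p_favorite,
                               colour = .data$spread_lab, group = .data$spread_lab)) +
    ggplot2::geom_hline(data = baselines,
                        ggplot2::aes(yintercept = .data$baseline),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$inertia_lab),
                        cols = ggplot2::vars(.data$length_lab)) +
    ggplot2::scale_colour_manual(values = c("black", "grey55"), drop = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Serial position", y = "P(final favorite)",
                  colour = "Quality variability") +
    ggplot2::theme_bw()
}

#' First- and last-position probabilities by sequence length
#'
#' Plots the raw probability that the first (primacy) and last (recency)
#' option ends up the final favorite as a function of sequence length,
#' panelled by inertia cell, with the decreasing dashed `1/L` baseline.
#'
#' @param results A `pcm_results` table.
#'
#' @return A ggplot object.
#' @export
plot_length_trends <- function(results) {
  results <- check_plot_input(results)
  ends <- results |>
    dplyr::filter(.data$position == 1 | .data$position == .data$length) |>
    dplyr::mutate(
      which_end = ifelse(.data$position == 1, "first (primacy)", "last (recency)"),
      spread_lab = factor(paste0("δ = ", .data$spread)),
      inertia_lab = paste0("π₁ = ", .data$pi1, ", c = ", .data$c))
  # L = 2 contributes to both ends; keep both labelled rows
  baselines <- dplyr::distinct(ends, .data$length) |>
    dplyr::mutate(baseline = 1 / .data$length)
  ggplot2::ggplot(ends,
                  ggplot2::aes(x = .data$length, y = .data$p_favorite,
                               colour = .data$spread_lab)) +
    ggplot2::geom_line(data = baselines, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$length, y = .data$baseline),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$inertia_lab),
                        cols = ggplot2::vars(.data$which_end)) +
    ggplot2::scale_colour_manual(values = c("black", "grey55"), drop = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Sequence length L", y = "P(final favorite)",
                  colour = "Quality variability") +
    ggplot2::theme_bw()
}

check_plot_input <- function(results) {
  needed <- c("spread", "length", "pi1", "c", "position", "p_favorite")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0L) {
    stop("malformed results table: missing column(s) ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  if (nrow(results) == 0L) stop("results table is empty.", call. = FALSE)
  bad <- which(is.na(results$p_favorite) | results$p_favorite < 0 |
                 results$p_favorite > 1)
  if (length(bad) > 0L) {
    stop("malformed results table: bad probability in row ", bad[1], ".",
         call. = FALSE)
  }
  results
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a position curve
#'
#' @param object A `pcm_curve`.
#' @param ... Unused.
#'
#' @return A ggplot object: probability against serial position with the
#'   dashed `1/L` random-choice baseline, plus 95% error bars for
#'   Monte-Carlo curves.
#' @export
autoplot.pcm_curve <- function(object, ...) {
  L <- attr(object, "length")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$p_favorite)) +
    ggplot2::geom_hline(yintercept = 1 / L, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point()
  if (curve_source(object) == "monte_carlo") {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$p_favorite - 1.96 * .data$se),
                   ymax = pmin(1, .data$p_favorite + 1.96 * .data$se)),
      width = 0.2)
  }
  p +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Serial position", y = "P(final favorite)",
                  subtitle = paste0("source: ", curve_source(object))) +
    ggplot2::theme_bw()
}
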