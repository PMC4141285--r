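#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a position curve
#'
#' @param x A `pcm_curve`.
#' @param ... Unused.
#'
#' @return A plain tibble with one row per serial position: `position`,
#'   `p_favorite`, `se`, `source`.
#' @export
tidy.pcm_curve <- function(x, ...) {
  tibble::tibble(position = x$position, p_favorite = x$p_favorite, se = x$se,
                 source = curve_source(x))
}

#' One-row summary of a position curve
#'
#' @param x A `pcm_curve`.
#' @param ... Unused.
#'
#' @return A one-row tibble: sequence length, source, run count, the
#'   random baseline `1/L`, and the primacy/recency effects from
#'   [summarize_effects()].
#' @export
glance.pcm_curve <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(length = attr(x, "length"), source = curve_source(x),
                   n_runs = attr(x, "n_runs")),
    summarize_effects(x))
}

#' @export
print.pcm_curve <- function(x, ...) {
  cat(sprintf("# Final-favorite probabilities by serial position (L = %d, %s)\n",
              attr(x, "length"), curve_source(x)))
  NextMethod()
}
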