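#' Factorial sensitivity-analysis design
#'
#' The full crossing of quality variability, sequence length, inertia level
#' and inertia dynamics, with a fixed number of Monte-Carlo runs per cell.
#' The defaults are the canonical sensitivity analysis:
#' 2 (spread 0 vs 5) x 6 (L in 2, 4, 6, 10, 12, 20) x 4 (pi1 in 0, 0.3,
#' 0.6, 0.9) x 2 (c = 0 static vs c = 0.3 dynamic) = 96 conditions at
#' 100,000 runs each.
#'
#' @param spreads Quality-variability levels (standard deviation of the
#'   untruncated normal; 0 = equal quality).
#' @param lengths Sequence lengths, all `>= 2`.
#' @param inertia_levels Inertia-at-first-position levels `pi1`.
#' @param dynamics Inertia growth exponents `c`.
#' @param runs Monte-Carlo runs per condition.
#' @param quality_mean,quality_lower,quality_upper Truncated-normal mean and
#'   bounds shared by all conditions.
#'
#' @return An object of class `factorial_design`.
#' @examples
#' factorial_design()
#' @export
factorial_design <- function(spreads = c(0, 5),
                             lengths = c(2, 4, 6, 10, 12, 20),
                             inertia_levels = c(0, 0.3, 0.6, 0.9),
                             dynamics = c(0, 0.3),
                             runs = 100000,
                             quality_mean = 5,
                             quality_lower = 0,
                             quality_upper = 10) {
  for (nm in c("spreads", "lengths", "inertia_levels", "dynamics")) {
    v <- get(nm)
    if (length(v) == 0L) stop(sprintf("`%s` must be non-empty.", nm), call. = FALSE)
    if (anyDuplicated(v)) stop(sprintf("`%s` has duplicated levels.", nm), call. = FALSE)
  }
  if (any(lengths < 2)) stop("all sequence lengths must be >= 2.", call. = FALSE)
  if (runs < 1) stop("`runs` must be >= 1.", call. = FALSE)
  structure(list(spreads = spreads, lengths = as.integer(lengths),
                 inertia_levels = inertia_levels, dynamics = dynamics,
                 runs = as.integer(runs), quality_mean = quality_mean,
                 quality_lower = quality_lower, quality_upper = quality_upper),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf(paste0("<factorial_design> %d x %d x %d x %d = %d conditions, ",
                     "%d runs each\n"),
              length(x$spreads), length(x$lengths), length(x$inertia_levels),
              length(x$dynamics),
              length(x$spreads) * length(x$lengths) * length(x$inertia_levels) *
                length(x$dynamics),
              x$runs))
  invisible(x)
}

#' Enumerate the conditions of a design
#'
#' Expands a [factorial_design()] into one row per condition in a fixed,
#' deterministic order (variability outermost, then length, inertia level,
#' dynamics). `condition_id` indexes that order and anchors per-condition
#' random substreams, so any single condition can be re-run independently.
#'
#' @param design A [factorial_design()].
#'
#' @return A tibble with columns `condition_id`, `spread`, `length`, `pi1`,
#'   `c`.
#' @examples
#' enumerate_conditions(factorial_design())
#' @export
enumerate_conditions <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  grid <- tidyr::expand_grid(spread = design$spreads,
                             length = design$lengths,
                             pi1 = design$inertia_levels,
                             c = design$dynamics)
  dplyr::mutate(grid, condition_id = dplyr::row_number(), .before = 1)
}

condition_from_row <- function(row, design) {
  pcm_condition(row$length,
                inertia_schedule(row$pi1, row$c),
                quality_model(mean = design$quality_mean, spread = row$spread,
                              lower = design$quality_lower,
                              upper = design$quality_upper))
}

#' Run the full factorial simulation
#'
#' Simulates every condition of the design with the Monte-Carlo engine and
#' returns a tidy table of per-position winner probabilities. Each
#' condition is simulated under its own random substream derived
#' deterministically from `seed` and the condition index, so the whole
#' table is bit-reproducible and any condition can be reproduced in
#' isolation.
#'
#' @param design A [factorial_design()].
#' @param seed Integer seed for the master random stream.
#' @param verbose Print per-condition progress messages?
#'
#' @return A tibble of class `pcm_results`, one row per condition and
#'   position: `condition_id`, `spread`, `length`, `pi1`, `c`, `position`,
#'   `p_favorite`, `se`, `n_runs`, `source`.
#' @examples
#' small <- factorial_design(spreads = 0, lengths = c(2, 4),
#'                           inertia_levels = 0.6, dynamics = 0, runs = 2000)
#' run_design(small, seed = 1)
#' @export
run_design <- function(design, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(design, "factorial_design"))
  conditions <- enumerate_conditions(design)
  cond_seeds <- condition_seeds(seed, nrow(conditions))
  rows <- purrr::pmap(conditions, function(condition_id, spread, length, pi1, c) {
    if (verbose) {
      message(sprintf("condition %d/%d: L=%d pi1=%g c=%g spread=%g",
                      condition_id, nrow(conditions), length, pi1, c, spread))
    }
    cond <- condition_from_row(
      list(length = length, pi1 = pi1, c = c, spread = spread), design)
    set.seed(cond_seeds[condition_id])
    curve <- simulate_runs(cond, design$runs)
    curve_rows(curve, condition_id, spread, length, pi1, c)
  })
  as_pcm_results(dplyr::bind_rows(rows))
}

# Per-condition seeds: a deterministic function of (seed, condition index)
# through R's RNG, kept inside the 32-bit integer range.
condition_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

curve_rows <- function(curve, condition_id, spread, length, pi1, c) {
  tibble::tibble(condition_id = condition_id, spread = spread,
                 length = as.integer(length), pi1 = pi1, c = c,
                 position = curve$position, p_favorite = curve$p_favorite,
                 se = curve$se,
                 n_runs = if (is.na(attr(curve, "n_runs"))) 0L else attr(curve, "n_runs"),
                 source = curve_source(curve))
}

as_pcm_results <- function(x) {
  structure(x, class = unique(c("pcm_results", class(x))))
}

#' Solve the design exactly
#'
#' The deterministic counterpart of [run_design()]: every equal-quality
#' condition is solved with [closed_form_equal_quality()], every
#' variability condition with [grid_dp()]. Standard errors are zero.
#'
#' @param design A [factorial_design()].
#' @param grid_size Grid resolution passed to [grid_dp()].
#'
#' @return A tibble of class `pcm_results` in the same layout as
#'   [run_design()].
#' @examples
#' exact_design(factorial_design(lengths = c(2, 4), runs = 1), grid_size = 100)
#' @export
exact_design <- function(design, grid_size = 400) {
  stopifnot(inherits(design, "factorial_design"))
  conditions <- enumerate_conditions(design)
  rows <- purrr::pmap(conditions, function(condition_id, spread, length, pi1, c) {
    sched <- inertia_schedule(pi1, c)
    curve <- if (spread == 0) {
      closed_form_equal_quality(length, sched)
    } else {
      grid_dp(condition_from_row(
        list(length = length, pi1 = pi1, c = c, spread = spread), design),
        grid_size = grid_size)
    }
    curve_rows(curve, condition_id, spread, length, pi1, c)
  })
  as_pcm_results(dplyr::bind_rows(rows))
}

#' Primacy and recency effects against the random baseline
#'
#' Under random choice every position is the final favorite with
#' probability `1/L` (the dashed reference line of the serial-position
#' figures). The primacy effect is `p(1) - 1/L`, the recency effect
#' `p(L) - 1/L`; the raw first/last probabilities are kept alongside.
#'
#' @param x A `pcm_curve` or a `pcm_results` table from [run_design()] /
#'   [exact_design()].
#' @param ... Unused.
#'
#' @return A tibble with columns `baseline`, `raw_first`, `raw_last`,
#'   `primacy`, `recency` (one row per condition for result tables, which
#'   also keep the condition descriptors).
#' @examples
#' summarize_effects(closed_form_equal_quality(6, inertia_schedule(0.9)))
#' @export
summarize_effects <- function(x, ...) UseMethod("summarize_effects")

#' @export
summarize_effects.pcm_curve <- function(x, ...) {
  L <- attr(x, "length")
  effect_row(L, x$p_favorite[1], x$p_favorite[L])
}

#' @export
summarize_effects.data.frame <- function(x, ...) {
  needed <- c("condition_id", "length", "position", "p_favorite")
  if (!all(needed %in% names(x))) {
    stop("expected a results table with columns ",
         paste(needed, collapse = ", "), ".", call. = FALSE)
  }
  x |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("condition_id", "spread", "length", "pi1", "c", "source")))) |>
    dplyr::summarise(
      effect_row(length[1],
                 p_favorite[position == 1],
                 p_favorite[position == length[1]]),
      .groups = "drop")
}

effect_row <- function(L, raw_first, raw_last) {
  baseline <- 1 / L
  tibble::tibble(baseline = baseline, raw_first = raw_first,
                 raw_last = raw_last, primacy = raw_first - baseline,
                 recency = raw_last - baseline)
}
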