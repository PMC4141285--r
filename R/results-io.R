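#' Write a results table to CSV
#'
#' Serialises a `pcm_results` table (from [run_design()] or
#' [exact_design()]) as UTF-8 CSV with a `.` decimal separator and full
#' double precision, so that [read_pcm_results()] round-trips every
#' numeric field exactly. Rows keep the stable (condition, position)
#' ordering.
#'
#' @param results A results table.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_pcm_results <- function(results, path) {
  needed <- c("condition_id", "spread", "length", "pi1", "c", "position",
              "p_favorite", "se", "n_runs", "source")
  if (!all(needed %in% names(results))) {
    stop("not a results table: missing column(s) ",
         paste(setdiff(needed, names(results)), collapse = ", "), ".",
         call. = FALSE)
  }
  out <- results[needed]
  for (col in c("spread", "pi1", "c", "p_favorite", "se")) {
    out[[col]] <- fmt_roundtrip(out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

# Shortest decimal representation that parses back to the identical double.
fmt_roundtrip <- function(x) {
  out <- sprintf("%.15g", x)
  for (digits in c("%.16g", "%.17g")) {
    bad <- as.numeric(out) != x
    if (!any(bad)) break
    out[bad] <- sprintf(digits, x[bad])
  }
  out
}

#' Read a results table written by [write_pcm_results()]
#'
#' @param path CSV file path.
#'
#' @return A tibble of class `pcm_results`.
#' @export
read_pcm_results <- function(path) {
  # doubles come in as text and go through strtod: readr's fast float path
  # can be off by one ulp, which would break exact round-tripping
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      condition_id = readr::col_integer(),
      spread = readr::col_character(),
      length = readr::col_integer(),
      pi1 = readr::col_character(),
      c = readr::col_character(),
      position = readr::col_integer(),
      p_favorite = readr::col_character(),
      se = readr::col_character(),
      n_runs = readr::col_integer(),
      source = readr::col_character()
    ))
  for (col in c("spread", "pi1", "c", "p_favorite", "se")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  if (nrow(out) == 0L) stop("results table at `", path, "` is empty.", call. = FALSE)
  as_pcm_results(out)
}

#' Run configuration
#'
#' Bundles everything one sweep needs: the factorial design, the master
#' seed, the output path, the grid resolution for exact-solver mode, and
#' the mode itself. Defaults reproduce the canonical sensitivity analysis
#' (96 conditions, 100,000 runs each).
#'
#' @param design A [factorial_design()].
#' @param seed Master seed.
#' @param output_path Where the sweep CSV goes.
#' @param grid_size Grid resolution for exact mode.
#' @param mode `"simulate"`, `"exact"`, or `"both"` (exact rows appended
#'   after simulated ones with their own condition ids preserved).
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = factorial_design(), seed = 1L,
                       output_path = "pcm_results.csv", grid_size = 400,
                       mode = c("simulate", "exact", "both")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "factorial_design"))
  structure(list(design = design, seed = as.integer(seed),
                 output_path = output_path, grid_size = grid_size, mode = mode),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Every field is optional; omitted fields fall back to the canonical
#' defaults of [run_config()] and [factorial_design()]. Recognised keys:
#' `spreads`, `lengths`, `inertia_levels`, `dynamics`, `runs`, `seed`,
#' `output_path`, `grid_size`, `mode`.
#'
#' @param path YAML file path.
#'
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("spreads", "lengths", "inertia_levels", "dynamics", "runs",
             "seed", "output_path", "grid_size", "mode")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), ".",
         call. = FALSE)
  }
  design_args <- raw[intersect(names(raw), c("spreads", "lengths",
                                             "inertia_levels", "dynamics", "runs"))]
  design <- do.call(factorial_design, design_args)
  args <- list(design = design)
  for (f in c("seed", "output_path", "grid_size", "mode")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(run_config, args)
}

#' Execute a sweep described by a run configuration
#'
#' Runs the Monte-Carlo sweep and/or the exact solvers per `config$mode`
#' and writes the combined CSV to `config$output_path`.
#'
#' @param config A [run_config()].
#' @param verbose Print per-condition progress?
#'
#' @return The results tibble, invisibly.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  parts <- list()
  if (config$mode %in% c("simulate", "both")) {
    parts$mc <- run_design(config$design, seed = config$seed, verbose = verbose)
  }
  if (config$mode %in% c("exact", "both")) {
    parts$exact <- exact_design(config$design, grid_size = config$grid_size)
  }
  results <- as_pcm_results(dplyr::bind_rows(parts))
  write_pcm_results(results, config$output_path)
  invisible(results)
}
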