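#' Choice-inertia schedule
#'
#' Inertia is the probability that the current favorite is retained
#' irrespective of the new option's quality. The schedule anchors inertia at
#' `pi1` for the first serial position and lets it grow towards 1 over the
#' sequence at a rate set by the exponent `c`:
#' \deqn{\pi_i = 1 - (1 - \pi_1) \frac{2}{1 + i^{c}}.}
#' With `c = 0` the schedule is static (`pi_i == pi1` everywhere); with
#' `c > 0` it is strictly increasing in `i` and approaches 1 in the limit.
#'
#' @param pi1 Inertia at position 1, a probability in `[0, 1]`.
#' @param c Growth exponent in `[0, 1]`; 0 means static inertia.
#'
#' @return An object of class `inertia_schedule`.
#' @examples
#' sched <- inertia_schedule(pi1 = 0.3, c = 0.3)
#' inertia_at(sched, 1:10)
#' @seealso [inertia_at()]
#' @export
inertia_schedule <- function(pi1, c = 0) {
  stopifnot(is.numeric(pi1), length(pi1) == 1L, is.numeric(c), length(c) == 1L)
  if (is.na(pi1) || pi1 < 0 || pi1 > 1) {
    stop("`pi1` must be a probability in [0, 1].", call. = FALSE)
  }
  if (is.na(c) || c < 0 || c > 1) {
    stop("`c` must lie in [0, 1].", call. = FALSE)
  }
  structure(list(pi1 = pi1, c = c), class = "inertia_schedule")
}

#' @export
print.inertia_schedule <- function(x, ...) {
  kind <- if (x$c == 0) "static" else "dynamic"
  cat(sprintf("<inertia_schedule> pi1 = %g, c = %g (%s)\n", x$pi1, x$c, kind))
  invisible(x)
}

as_inertia_schedule <- function(x) {
  if (inherits(x, "inertia_schedule")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(inertia_schedule(x))
  stop("expected an `inertia_schedule` or a single inertia value.", call. = FALSE)
}

#' Inertia at a serial position
#'
#' Evaluates the inertia schedule at one or more serial positions
#' (1-based; position 1 is the first option encountered).
#'
#' @param schedule An [inertia_schedule()], or a single number taken as a
#'   static inertia level.
#' @param position Integer vector of serial positions, all `>= 1`.
#'
#' @return Numeric vector of inertia probabilities, each in `[pi1, 1]`.
#' @examples
#' inertia_at(inertia_schedule(0.3, c = 0.3), c(1, 5, 10))
#' @export
inertia_at <- function(schedule, position) {
  schedule <- as_inertia_schedule(schedule)
  if (length(position) == 0L || any(is.na(position)) || any(position < 1)) {
    stop("`position` must contain integers >= 1.", call. = FALSE)
  }
  1 - (1 - schedule$pi1) * 2 / (1 + position^schedule$c)
}

#' Probability that a new option displaces the current favorite
#'
#' The pairwise acceptance rule: with probability `inertia` the current
#' favorite is retained outright; otherwise the new option wins a Luce
#' comparison with probability `q_new / (q_new + q_old)`, giving
#' \deqn{p(\mathrm{new}) = (1 - \pi)\,\frac{Q_{new}}{Q_{new} + Q_{old}}.}
#' The old favorite remains with probability `1 - p(new)`. When both
#' qualities are exactly zero the quality ratio is taken to be 1/2 (the
#' symmetric completion of the rule).
#'
#' @param q_new,q_old Non-negative quality values; recycled to a common
#'   length.
#' @param inertia Inertia probability in `[0, 1]` applying to this
#'   comparison.
#'
#' @return Numeric vector of acceptance probabilities in `[0, 1 - inertia]`.
#' @examples
#' acceptance_probability(q_new = 5, q_old = 5, inertia = 0.6) # 0.2
#' @export
acceptance_probability <- function(q_new, q_old, inertia) {
  if (any(is.na(q_new)) || any(q_new < 0) || any(is.na(q_old)) || any(q_old < 0)) {
    stop("qualities must be non-negative.", call. = FALSE)
  }
  if (any(is.na(inertia)) || any(inertia < 0) || any(inertia > 1)) {
    stop("`inertia` must lie in [0, 1].", call. = FALSE)
  }
  total <- q_new + q_old
  ratio <- ifelse(total == 0, 0.5, q_new / ifelse(total == 0, 1, total))
  (1 - inertia) * ratio
}

#' Quality distribution of the options
#'
#' Option quality is a scalar drawn from a normal distribution with mean
#' `mean` and standard deviation `spread`, truncated to `[lower, upper]`.
#' `mean` and `spread` parameterise the untruncated normal. `spread = 0` is
#' the degenerate equal-quality case in which every option has quality
#' `mean` exactly.
#'
#' @param mean Mean of the untruncated normal (quality units).
#' @param spread Standard deviation of the untruncated normal; `>= 0`.
#' @param lower,upper Truncation bounds, `0 <= lower < upper`.
#'
#' @return An object of class `quality_model`.
#' @examples
#' qm <- quality_model(mean = 5, spread = 5)
#' summary(sample_qualities(qm, 1000))
#' @export
quality_model <- function(mean = 5, spread = 5, lower = 0, upper = 10) {
  stopifnot(is.numeric(mean), is.numeric(spread), is.numeric(lower), is.numeric(upper))
  if (is.na(spread) || spread < 0) stop("`spread` must be >= 0.", call. = FALSE)
  if (!(lower < upper)) stop("`lower` must be strictly below `upper`.", call. = FALSE)
  if (lower < 0) stop("`lower` must be >= 0: qualities are non-negative.", call. = FALSE)
  if (spread == 0 && (mean < lower || mean > upper)) {
    stop("with `spread = 0`, `mean` must lie inside the bounds.", call. = FALSE)
  }
  structure(list(mean = mean, spread = spread, lower = lower, upper = upper),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("<quality_model> N(%g, %g) truncated to [%g, %g]\n",
              x$mean, x$spread, x$lower, x$upper))
  invisible(x)
}

#' Draw option qualities
#'
#' Samples `n` independent qualities from a [quality_model()]. A positive
#' spread uses rejection sampling: normal draws are redrawn until they fall
#' inside the truncation bounds, so the result is the true truncated normal
#' (no point masses at the bounds). Uses R's global random stream, so
#' results are reproducible under [set.seed()].
#'
#' @param model A [quality_model()].
#' @param n Number of draws, `>= 1`.
#'
#' @return Numeric vector of length `n` with values in
#'   `[model$lower, model$upper]`.
#' @examples
#' set.seed(1)
#' sample_qualities(quality_model(5, 5), 5)
#' @export
sample_qualities <- function(model, n) {
  stopifnot(inherits(model, "quality_model"))
  if (length(n) != 1L || is.na(n) || n < 1) stop("`n` must be >= 1.", call. = FALSE)
  n <- as.integer(n)
  if (model$spread == 0) return(rep(model$mean, n))
  out <- stats::rnorm(n, model$mean, model$spread)
  bad <- which(out < model$lower | out > model$upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), model$mean, model$spread)
    bad <- bad[out[bad] < model$lower | out[bad] > model$upper]
  }
  out
}

#' A single cell of the simulation design
#'
#' Bundles a sequence length with an inertia schedule and a quality model.
#'
#' @param length Number of options encountered serially; integer `>= 2`.
#' @param schedule An [inertia_schedule()] (or a single static inertia
#'   level).
#' @param quality A [quality_model()].
#'
#' @return An object of class `pcm_condition`.
#' @examples
#' pcm_condition(6, inertia_schedule(0.9), quality_model(spread = 0))
#' @export
pcm_condition <- function(length, schedule = inertia_schedule(0),
                          quality = quality_model()) {
  if (length(length) != 1L || is.na(length) || length < 2 || length != round(length)) {
    stop("`length` must be an integer >= 2.", call. = FALSE)
  }
  schedule <- as_inertia_schedule(schedule)
  stopifnot(inherits(quality, "quality_model"))
  structure(list(length = as.integer(length), schedule = schedule, quality = quality),
            class = "pcm_condition")
}

#' @export
print.pcm_condition <- function(x, ...) {
  cat(sprintf("<pcm_condition> L = %d, pi1 = %g, c = %g, delta = %g\n",
              x$length, x$schedule$pi1, x$schedule$c, x$quality$spread))
  invisible(x)
}

#' Simulate one sequential choice episode
#'
#' Draws `L` qualities, installs the first option as the initial favorite,
#' then walks the sequence: at each position `i >= 2` the new option
#' displaces the favorite with probability
#' `acceptance_probability(Q[i], Q[favorite], inertia_at(schedule, i))`.
#' The survivor of the last comparison is the final favorite.
#'
#' @param condition A [pcm_condition()].
#'
#' @return A list of class `sequence_run` with elements `qualities`
#'   (length-`L` numeric) and `winner` (serial position of the final
#'   favorite).
#' @examples
#' set.seed(42)
#' simulate_sequence(pcm_condition(6, inertia_schedule(0.3)))
#' @export
simulate_sequence <- function(condition) {
  stopifnot(inherits(condition, "pcm_condition"))
  L <- condition$length
  q <- sample_qualities(condition$quality, L)
  fav <- 1L
  for (i in 2:L) {
    p <- acceptance_probability(q[i], q[fav], inertia_at(condition$schedule, i))
    if (stats::runif(1) < p) fav <- i
  }
  structure(list(qualities = q, winner = fav), class = "sequence_run")
}

#' Simulate many episodes and tally winners
#'
#' Vectorised Monte-Carlo engine: runs `runs` independent episodes of a
#' condition in parallel (one vectorised pass per serial position) and
#' returns the winner frequency per position together with binomial
#' standard errors.
#'
#' @param condition A [pcm_condition()].
#' @param runs Number of independent episodes, `>= 1`.
#'
#' @return A position-probability curve (see [position_curve()]) with
#'   `source = "monte_carlo"`.
#' @examples
#' set.seed(7)
#' simulate_runs(pcm_condition(6, inertia_schedule(0.9), quality_model(spread = 0)), 1e4)
#' @export
simulate_runs <- function(condition, runs) {
  stopifnot(inherits(condition, "pcm_condition"))
  if (length(runs) != 1L || is.na(runs) || runs < 1) stop("`runs` must be >= 1.", call. = FALSE)
  runs <- as.integer(runs)
  L <- condition$length
  qm <- condition$quality
  equal_q <- qm$spread == 0
  pis <- inertia_at(condition$schedule, seq_len(L))
  q_fav <- if (equal_q) rep(qm$mean, runs) else sample_qualities(qm, runs)
  fav <- rep(1L, runs)
  for (i in 2:L) {
    q_new <- if (equal_q) rep(qm$mean, runs) else sample_qualities(qm, runs)
    p <- acceptance_probability(q_new, q_fav, pis[i])
    take <- stats::runif(runs) < p
    fav[take] <- i
    q_fav[take] <- q_new[take]
  }
  counts <- tabulate(fav, nbins = L)
  p_hat <- counts / runs
  position_curve(p_hat,
                 se = sqrt(p_hat * (1 - p_hat) / runs),
                 source = "monte_carlo", n_runs = runs)
}
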