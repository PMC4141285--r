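#' Position-probability curve
#'
#' The central result container: for each serial position `j` of a sequence
#' of length `L`, the probability that the option presented at `j` is the
#' final favorite. Stored as a tibble subclass so results pipe directly
#' into dplyr/ggplot2 workflows.
#'
#' @param probabilities Numeric vector of per-position probabilities; must
#'   sum to 1 (within 1e-9).
#' @param se Per-position standard errors (zero for exact solvers).
#' @param source One of `"closed_form"`, `"path_dp"`, `"grid_dp"`,
#'   `"monte_carlo"`.
#' @param n_runs Number of Monte-Carlo runs behind the estimate, `NA` for
#'   exact sources.
#'
#' @return A tibble of class `pcm_curve` with columns `position`,
#'   `p_favorite`, `se` and attributes `length`, `source`, `n_runs`.
#' @examples
#' position_curve(c(0.25, 0.75), source = "path_dp")
#' @export
position_curve <- function(probabilities,
                           se = rep(0, length(probabilities)),
                           source = c("closed_form", "path_dp", "grid_dp", "monte_carlo"),
                           n_runs = NA_integer_) {
  source <- match.arg(source)
  L <- length(probabilities)
  if (L < 2) stop("a curve needs at least two positions.", call. = FALSE)
  if (any(probabilities < -1e-12) || any(probabilities > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (abs(sum(probabilities) - 1) > 1e-9) {
    stop("position probabilities must sum to 1.", call. = FALSE)
  }
  out <- tibble::tibble(position = seq_len(L),
                        p_favorite = as.numeric(probabilities),
                        se = as.numeric(se))
  structure(out, class = c("pcm_curve", class(out)),
            length = L, source = source, n_runs = n_runs)
}

curve_source <- function(curve) attr(curve, "source")

#' Exact curve for equal-quality sequences
#'
#' When every option has the same quality, the Luce comparison is a fair
#' coin and the acceptance probability at position `i` reduces to
#' `a_i = (1 - pi_i) / 2`. The final-favorite distribution then has the
#' closed form `p(j) = a_j * prod_{k > j} (1 - a_k)` for `j >= 2` and
#' `p(1) = prod_{k >= 2} (1 - a_k)`: the option at `j` must win its own
#' comparison and survive all later ones.
#'
#' @param length Sequence length `L >= 2`.
#' @param schedule An [inertia_schedule()] (or a static inertia level).
#'
#' @return A `pcm_curve` with `source = "closed_form"` and zero standard
#'   errors.
#' @examples
#' closed_form_equal_quality(6, inertia_schedule(0.9))
#' @export
closed_form_equal_quality <- function(length, schedule = inertia_schedule(0)) {
  schedule <- as_inertia_schedule(schedule)
  if (length(length) != 1L || length < 2) stop("`length` must be >= 2.", call. = FALSE)
  L <- as.integer(length)
  a <- c(0, (1 - inertia_at(schedule, 2:L)) / 2) # a[1] unused: no comparison at 1
  surv <- c(rev(cumprod(rev(1 - a[-1]))), 1)     # surv[j] = prod_{k > j} (1 - a_k)
  p <- a * surv
  p[1] <- surv[1]
  position_curve(p, source = "closed_form")
}

#' Exact curve for a fixed quality vector
#'
#' Forward dynamic programming over the identity of the current favorite:
#' after each comparison the distribution over "favorite is the option at
#' position f" is updated, moving mass `f -> i` with the acceptance
#' probability of the new option at `i`. Exact in O(L^2).
#'
#' With `average_permutations = TRUE` the curve is averaged over all `L!`
#' assignments of the supplied qualities to serial positions (the
#' random-position reading of a fixed option set); only practical for
#' `L <= 8`.
#'
#' @param qualities Non-negative quality values by serial position.
#' @param schedule An [inertia_schedule()] (or a static inertia level).
#' @param average_permutations Average over all orderings of `qualities`?
#'
#' @return A `pcm_curve` with `source = "path_dp"`.
#' @examples
#' path_dp(c(5, 5), inertia_schedule(0.6)) # p = (0.8, 0.2)
#' @export
path_dp <- function(qualities, schedule = inertia_schedule(0),
                    average_permutations = FALSE) {
  schedule <- as_inertia_schedule(schedule)
  if (length(qualities) < 2) stop("need at least two qualities.", call. = FALSE)
  if (any(is.na(qualities)) || any(qualities < 0)) {
    stop("qualities must be non-negative.", call. = FALSE)
  }
  if (average_permutations) {
    L <- length(qualities)
    if (L > 8) stop("permutation averaging is limited to L <= 8.", call. = FALSE)
    perms <- permutations_of(L)
    p <- rowMeans(vapply(perms,
                         function(ord) path_dp_probs(qualities[ord], schedule),
                         numeric(L)))
    return(position_curve(p, source = "path_dp"))
  }
  position_curve(path_dp_probs(qualities, schedule), source = "path_dp")
}

path_dp_probs <- function(q, schedule) {
  L <- length(q)
  pis <- inertia_at(schedule, seq_len(L))
  m <- numeric(L)
  m[1] <- 1
  for (i in 2:L) {
    f <- seq_len(i - 1L)
    a <- acceptance_probability(rep(q[i], i - 1L), q[f], pis[i])
    m[i] <- sum(m[f] * a)
    m[f] <- m[f] * (1 - a)
  }
  m
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  unlist(lapply(seq_len(n), function(k) {
    lapply(sub, function(p) c(k, p + (p >= k)))
  }), recursive = FALSE)
}

#' Exact curve for a finite-support quality distribution
#'
#' Dynamic programming over the joint state (favorite position, favorite
#' quality) when option qualities are i.i.d. draws from a finite support
#' with given weights. Each new position integrates the acceptance rule
#' over the new option's quality. This is the exact average of
#' [path_dp()] over all `|support|^L` quality tuples, computed in
#' O(L * (L + G) * G) instead.
#'
#' @param support Numeric vector of distinct non-negative quality values.
#' @param weights Positive weights, same length as `support`; normalised
#'   internally.
#' @param length Sequence length `L >= 2`.
#' @param schedule An [inertia_schedule()] (or a static inertia level).
#' @param source Label recorded on the returned curve.
#'
#' @return A `pcm_curve`.
#' @examples
#' support_dp(c(2, 5, 8), rep(1, 3), length = 3, schedule = inertia_schedule(0.3, 0.3))
#' @export
support_dp <- function(support, weights, length, schedule = inertia_schedule(0),
                       source = "grid_dp") {
  schedule <- as_inertia_schedule(schedule)
  stopifnot(length(support) == length(weights))
  if (any(support < 0)) stop("support must be non-negative.", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be positive.", call. = FALSE)
  if (length(length) != 1L || length < 2) stop("`length` must be >= 2.", call. = FALSE)
  L <- as.integer(length)
  G <- length(support)
  w <- weights / sum(weights)
  pis <- inertia_at(schedule, seq_len(L))

  # ratio[j, k] = support[j] / (support[j] + support[k]), 0/0 -> 1/2
  tot <- outer(support, support, `+`)
  ratio <- outer(support, rep(1, G)) / ifelse(tot == 0, 1, tot)
  ratio[tot == 0] <- 0.5
  # rbar[k] = E_qnew[ ratio(qnew, k) ]: chance a random challenger beats quality k
  rbar <- as.numeric(crossprod(w, ratio))

  m <- matrix(0, nrow = L, ncol = G) # m[f, k] = P(favorite at f with quality support[k])
  m[1, ] <- w
  for (i in 2:L) {
    one_minus_pi <- 1 - pis[i]
    mq <- colSums(m[seq_len(i - 1L), , drop = FALSE]) # mass by favorite quality
    m[seq_len(i - 1L), ] <- m[seq_len(i - 1L), , drop = FALSE] *
      rep(1 - one_minus_pi * rbar, each = i - 1L)
    m[i, ] <- w * one_minus_pi * as.numeric(ratio %*% mq)
  }
  position_curve(rowSums(m), source = source)
}

#' Exact curve for the truncated-normal quality model
#'
#' Deterministic solver for conditions with quality variability: the
#' truncated-normal density is discretised onto `grid_size` midpoints of
#' equal-width cells over `[lower, upper]`, each weighted by the normal
#' mass of its cell (renormalised), and the finite-support dynamic program
#' [support_dp()] is run on that grid. Converges to the continuous-model
#' answer as `grid_size` grows; `grid_size = 400` is well inside
#' Monte-Carlo resolution at 100,000 runs.
#'
#' @param condition A [pcm_condition()] with `spread > 0` (use
#'   [closed_form_equal_quality()] for the degenerate case).
#' @param grid_size Number of grid cells, `>= 2`.
#'
#' @return A `pcm_curve` with `source = "grid_dp"`.
#' @examples
#' grid_dp(pcm_condition(4, inertia_schedule(0.3)), grid_size = 200)
#' @export
grid_dp <- function(condition, grid_size = 400) {
  stopifnot(inherits(condition, "pcm_condition"))
  if (grid_size < 2) stop("`grid_size` must be >= 2.", call. = FALSE)
  qm <- condition$quality
  if (qm$spread == 0) {
    stop("`spread` is 0: use closed_form_equal_quality() for equal qualities.",
         call. = FALSE)
  }
  g <- quality_grid(qm, grid_size)
  support_dp(g$support, g$weights, condition$length, condition$schedule,
             source = "grid_dp")
}

quality_grid <- function(model, grid_size) {
  edges <- seq(model$lower, model$upper, length.out = grid_size + 1L)
  cdf <- stats::pnorm(edges, model$mean, model$spread)
  w <- diff(cdf)
  list(support = (edges[-1] + edges[-length(edges)]) / 2,
       weights = w / sum(w))
}
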