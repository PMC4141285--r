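# Brute-force oracle: average path_dp over every quality tuple of a finite
# support, weighting by the product of the tuple's draw probabilities.
# Exponential in L; use only for tiny cases.
enumerate_support_curve <- function(support, weights, length, schedule) {
  weights <- weights / sum(weights)
  idx <- do.call(expand.grid, rep(list(seq_along(support)), length))
  p <- numeric(length)
  for (r in seq_len(nrow(idx))) {
    ord <- as.integer(idx[r, ])
    p <- p + prod(weights[ord]) * path_dp(support[ord], schedule)$p_favorite
  }
  p
}

# The canonical sensitivity-analysis grid, small helpers for tests.
paper_lengths <- c(2L, 4L, 6L, 10L, 12L, 20L)
paper_inertias <- c(0, 0.3, 0.6, 0.9)
paper_dynamics <- c(0, 0.3)

curve_for <- function(results, sp, L, p1, cc) {
  rows <- results[results$spread == sp & results$length == L &
                    results$pi1 == p1 & results$c == cc, ]
  rows[order(rows$position), ]
}
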