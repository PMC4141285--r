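test_that("closed form matches hand-derived equal-quality values", {
  expect_equal(closed_form_equal_quality(2, inertia_schedule(0))$p_favorite,
               c(0.5, 0.5))
  cf0 <- closed_form_equal_quality(6, inertia_schedule(0))$p_favorite
  expect_equal(cf0[6], 0.5)
  expect_equal(cf0[1], 0.5^5)
  expect_equal(cf0[2], 0.5^5)
  cf9 <- closed_form_equal_quality(6, inertia_schedule(0.9))$p_favorite
  expect_equal(cf9[1], 0.95^5)
  expect_equal(cf9[6], 0.05)
})

test_that("closed form and path DP agree exactly on constant qualities", {
  for (L in paper_lengths) {
    for (pi1 in paper_inertias) {
      for (cc in paper_dynamics) {
        sched <- inertia_schedule(pi1, cc)
        expect_equal(closed_form_equal_quality(L, sched)$p_favorite,
                     path_dp(rep(5, L), sched)$p_favorite,
                     tolerance = 1e-13)
      }
    }
  }
})

test_that("path DP reproduces single-comparison and dominance cases", {
  expect_equal(path_dp(c(5, 5), inertia_schedule(0.6))$p_favorite, c(0.8, 0.2))
  # a zero-quality challenger never displaces a positive favorite
  expect_equal(path_dp(c(10, 0, 0), inertia_schedule(0))$p_favorite, c(1, 0, 0))
  expect_error(path_dp(c(-1, 2), inertia_schedule(0)), "non-negative")
  expect_error(path_dp(3, inertia_schedule(0)), "two")
})

test_that("permutation averaging equalises exchangeable options", {
  sched <- inertia_schedule(0.3, 0.3)
  # identical qualities: averaging over orders changes nothing
  expect_equal(path_dp(rep(2, 4), sched, average_permutations = TRUE)$p_favorite,
               path_dp(rep(2, 4), sched)$p_favorite)
  # distinct qualities: hand enumeration over all 3! orders
  q <- c(1, 4, 9)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  manual <- Reduce(`+`, lapply(perms, function(o) path_dp(q[o], sched)$p_favorite)) / 6
  expect_equal(path_dp(q, sched, average_permutations = TRUE)$p_favorite,
               manual, tolerance = 1e-13)
  expect_error(path_dp(rep(1, 9), sched, average_permutations = TRUE), "L <= 8")
})

test_that("finite-support DP equals brute-force enumeration of path DP", {
  cases <- list(
    list(support = c(2, 5, 8), weights = c(0.2, 0.5, 0.3), L = 3,
         sched = inertia_schedule(0.3, 0.3)),
    list(support = c(0, 1, 3, 7, 10), weights = rep(0.2, 5), L = 4,
         sched = inertia_schedule(0.6, 0)),
    list(support = c(1, 9), weights = c(0.5, 0.5), L = 4,
         sched = inertia_schedule(0, 0.3))
  )
  for (cs in cases) {
    expect_equal(
      support_dp(cs$support, cs$weights, cs$L, cs$sched)$p_favorite,
      enumerate_support_curve(cs$support, cs$weights, cs$L, cs$sched),
      tolerance = 1e-13)
  }
})

test_that("grid DP respects exchange symmetry and converges with the grid", {
  # positions 1 and 2 are exchangeable without inertia
  g2 <- grid_dp(pcm_condition(2, inertia_schedule(0)), grid_size = 400)
  expect_equal(g2$p_favorite, c(0.5, 0.5), tolerance = 1e-6)
  cond <- pcm_condition(6, inertia_schedule(0.3, 0.3))
  gs <- lapply(c(50, 100, 200, 400), function(G) grid_dp(cond, G)$p_favorite)
  gaps <- sapply(1:3, function(k) max(abs(gs[[k + 1]] - gs[[k]])))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-5)
})

test_that("grid DP refuses the degenerate equal-quality case", {
  cond <- pcm_condition(4, inertia_schedule(0.3), quality_model(spread = 0))
  expect_error(grid_dp(cond), "closed_form_equal_quality")
})

test_that("grid DP matches Monte Carlo under quality variability", {
  cond <- pcm_condition(4, inertia_schedule(0.3), quality_model())
  g <- grid_dp(cond, grid_size = 400)
  set.seed(31)
  mc <- simulate_runs(cond, 1e5)
  z <- abs(mc$p_favorite - g$p_favorite) /
    sqrt(g$p_favorite * (1 - g$p_favorite) / 1e5)
  expect_true(all(z < 3))
})

test_that("every solver yields a conserved, well-formed curve", {
  curves <- list(
    closed_form_equal_quality(12, inertia_schedule(0.6, 0.3)),
    path_dp(c(3, 8, 1, 6), inertia_schedule(0.3)),
    grid_dp(pcm_condition(10, inertia_schedule(0.9, 0.3)), 200)
  )
  for (cv in curves) {
    expect_s3_class(cv, "pcm_curve")
    expect_equal(sum(cv$p_favorite), 1, tolerance = 1e-12)
    expect_true(all(cv$p_favorite >= 0 & cv$p_favorite <= 1))
    expect_true(all(cv$se == 0))
  }
  expect_error(position_curve(c(0.2, 0.2)), "sum to 1")
  expect_error(position_curve(c(1.4, -0.4)), "\\[0, 1\\]")
})

test_that("equal-quality curves show monotone recency below full inertia", {
  for (pi1 in c(0, 0.3, 0.6, 0.9)) {
    p <- closed_form_equal_quality(10, inertia_schedule(pi1))$p_favorite
    expect_true(all(diff(p[2:10]) > 0))
  }
  # full inertia: all mass on the first option
  expect_equal(closed_form_equal_quality(8, inertia_schedule(1))$p_favorite,
               c(1, rep(0, 7)))
})
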