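test_that("inertia schedule reproduces hand-computed values", {
  # static schedule: growth exponent 0 leaves inertia flat
  expect_equal(inertia_at(inertia_schedule(0.3, c = 0), 7), 0.3)
  # position 1 is the anchor for every growth exponent
  expect_equal(inertia_at(inertia_schedule(0.6, c = 0.3), 1), 0.6)
  # 1 - 0.7 * 2 / (1 + 10^0.3), evaluated independently
  expect_equal(inertia_at(inertia_schedule(0.3, c = 0.3), 10), 0.5325952,
               tolerance = 1e-7)
})

test_that("inertia schedule is anchored, bounded and monotone over a grid", {
  for (pi1 in c(0, 0.25, 0.6, 0.9, 1)) {
    for (cc in c(0, 0.15, 0.5, 1)) {
      sched <- inertia_schedule(pi1, cc)
      pis <- inertia_at(sched, 1:50)
      expect_equal(pis[1], pi1)
      expect_true(all(pis >= pi1 - 1e-12 & pis <= 1 + 1e-12))
      if (cc == 0) {
        expect_equal(pis, rep(pi1, 50))
      } else if (pi1 < 1) {
        expect_true(all(diff(pis) > 0))
        # approaches 1 in the limit; convergence rate is ~ i^-c
        expect_lt(1 - inertia_at(sched, 1e12), 0.05 * (1 - pi1) + 1e-12)
      }
    }
  }
})

test_that("schedule and position arguments are validated", {
  expect_error(inertia_schedule(-0.1), "pi1")
  expect_error(inertia_schedule(0.5, c = 1.5), "c")
  expect_error(inertia_at(inertia_schedule(0.5), 0), "position")
})

test_that("acceptance probability follows the inertia-weighted Luce rule", {
  expect_equal(acceptance_probability(5, 5, 0), 0.5)
  expect_equal(acceptance_probability(5, 5, 0.6), 0.2)
  # both qualities zero: symmetric completion gives ratio 1/2
  expect_equal(acceptance_probability(0, 0, 0.3), 0.35)
  expect_error(acceptance_probability(-1, 5, 0), "non-negative")
  expect_error(acceptance_probability(5, 5, 1.2), "inertia")
})

test_that("acceptance probability is bounded and monotone in the qualities", {
  qs <- c(0, 0.5, 2, 5, 9.7)
  for (pi in c(0, 0.3, 0.9)) {
    for (q_old in qs) {
      p <- acceptance_probability(qs, rep(q_old, length(qs)), pi)
      expect_true(all(p >= 0 & p <= 1 - pi + 1e-12))
      # strictly increasing in q_new (flat at 1 - pi when q_old = 0)
      if (q_old > 0) expect_true(all(diff(p) > 0))
    }
    for (q_new in qs[-1]) {
      p <- acceptance_probability(rep(q_new, length(qs)), qs, pi)
      expect_true(all(diff(p) < 0)) # decreasing in q_old
    }
    expect_equal(acceptance_probability(3, 3, pi), (1 - pi) / 2)
  }
})

test_that("quality sampling honours the degenerate and truncated cases", {
  expect_equal(sample_qualities(quality_model(mean = 5, spread = 0), 4),
               rep(5, 4))
  qm <- quality_model(mean = 5, spread = 5, lower = 0, upper = 10)
  set.seed(101)
  x <- sample_qualities(qm, 1e5)
  expect_true(min(x) >= 0 && max(x) <= 10)
  # symmetric truncation about the mean preserves it; 3 SEs of the sample mean
  expect_lt(abs(mean(x) - 5), 3 * sd(x) / sqrt(length(x)))
  set.seed(101)
  expect_identical(sample_qualities(qm, 1e5), x)
})

test_that("quality model rejects inconsistent parameters", {
  expect_error(quality_model(spread = -1), "spread")
  expect_error(quality_model(lower = 4, upper = 4), "lower")
  expect_error(quality_model(mean = 12, spread = 0), "bounds")
})

test_that("single-sequence simulation respects the process contract", {
  cond <- pcm_condition(4, inertia_schedule(0.3, 0.3), quality_model())
  set.seed(5)
  run <- simulate_sequence(cond)
  expect_s3_class(run, "sequence_run")
  expect_length(run$qualities, 4)
  expect_true(all(run$qualities >= 0 & run$qualities <= 10))
  expect_true(run$winner %in% 1:4)
  # full inertia: the first option can never be displaced
  frozen <- pcm_condition(5, inertia_schedule(1), quality_model())
  winners <- replicate(50, simulate_sequence(frozen)$winner)
  expect_true(all(winners == 1L))
})

test_that("vectorised runs match the closed form within Monte-Carlo noise", {
  set.seed(20)
  eq <- quality_model(spread = 0)
  # one fair comparison: the newcomer wins half the time
  mc2 <- simulate_runs(pcm_condition(2, inertia_schedule(0), eq), 1e5)
  expect_lt(abs(mc2$p_favorite[2] - 0.5), 3 * sqrt(0.25 / 1e5))
  # survival of the first option under strong inertia: (1 - 0.05)^5
  mc6 <- simulate_runs(pcm_condition(6, inertia_schedule(0.9), eq), 1e5)
  p1 <- 0.95^5
  expect_lt(abs(mc6$p_favorite[1] - p1), 3 * sqrt(p1 * (1 - p1) / 1e5))
  expect_equal(sum(mc6$p_favorite), 1)
  expect_equal(mc6$se, sqrt(mc6$p_favorite * (1 - mc6$p_favorite) / 1e5))
})

test_that("simulation with a fixed seed is bit-reproducible", {
  cond <- pcm_condition(6, inertia_schedule(0.6, 0.3), quality_model())
  set.seed(99)
  a <- simulate_runs(cond, 5000)
  set.seed(99)
  b <- simulate_runs(cond, 5000)
  expect_identical(a$p_favorite, b$p_favorite)
})
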