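test_that("encounter statistics summarize post-burn-in intervals", {
  tr <- linear_trace(500, dt = 0.01, n_ribosomes = 100)
  es <- encounter_stats(tr, burn_in = 100)
  expect_equal(es$mean, 0.01)
  expect_equal(es$median, 0.01)
  expect_equal(es$sd, 0)
  expect_equal(es$n, 399)
  expect_error(encounter_stats(tr, burn_in = 499), "too short")
})

test_that("elongation rate is the per-ribosome OLS slope", {
  # events at exactly 10 ms spacing, 100 ribosomes: slope 100/s -> 1 aa/rib/s
  tr <- linear_trace(1000, dt = 0.01, n_ribosomes = 100)
  est <- elongation_rate(tr, burn_in = 100)
  expect_equal(est$rate, 1)
  expect_equal(est$slope, 100)
  # OLS equals total steps / total time for perfectly linear traces
  kept <- tr[101:1000, ]
  expect_equal(est$slope,
               diff(range(kept$cumulative_steps)) / diff(range(kept$time_s)))
})

test_that("elongation rate ignores events before the analysis window", {
  base <- linear_trace(600, dt = 0.02, n_ribosomes = 10)
  # prepend a fast transient: only the window should matter
  warped <- base
  warped$time_s[1:100] <- seq(0, 0.1, length.out = 100)
  expect_equal(elongation_rate(warped, burn_in = 100)$rate,
               elongation_rate(base, burn_in = 100)$rate)
})

test_that("replicate rates agree across independent master seeds", {
  scen <- scen_small()
  sq <- fixture_gfp()
  st <- steps_small()
  a <- replicate_rate(scen, sq, n_seeds = 4, master_seed = 1,
                      stop_steps = st$stop, burn_in_steps = st$burn)
  b <- replicate_rate(scen, sq, n_seeds = 4, master_seed = 99,
                      stop_steps = st$stop, burn_in_steps = st$burn)
  expect_equal(a$n_seeds, 4)
  expect_length(a$per_seed, 4)
  expect_gt(a$se, 0)
  expect_equal(a$se, sd(a$per_seed) / 2)
  expect_lt(abs(a$rate - b$rate), 4 * sqrt(a$se^2 + b$se^2) + 1e-9)
  # deterministic seed derivation: same master seed, same result
  a2 <- replicate_rate(scen, sq, n_seeds = 4, master_seed = 1,
                       stop_steps = st$stop, burn_in_steps = st$burn)
  expect_identical(a$per_seed, a2$per_seed)
})

test_that("slope comparison reproduces an independent regression oracle", {
  # synthetic noisy traces with distinct known slopes
  make_noisy <- function(n, rate_per_s, seed) {
    dt <- withr::with_seed(seed, rexp(n, rate_per_s))
    structure(data.frame(event_index = seq_len(n), time_s = cumsum(dt),
                         cumulative_steps = seq_len(n)),
              n_ribosomes = 50, seed = seed, burn_in_steps = 0,
              class = c("elongation_trace", "data.frame"))
  }
  a <- make_noisy(3000, 1000, seed = 21)
  b <- make_noisy(3000, 1100, seed = 22)
  res <- compare_slopes(a, b, burn_in = 1000, window_end = 3000)
  expect_equal(res$df, 3996)  # 2000 + 2000 - 4

  # brute-force oracle: two independent lm fits
  fit_a <- lm(cumulative_steps ~ time_s, a[1001:3000, ])
  fit_b <- lm(cumulative_steps ~ time_s, b[1001:3000, ])
  b1 <- coef(fit_a)[2]; s1 <- summary(fit_a)$coefficients[2, 2]
  b2 <- coef(fit_b)[2]; s2 <- summary(fit_b)$coefficients[2, 2]
  z_oracle <- unname((b1 - b2) / sqrt(s1^2 + s2^2))
  expect_equal(res$z, z_oracle)
  expect_lt(res$p, 0.001)  # slopes differ by construction

  same <- compare_slopes(a, a, burn_in = 1000, window_end = 3000)
  expect_equal(same$z, 0)
  expect_error(compare_slopes(a, b, window_end = 5000), "exceeds trace length")
})

test_that("estimated system rate is consistent for Poissonian traces", {
  lambda <- 2000
  dt <- withr::with_seed(31, rexp(8000, lambda))
  tr <- structure(data.frame(event_index = 1:8000, time_s = cumsum(dt),
                             cumulative_steps = 1:8000),
                  n_ribosomes = 1, seed = 31, burn_in_steps = 0,
                  class = c("elongation_trace", "data.frame"))
  est <- elongation_rate(tr, burn_in = 1000)
  expect_lt(abs(est$slope - lambda) / lambda, 0.05)
})
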