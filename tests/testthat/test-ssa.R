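test_that("jump rate follows the discretized diffusion equation", {
  expect_equal(jump_rate(2.567e-12, 20e-9), 6417.5)
  expect_equal(jump_rate(0, 1e-9), 0)
  expect_equal(jump_rate(1, 1), 1)
  expect_error(jump_rate(1, 0))
})

test_that("total propensity decomposes into travel and dissociation channels", {
  expect_equal(total_propensity(0, D = 1, h = 1, k_diss = 1)$alpha0, 0)
  # 10 complexes, d = 100 per direction, k_diss = 1: 10 * (600 + 1)
  res <- total_propensity(10, D = 100, h = 1, k_diss = 1)
  expect_equal(res$alpha0, 6010)
  expect_equal(res$travel, 6000)
  expect_equal(res$diss, 10)
  pure <- total_propensity(c(A = 3, B = 4), D = 2, h = 1, k_diss = 0)
  expect_equal(pure$alpha0, pure$travel)
  expect_equal(pure$per_species$diss, c(0, 0))
  expect_equal(pure$per_species$travel, c(3, 4) * 12)
})

test_that("waiting times are exponential with rate alpha0", {
  expect_equal(sample_tau(1, exp(-1)), 1)
  expect_equal(sample_tau(2, exp(-2)), 1)
  expect_error(sample_tau(0), "stalled")
  r1 <- withr::with_seed(50, runif(1e5))
  taus <- sample_tau(40, r1)
  ks <- ks.test(taus, "pexp", rate = 40)
  expect_gt(ks$p.value, 0.01)
})

test_that("channel selection follows the direct-method rule", {
  expect_equal(select_channel(c(1, 1), 0.4), 1L)
  expect_equal(select_channel(c(1, 3), 0.5), 2L)
  expect_equal(select_channel(c(0, 0, 5), 0.99), 3L)
  expect_error(select_channel(c(0, 0)), "all-zero")
  # frequency property: selection frequencies proportional to propensities
  props <- c(2, 5, 1, 12)
  r2 <- withr::with_seed(6, runif(1e5))
  picks <- findInterval(r2 * sum(props), cumsum(props)) + 1  # vectorized oracle
  sel <- vapply(r2[1:2000], function(r) select_channel(props, r), integer(1))
  expect_equal(sel, picks[1:2000])
  p <- chisq.test(table(factor(picks, levels = 1:4)),
                  p = props / sum(props))$p.value
  expect_gt(p, 0.01)
})

test_that("simulation traces are reproducible and well-formed", {
  scen <- scen_small()
  sq <- fixture_gfp()
  st <- steps_small()
  tr1 <- run_simulation(scen, sq, seed = 9, stop_steps = st$stop,
                        burn_in_steps = st$burn)
  tr2 <- run_simulation(scen, sq, seed = 9, stop_steps = st$stop,
                        burn_in_steps = st$burn)
  expect_identical(tr1$time_s, tr2$time_s)
  expect_equal(nrow(tr1), st$stop)
  expect_true(all(diff(tr1$time_s) > 0))
  expect_equal(tr1$cumulative_steps, seq_len(st$stop))
  tr3 <- run_simulation(scen, sq, seed = 10, stop_steps = st$stop,
                        burn_in_steps = st$burn)
  expect_false(identical(tr1$time_s, tr3$time_s))
})

test_that("degenerate scenarios fail with stall diagnostics", {
  scen <- scen_single_species(n_rib = 5, n_eftu = 0, pool = 10)
  sq <- codon_sequence(c("GCA", "GCA"))
  expect_error(run_simulation(scen, sq), "stalled system")
  # a sequence demanding a species the scenario lacks
  scen2 <- scen_single_species()
  expect_error(run_simulation(scen2, codon_sequence("TGG")), "absent")
  # event-count guard reports a stall instead of hanging
  scen3 <- scen_single_species(n_rib = 1, n_eftu = 2, pool = 4)
  expect_error(
    run_simulation(scen3, codon_sequence("GCA"), stop_steps = 5000,
                   max_events = 2e4),
    "stalled after"
  )
})

test_that("per-ribosome rate never exceeds the catalytic cap", {
  # saturating cognate pool, single codon type: rate approaches 24 aa/s
  scen <- scen_single_species(n_rib = 20, n_eftu = 500, pool = 600)
  sq <- codon_sequence(rep("GCA", 10))
  tr <- run_simulation(scen, sq, seed = 2, stop_steps = 2000,
                       burn_in_steps = 200)
  est <- elongation_rate(tr)
  expect_lte(est$rate, 24)
  expect_gt(est$rate, 20)
})

test_that("tracer mean squared displacement matches 6 D t", {
  D <- 2.567e-12; h <- 20e-9; t_end <- 1e-4
  r2 <- tracer_msd(1500, D, h, t_end, seed = 4)
  msd <- mean(r2)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(msd - 6 * D * t_end), 3 * se)
})

test_that("complex lifetimes through the two-channel machinery are exponential", {
  lt <- dissociation_lifetimes(5000, d_per_dir = 100, k_diss = 2, seed = 8)
  ks <- ks.test(lt, "pexp", rate = 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("jump directions are uniform and tRNA pools are conserved", {
  scen <- scen_small()
  d <- ssa_diagnostics(scen, fixture_gfp(), n_events = 1e6, seed = 5)
  # per-species conservation: bound + free equals the initial pool
  expect_equal(unname(d$free_final + d$bound_final),
               unname(as.integer(d$trna_initial)))
  expect_equal(sum(d$bound_final), d$n_complexes)
  # direction uniformity, 1/6 each
  p <- chisq.test(d$dir_counts)$p.value
  expect_gt(p, 0.01)
  expect_equal(d$n_jumps + d$n_diss, d$n_events)
})

test_that("per-ribosome rate is intensive under volume rescaling", {
  sq <- fixture_tufa()
  small <- scen_small()
  large <- in_vivo_scenario(volume_um3 = 0.013824)  # (12 * 20 nm)^3
  r_small <- replicate_rate(small, sq, n_seeds = 3, master_seed = 2,
                            stop_steps = 1250, burn_in_steps = 500)
  r_large <- replicate_rate(large, sq, n_seeds = 3, master_seed = 2,
                            stop_steps = 2160, burn_in_steps = 864)
  se <- sqrt(r_small$se^2 + r_large$se^2)
  expect_lt(abs(r_small$rate - r_large$rate), 3 * se + 1e-6)
})
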