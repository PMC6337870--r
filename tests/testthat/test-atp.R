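test_that("flux demand multiplies its factors", {
  expect_equal(flux_demand(1, 1, 1), 1)
  expect_equal(flux_demand(0, 0.5, 10), 0)
  expect_equal(flux_demand(13500, 0.8, 16), 172800)
})

test_that("RNA cost sums per-base ATP equivalents", {
  tab <- cost_table()
  expect_equal(rna_cost(c(A = 1), tab), 11)
  expect_equal(rna_cost(numeric(0), tab), 0)
  # 76-nt tRNA at equal base composition: 19 * (6 + 7 + 11 + 12) = 684
  expect_equal(rna_cost(c(U = 19, C = 19, A = 19, G = 19), tab), 684)
  expect_error(rna_cost(c(X = 1), tab), "unknown base")
})

test_that("protein cost separates synthesis and translation terms", {
  # ribosomal protein content: translation alone is 4 * 7459
  rp <- protein_cost(7459, synthesis_atp = 35689)
  expect_equal(rp$translation, 29836)
  # EFTu: published synthesis 1989 + translation 4 * 394 = 1576
  ef <- protein_cost(394, synthesis_atp = 1989)
  expect_equal(ef$translation, 1576)
  expect_equal(ef$total, 3565)
  expect_equal(protein_cost(0), list(synthesis = 0, translation = 0, total = 0))
  expect_error(protein_cost(10, aa_counts = c(A = 3)), "inconsistent")
  # composition route uses the amino-acid table
  cc <- protein_cost(2, aa_counts = c(A = 1, G = 1))
  expect_equal(cc$translation, 8)
  expect_gt(cc$synthesis, 0)
})

test_that("ATP allocation floors counts and respects the budget", {
  costs <- unit_costs()
  a <- allocate_atp(1e8, c(0.375, 0.125, 0.5))
  expect_equal(unname(a$added["ribosome"]), floor(3.75e7 / 108461))  # 345
  expect_equal(unname(a$added["ribosome"]), 345)
  expect_lte(a$spent, 1e8)
  expect_equal(unname(allocate_atp(0, c(1, 0, 0))$added), c(0, 0, 0))
  expect_equal(unname(allocate_atp(108461, c(1, 0, 0))$added["ribosome"]), 1)
  # property: spent <= budget on random simplex points
  pts <- simplex_grid(1 / 5)
  for (i in seq_len(nrow(pts))) {
    al <- allocate_atp(3.3e7, as.numeric(pts[i, ]))
    expect_lte(al$spent, 3.3e7)
  }
  expect_error(allocate_atp(1, c(0.5, 0.5, 0.5)))
})

test_that("added tRNAs are split over species by largest remainder", {
  base <- load_default_tables()$trna
  a <- allocate_atp(1e7, c(0, 1, 0), trna_baseline = base)
  expect_equal(sum(a$trna_by_species), unname(a$added["trna"]))
  expect_true(all(a$trna_by_species >= 0))
  # proportionality: largest baseline species gets the most additions
  expect_equal(names(which.max(a$trna_by_species)), names(which.max(base)))
  u <- allocate_atp(1e6, c(0, 1, 0), trna_baseline = base,
                    trna_split = "uniform")
  expect_lte(diff(range(u$trna_by_species)), 1)
})

test_that("simplex grids have the closed-form point count", {
  expect_equal(nrow(simplex_grid(1 / 8)), choose(10, 2))  # 45
  expect_equal(nrow(simplex_grid(1 / 10)), choose(12, 2)) # 66
  g <- simplex_grid(1 / 4)
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  expect_error(simplex_grid(0.3), "divide 1 evenly")
})

test_that("ATP amounts convert to production minutes and doubling fractions", {
  ctx <- atp_context(1)
  expect_equal(ctx$minutes, 1000 / (3.56 * 311))
  expect_equal(ctx$minutes, 0.9, tolerance = 0.01)
  expect_equal(ctx$fraction, 0.024, tolerance = 0.02)
  expect_equal(atp_context(0)$minutes, 0)
  # 10 fmol: 9 minutes, 24% of a doubling
  ctx10 <- atp_context(10)
  expect_equal(ctx10$minutes, 9, tolerance = 0.01)
  expect_equal(ctx10$fraction, 0.24, tolerance = 0.02)
})

test_that("zero-budget simplex sweeps stay at the unaltered rate", {
  scen <- scen_small()
  sq <- fixture_gfp()
  st <- steps_small()
  sw <- simplex_sweep(scen, sq, budget = 0, resolution = 1 / 2, n_seeds = 2,
                      master_seed = 5, stop_steps = st$stop,
                      burn_in_steps = st$burn)
  expect_equal(nrow(sw$grid), 6)
  # identical seeds, identical scenario: exactly 1 everywhere
  expect_true(all(abs(sw$grid$norm_rate - 1) < 1e-12))
})
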