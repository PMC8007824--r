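test_that("phospho proximity counts exclude the site and respect the window", {
  ms <- data.frame(protein = "P1", position = 100)
  ph <- data.frame(protein = "P1", position = c(98, 103, 104, 100))
  expect_equal(phospho_proximity(ms, ph, w = 3)$counts, 2L)
  expect_equal(phospho_proximity(ms, ph, w = 5)$counts, 3L)

  ms2 <- data.frame(protein = "P2", position = c(10, 20, 30, 40, 50))
  ph2 <- data.frame(protein = "P2",
                    position = c(31, 41, 42, 48, 49, 51, 52))
  res <- phospho_proximity(ms2, ph2, w = 3)
  expect_equal(res$counts, c(0L, 0L, 1L, 2L, 4L))
  expect_equal(unname(res$bins), c(0.4, 0.2, 0.2, 0, 0.2))
  expect_equal(sum(res$bins), 1)
  expect_equal(res$frac_ge1, 0.6)
})

test_that("proximity counts are monotone in the window width", {
  sim <- simulate_all(sim_config(seed = 21, n_proteins = 450,
                                 n_phospho = 1500))
  ms <- sim$truth$substrate_sites
  c3 <- phospho_proximity(ms, sim$phospho, w = 3)
  c5 <- phospho_proximity(ms, sim$phospho, w = 5)
  expect_true(all(c5$counts >= c3$counts))
  expect_gte(c5$frac_ge1, c3$frac_ge1)
})

test_that("phospho null distribution handles the empty and clustered cases", {
  db <- c(P1 = strrep("RA", 200))
  none <- phospho_background(db, data.frame(protein = character(0),
                                            position = integer(0)),
                             n_fg = 20, observed_ge1 = 0, n_resamples = 99,
                             seed = 1)
  expect_true(all(none$bg_ge1 == 0))
  expect_equal(none$p_value, 1)

  # planted clustering at 10x density is detected
  cfg <- sim_config(seed = 22, n_proteins = 450, phospho_enrichment = 10)
  sim <- simulate_all(cfg)
  ms <- sim$truth$substrate_sites
  obs <- phospho_proximity(ms, sim$phospho, w = 3)
  nullp <- phospho_background(sim$proteome, sim$phospho, n_fg = nrow(ms),
                              observed_ge1 = obs$frac_ge1, w = 3,
                              n_resamples = 999, seed = 23, exclude = ms)
  expect_lte(nullp$p_value, 0.01)
})

test_that("mutation rates respect mode, dedup and protein bounds", {
  db <- c(P1 = strrep("A", 200), P2 = strrep("A", 200))
  mut <- data.frame(protein = "P1", position = c(97, 105, 120))

  two <- data.frame(protein = c("P1", "P2"), position = c(97, 100))
  expect_equal(mutation_rate(two, mut, mode = "at_site")$rate, 0.5)

  one <- data.frame(protein = "P1", position = 100)
  v <- mutation_rate(one, mut, db, w = 5, mode = "vicinity")
  expect_equal(v$n_positions, 11)
  expect_equal(v$n_mutated, 2)
  expect_equal(v$rate, 2 / 11)

  adj <- data.frame(protein = "P1", position = c(100, 102))
  expect_equal(mutation_rate(adj, mut, db, w = 5,
                             mode = "vicinity")$n_positions, 13)

  # clipped at the N-terminus
  edge <- data.frame(protein = "P1", position = 2)
  pe <- mutation_rate(edge, mut, db, w = 5, mode = "vicinity")
  expect_equal(pe$n_positions, 7)
  expect_true(all(pe$positions$position >= 1))
})

test_that("mutation enrichment builds the 2x2 table and exact p correctly", {
  # contingency example with a strong association
  p <- fisher_exact(rbind(c(10, 90), c(20, 1980)))
  expect_equal(p$odds_ratio, 11.0)
  expect_equal(p$p_value, oracle_fisher_two_sided(10, 90, 20, 1980),
               tolerance = 1e-12)

  sym <- fisher_exact(rbind(c(5, 5), c(5, 5)))
  expect_equal(sym$odds_ratio, 1.0)
  expect_equal(sym$p_value, 1.0)

  expect_warning(res <- fisher_exact(rbind(c(0, 10), c(0, 10))),
                 "degenerate")
  expect_equal(res$p_value, 1)
  expect_error(fisher_exact(rbind(c(-1, 1), c(1, 1))), "negative")
})

test_that("fisher_exact matches stats::fisher.test across random tables", {
  set.seed(9)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 8), 2)
    ours <- suppressWarnings(fisher_exact(tab))
    ref <- stats::fisher.test(tab)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("planted mutation hotspots give enriched odds ratios", {
  cfg <- sim_config(seed = 24, n_proteins = 450, mutation_enrichment = 5)
  sim <- simulate_all(cfg)
  fg <- sim$truth$substrate_sites
  bg <- arginine_positions(sim$proteome)
  res <- mutation_enrichment(fg, bg, sim$mutations, sim$proteome,
                             mode = "at_site")
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.01)
  expect_equal(sum(res$table), res$table[1, 1] + res$table[1, 2] +
                 res$table[2, 1] + res$table[2, 2])
})
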