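test_that("SILAC ratios handle absent and zero channels", {
  x <- compute_site_ratio(site_rows("P1", c(1, 2, 3, 4), c(1000, 800, 1000, 0),
                                    c(500, 800, NA, 100)))
  expect_equal(x$ratio_HL, c(0.5, 1, NA, NA))
  expect_equal(x$log2_ratio, c(-1, 0, NA, NA))
  expect_equal(x$light_only, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("site classification uses inclusive fold-change boundaries", {
  x <- classify_site(site_rows("P1", 1:6,
                               L = c(1000, 1000, 1000, 1000, 0, 1000),
                               H = c(500, 510, 2000, NA, 100, 1999)),
                     fold_change = 2)
  expect_equal(as.character(x$status),
               c("decreased", "unchanged", "increased", "abolished",
                 "not_quantified", "unchanged"))
  expect_error(classify_site(site_rows("P", 1, 1, 1), fold_change = 1),
               "fold_change")
})

test_that("protein normalization flags abundance-explained decreases only", {
  x <- classify_site(site_rows("A", 1, 1000, 400))
  x <- rbind(x, x, x)
  x$protein <- c("A", "B", "C")
  pr <- c(A = 0.4, B = 1.0)
  y <- normalize_to_protein(x, pr)
  expect_equal(y$normalized_ratio, c(1.0, 0.4, NA))
  expect_equal(y$protein_explained, c(TRUE, FALSE, FALSE))
  expect_warning(normalize_to_protein(x, c(A = 0, B = 1, C = 1)), "zero")
})

test_that("the calling cascade recovers a known substrate's site set", {
  pos <- c(194, 206, 218, 225, 232)
  sites <- site_rows("HNRNPA1", pos, L = 1000, H = 400)
  other <- site_rows("PLAIN", 51, L = 1000, H = 900)
  prot <- data.frame(protein = c("HNRNPA1", "PLAIN"),
                     intensity_L = c(1e5, 1e5), intensity_H = c(1e5, 1e5))
  m <- call_methylome(rbind(sites, other), prot, modalities = "MMA",
                      prmt_label = "PRMT7")
  expect_equal(m$proteins, "HNRNPA1")
  expect_setequal(m$sites$position, pos)
  expect_equal(m$tally$n_detected, 6)
  expect_equal(m$tally$n_decreased, 5)
})

test_that("duplicate site records are counted once", {
  sites <- site_rows("P1", c(10, 10, 20), L = 1000, H = 400)
  m <- call_methylome(sites, NULL, prmt_label = "X")
  expect_equal(m$tally$n_detected, 2)
})

test_that("all-unchanged input yields an empty methylome", {
  m <- call_methylome(site_rows("P1", 1:3, L = 1000, H = 1000), NULL)
  expect_length(m$proteins, 0)
  expect_equal(m$tally$n_regulated, 0)
})

test_that("a protein-explained decrease is excluded but tallied", {
  sites <- site_rows("P1", 10, L = 1000, H = 400)
  prot <- data.frame(protein = "P1", intensity_L = 1000, intensity_H = 400)
  m <- call_methylome(sites, prot)
  expect_length(m$proteins, 0)
  expect_equal(m$tally$n_protein_explained, 1)
  expect_equal(m$tally$n_decreased, 1)
})

test_that("cross-enzyme intersection partitions shared arginines", {
  m4 <- make_methylome("PRMT4", "HNRNPA1", c(206, 218, 225, 232))
  m5 <- make_methylome("PRMT5", "HNRNPA1", c(194, 196, 206, 218))
  m7 <- make_methylome("PRMT7", "HNRNPA1", c(194, 206, 218, 225, 232))
  out <- intersect_methylomes(list(m4, m5, m7), level = "position")
  expect_setequal(out$position[out$n_regulators == 3], c(206, 218))
  expect_setequal(out$position[out$n_regulators == 1], 196)
  # classes partition the union
  expect_equal(sum(out$n_regulators %in% 1:3), nrow(out))
  expect_setequal(out$position, c(194, 196, 206, 218, 225, 232))
})

test_that("degenerate intersections and duplicate labels are handled", {
  a <- make_methylome("A", c("P1", "P2"), c(1, 1))
  b <- make_methylome("B", c("P1", "P2"), c(1, 1))
  c_ <- make_methylome("C", c("P1", "P2"), c(1, 1))
  out <- intersect_methylomes(list(a, b, c_), level = "protein")
  expect_true(all(out$n_regulators == 3))

  d <- make_methylome("D", "P3", 1)
  e <- make_methylome("E", "P4", 1)
  out2 <- intersect_methylomes(list(d, e), level = "protein")
  expect_true(all(out2$n_regulators == 1))

  expect_error(intersect_methylomes(list(a, a)), "duplicate")
})

test_that("sites-per-protein distribution is a proper histogram", {
  m <- make_methylome("X", c("A", "B", "C", "C", "D", "D", "D", "D",
                             "D", "D", "D", "D"),
                      c(1, 1, 1, 2, 1:8))
  h <- sites_per_protein(m)
  expect_equal(h$fraction[h$n_sites == 1], 0.5)
  expect_equal(h$fraction[h$n_sites == 2], 0.25)
  expect_equal(h$fraction[h$n_sites == 8], 0.25)
  expect_equal(sum(h$fraction), 1)
})

test_that("cross-validation overlap fraction and p match the exact tail", {
  u <- sprintf("U%03d", 1:500)
  a <- u[1:20]
  b <- u[6:35]   # overlap 15
  res <- crossvalidate_calls(a, b, u)
  expect_equal(res$fraction, 15 / 20)
  expect_equal(res$p_value, oracle_hyper_tail(15, 500, 20, 30),
               tolerance = 1e-12)

  expect_equal(crossvalidate_calls(a, a, u)$fraction, 1)
  expect_equal(crossvalidate_calls(a, u[100:120], u)$fraction, 0)
  expect_error(crossvalidate_calls(a, b, u[1:10]), "universe")
})
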