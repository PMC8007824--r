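test_that("PSI follows the effective-length-weighted isoform ratio", {
  expect_equal(compute_psi(50, 50), 0.5)
  expect_equal(compute_psi(30, 10, inc_len = 2, skip_len = 1), 0.6)
  expect_true(is.na(compute_psi(0, 0, min_total = 0)))
  expect_true(is.na(compute_psi(4, 3, min_total = 10)))
  expect_error(compute_psi(-1, 5), "negative")

  # equal-length limit: plain inc / (inc + skip)
  set.seed(1)
  inc <- rpois(50, 40); skip <- rpois(50, 40)
  expect_equal(compute_psi(inc, skip, 3, 3, min_total = 0),
               inc / (inc + skip))

  # monotone non-decreasing in the inclusion count
  psis <- compute_psi(0:100, 50, 2, 1, min_total = 0)
  expect_true(all(diff(psis) >= 0, na.rm = TRUE))
  expect_true(all(psis >= 0 & psis <= 1, na.rm = TRUE))
})

test_that("delta-PSI calls use an inclusive threshold and kd-relative direction", {
  x <- call_delta_psi(c(0.9, 0.4, 1.0, 0.2), c(0.2, 0.6, 0.5, 0.9))
  expect_equal(x$delta_psi, c(0.7, -0.2, 0.5, -0.7))
  expect_equal(x$differential, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(as.character(x$direction), c("ES", "none", "ES", "EI"))

  # antisymmetry: swapping conditions negates delta and swaps EI and ES
  y <- call_delta_psi(c(0.2, 0.6, 0.5, 0.9), c(0.9, 0.4, 1.0, 0.2))
  expect_equal(y$delta_psi, -x$delta_psi)
  swapped <- c(EI = "ES", ES = "EI", none = "none")
  expect_equal(as.character(y$direction),
               unname(swapped[as.character(x$direction)]))
})

test_that("event summaries tally differential events by type and direction", {
  calls <- data.frame(
    event_id = sprintf("E%d", 1:6),
    event_type = c("SE", "SE", "SE", "IR", "SE", "MXE"),
    psi_ctl = 1, psi_kd = 1,
    delta_psi = c(0.8, 0.7, 0.9, -0.6, 0.1, NA),
    differential = c(TRUE, TRUE, TRUE, TRUE, FALSE, NA),
    direction = factor(c("ES", "ES", "ES", "EI", "none", NA),
                       levels = c("EI", "ES", "none")))
  s <- summarize_events(calls)
  expect_equal(s$ES[s$event_type == "SE"], 3)
  expect_equal(s$EI[s$event_type == "IR"], 1)
  expect_equal(attr(s, "n_differential"), 4)
  expect_equal(sum(s$EI) + sum(s$ES), 4)
})

test_that("concordance classifies shared events and spots contradictions", {
  mk <- function(dirs) {
    data.frame(event_id = sprintf("E%d", seq_along(dirs)),
               event_type = "SE", psi_ctl = NA, psi_kd = NA,
               delta_psi = NA,
               differential = dirs != "none",
               direction = factor(dirs, levels = c("EI", "ES", "none")))
  }
  calls <- list(A = mk(c("ES", "EI", "none")),
                B = mk(c("ES", "ES", "none")),
                C = mk(c("ES", "none", "EI")))
  conc <- concordance_analysis(calls)
  expect_equal(unname(conc$n_by_class), c(1, 1, 1))
  expect_equal(conc$n_concordant, 1)   # E1: ES,ES,ES
  expect_equal(conc$n_discordant, 1)   # E2: EI vs ES
  expect_equal(conc$n_contradictory, 1)
  expect_equal(conc$n_concordant + conc$n_discordant,
               sum(conc$events$n_regulators >= 2))

  bad <- list(A = mk(c("ES", "EI")), B = mk("ES"))
  expect_error(concordance_analysis(bad), "universes differ")
})

test_that("splice_calls ties each knockdown to the control universe", {
  cfg <- sim_config(seed = 31, n_proteins = 450, depth = 2000)
  sim <- simulate_all(cfg)
  calls <- splice_calls(sim$splice_counts)
  expect_named(calls, paste0("si", cfg$prmts))
  truth <- sim$truth$splice_events
  for (p in cfg$prmts) {
    cc <- calls[[paste0("si", p)]]
    reg <- truth$event_id[grepl(p, truth$regulators)]
    called <- cc$event_id[!is.na(cc$differential) & cc$differential]
    expect_gt(length(intersect(called, reg)) / length(reg), 0.97)
  }
  expect_error(splice_calls(sim$splice_counts, control = "nope"),
               "not in counts")
})

test_that("FPKM definition, strict filter and scale invariance hold", {
  expect_equal(fpkm(100, 1000, 1e6), 100)
  expect_equal(fpkm(2 * 100, 1000, 2 * 1e6), 100)
  expect_error(fpkm(1, 0, 1e6), "positive")

  m <- rbind(g1 = c(0.5, 0.5), g2 = c(0.5, 0.51), g3 = c(0, 0))
  expect_equal(unname(fpkm_keep(m)), c(FALSE, TRUE, FALSE))
})

test_that("central motif enrichment matches the exact binomial tail", {
  # all matches central: 100 planted motifs in the middle of 575-bp seqs
  set.seed(7)
  seqs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 575, TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1)), collapse = ""),
    character(1))
  mid <- 288
  substr(seqs, mid, mid + 5) <- "TAGGGA"
  res <- central_motif_enrichment(seqs, "TAGGGW", center_window = 50)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$p_value,
               oracle_binom_tail(res$n_central, res$n_matches, res$p0),
               tolerance = 1e-9)

  # no matches anywhere
  none <- central_motif_enrichment(c("AAAAAAAAAA", "CCCCCCCCCC"), "TAGGGW",
                                   center_window = 4)
  expect_equal(none$n_matches, 0L)
  expect_equal(none$p_value, 1)

  expect_error(central_motif_enrichment(character(0), "TAGGGW"), "empty")
  # U is accepted as T
  expect_equal(central_motif_enrichment("AAUAGGGAAA", "TAGGGW",
                                        center_window = 10)$n_matches, 1L)
})
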