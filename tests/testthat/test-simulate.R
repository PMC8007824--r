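test_that("generators are deterministic under a fixed master seed", {
  cfg <- sim_config(seed = 41, n_proteins = 450)
  a <- simulate_all(cfg)
  b <- simulate_all(cfg)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$methyl, b$methyl)
  expect_identical(a$phospho, b$phospho)
  expect_identical(a$splice_counts, b$splice_counts)
  expect_identical(a$event_seq, b$event_seq)
})

test_that("simulated files round-trip and record the seed", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 42, n_proteins = 450)
  sim <- simulate_all(cfg, outdir = dir)
  expect_identical(read_fasta(file.path(dir, "proteome.fa")), sim$proteome)
  sites <- read_table(file.path(dir, "sites_PRMT7.tsv"),
                      methylomap_schemas()$site_quant)
  expect_equal(sites, sim$methyl$PRMT7$sites, ignore_attr = TRUE)
  first <- readLines(file.path(dir, "sites_PRMT7.tsv"), n = 1)
  expect_match(first, "seed: 42")
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_proteins = 0))
  expect_error(sim_config(n_proteins = 100), "overlap design")
  expect_error(sim_config(effect_ratio = 1.2))
  expect_error(sim_config(motif_mix = c(GAR = 0.9, RXR = 0.2, other = 0.2)))
})

test_that("planted motif classes are recovered from the proteome", {
  cfg <- sim_config(seed = 43, n_proteins = 450)
  sim <- generate_proteome(cfg)
  truth <- sim$truth$substrate_sites
  expect_gt(nrow(truth), 500)
  wins <- extract_windows(sim$proteome, truth, k = 5)
  cls <- classify_motif(wins)
  # every planted class is classified back exactly
  expect_equal(as.character(cls), truth$motif_class)
  fr <- motif_fractions(cls)
  expect_lt(max(abs(fr - cfg$motif_mix[names(fr)])), 0.05)
})

test_that("noise-free tables are recovered exactly by the calling cascade", {
  cfg <- sim_config(seed = 44, n_proteins = 450, noise_sd = 0,
                    confound_fraction = 0)
  sim <- simulate_all(cfg)
  mods <- modality_map(cfg)
  for (p in cfg$prmts) {
    m <- call_methylome(sim$methyl[[p]]$sites, sim$methyl[[p]]$proteins,
                        mods[[p]], prmt_label = p)
    called <- unique(paste(m$sites$protein, m$sites$position))
    planted <- unique(paste(sim$truth$regulated_sites[[p]]$protein,
                            sim$truth$regulated_sites[[p]]$position))
    expect_setequal(called, planted)
  }
})

test_that("the protein-abundance confound is planted at the stated rate", {
  cfg <- sim_config(seed = 45, n_proteins = 450, confound_fraction = 0.1)
  sim <- simulate_all(cfg)
  mods <- modality_map(cfg)
  m <- call_methylome(sim$methyl$PRMT7$sites, sim$methyl$PRMT7$proteins,
                      mods$PRMT7, prmt_label = "PRMT7")
  n_reg <- nrow(sim$truth$regulated_sites$PRMT7)
  planted_conf <- nrow(sim$truth$confounded_sites$PRMT7)
  expect_equal(planted_conf, round(0.1 * n_reg))
  # flagged sites are (up to noise in which confounds stay callable)
  # the planted confounds
  expect_gt(m$tally$n_protein_explained, 0.5 * planted_conf)
  flagged <- m$calls[m$calls$protein_explained, c("protein", "position")]
  conf_keys <- paste(sim$truth$confounded_sites$PRMT7$protein,
                     sim$truth$confounded_sites$PRMT7$position)
  expect_gt(mean(paste(flagged$protein, flagged$position) %in% conf_keys),
            0.95)
})

test_that("deep sequencing recovers the planted PSI almost exactly", {
  cfg <- sim_config(seed = 46, n_proteins = 450, depth = 1e6)
  sim <- generate_splice_tables(cfg, list())
  counts <- sim$splice_counts
  truth <- sim$truth$splice_events
  ctl <- counts[counts$condition == "siCTL", ]
  psi <- compute_psi(ctl$inc_count, ctl$skip_count, ctl$inc_len,
                     ctl$skip_len)
  expect_true(all(abs(psi - truth$psi_ctl[match(ctl$event_id,
                                                truth$event_id)]) < 0.005))
})
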