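#' Modality filters for the three enzyme classes
#'
#' Maps each configured enzyme label to the methyl modalities profiled for
#' it: the first label is treated as a type I enzyme (MMA + aDMA), the
#' second as type II (MMA + sDMA), the third as type III (MMA only) —
#' matching the antibody panels used per enzyme class.
#'
#' @param cfg A [sim_config()].
#' @return Named list of modality character vectors.
#' @export
modality_map <- function(cfg) {
  m <- list(c("MMA", "aDMA"), c("MMA", "sDMA"), "MMA")
  names(m) <- cfg$prmts
  m
}

.score_sites <- function(called, planted) {
  ck <- paste(called$protein, called$position)
  pk <- paste(planted$protein, planted$position)
  tp <- sum(unique(ck) %in% pk)
  list(precision = if (length(unique(ck))) tp / length(unique(ck))
                   else NA_real_,
       recall = tp / length(unique(pk)),
       n_called = length(unique(ck)), n_planted = length(unique(pk)))
}

#' Run the full simulate-to-report pipeline
#'
#' Generates all inputs from `cfg`, runs every analysis stage in dependency
#' order, and returns a machine-readable run report joining the stage
#' outputs: substrate-calling cascade tallies plus precision/recall against
#' the planted truth, cross-enzyme substrate overlap, motif fractions and
#' flagged positional enrichments, phospho proximity with its resampled
#' null, mutation enrichment at and around methyl sites, differential
#' splicing counts with cross-enzyme concordance, central motif enrichment
#' in shared events' upstream sequences, and an ORA of the called
#' substrates against the planted sets. Deterministic for a fixed
#' `cfg$seed`; the report carries no timestamps so reruns are byte-stable.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, the simulated inputs, the
#'   per-stage tables and `report.json` are written there.
#' @param delta_psi Differential-splicing threshold.
#' @param min_total PSI coverage filter.
#' @param n_enrichment_samples Background sets for [positional_enrichment()].
#' @param n_resamples Resamples for [phospho_background()].
#' @return The run report (list); also written as JSON when `outdir` is
#'   given.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir = NULL, delta_psi = 0.5,
                         min_total = 10, n_enrichment_samples = 100,
                         n_resamples = 499) {
  sim <- simulate_all(cfg, outdir = if (!is.null(outdir))
    file.path(outdir, "sim") else NULL)
  mods <- modality_map(cfg)

  methylomes <- lapply(cfg$prmts, function(prmt) {
    call_methylome(sim$methyl[[prmt]]$sites, sim$methyl[[prmt]]$proteins,
                   modalities = mods[[prmt]], fold_change = cfg$fold_change,
                   prmt_label = prmt)
  })
  names(methylomes) <- cfg$prmts
  scores <- lapply(cfg$prmts, function(prmt) {
    .score_sites(methylomes[[prmt]]$sites,
                 sim$truth$regulated_sites[[prmt]])
  })
  names(scores) <- cfg$prmts

  inter_prot <- intersect_methylomes(methylomes, level = "protein")
  inter_pos <- intersect_methylomes(methylomes, level = "position")

  # sequence context of the type III (MMA-only) methylome
  mma_prmt <- cfg$prmts[3]
  m3 <- methylomes[[mma_prmt]]
  windows <- extract_windows(sim$proteome, m3$sites, k = 5)
  motif_fr <- motif_fractions(windows)
  enr <- positional_enrichment(windows, sim$proteome,
                               n_samples = n_enrichment_samples,
                               seed = cfg$seed + 7)

  prox <- phospho_proximity(m3$sites, sim$phospho, w = cfg$phospho_window)
  prox_null <- phospho_background(sim$proteome, sim$phospho,
                                  n_fg = nrow(m3$sites),
                                  observed_ge1 = prox$frac_ge1,
                                  w = cfg$phospho_window,
                                  n_resamples = n_resamples,
                                  seed = cfg$seed + 8,
                                  exclude = m3$sites)

  all_arg <- arginine_positions(sim$proteome)
  mut_at <- mutation_enrichment(m3$sites, all_arg, sim$mutations,
                                sim$proteome, mode = "at_site")
  mut_vic <- mutation_enrichment(m3$sites, all_arg, sim$mutations,
                                 sim$proteome, w = cfg$mutation_window,
                                 mode = "vicinity")

  calls <- splice_calls(sim$splice_counts, control = "siCTL",
                        threshold = delta_psi, min_total = min_total)
  splice_sum <- lapply(calls, summarize_events)
  conc <- concordance_analysis(calls)

  shared_ids <- conc$events$event_id[conc$events$n_regulators == 3]
  rna <- if (length(shared_ids)) {
    seqs <- sim$event_seq$upstream_sequence[
      match(shared_ids, sim$event_seq$event_id)]
    central_motif_enrichment(seqs, cfg$rna_motif, center_window = 100)
  } else list(n_matches = 0L, n_central = 0L, p0 = NA_real_, p_value = 1)

  # ORA of the called MMA-only methylome against the planted substrate
  # sets plus seeded decoy sets
  universe <- names(sim$proteome)
  planted_sets <- lapply(cfg$prmts, function(prmt)
    unique(sim$truth$regulated_sites[[prmt]]$protein))
  names(planted_sets) <- paste0(cfg$prmts, "_planted")
  set.seed(cfg$seed + 9)
  decoys <- lapply(1:5, function(i) sample(universe, 100))
  names(decoys) <- paste0("decoy_", 1:5)
  ora_res <- ora(m3$proteins, c(planted_sets, decoys), universe)

  report <- list(
    tool = "methylomap",
    version = as.character(utils::packageVersion("methylomap")),
    config = unclass(cfg),
    thresholds = list(fold_change = cfg$fold_change, delta_psi = delta_psi,
                      min_total = min_total,
                      phospho_window = cfg$phospho_window,
                      mutation_window = cfg$mutation_window),
    calling = list(tallies = lapply(methylomes, `[[`, "tally"),
                   scores = scores),
    intersection = list(
      protein_by_class = as.list(table(inter_prot$n_regulators)),
      position_by_class = as.list(table(inter_pos$n_regulators))),
    motif = list(fractions = as.list(motif_fr),
                 n_flagged = sum(enr$flagged),
                 top_flagged = utils::head(
                   enr[order(-abs(enr$z)),
                       c("offset", "residue", "z", "pct_diff")], 10)),
    phospho = list(bins = as.list(prox$bins), frac_ge1 = prox$frac_ge1,
                   bg_ge1_mean = mean(prox_null$bg_ge1),
                   p_value = prox_null$p_value),
    mutation = list(
      at_site = mut_at[c("rate_fg", "rate_bg", "odds_ratio", "p_value")],
      vicinity = mut_vic[c("rate_fg", "rate_bg", "odds_ratio", "p_value")]),
    splicing = list(
      n_differential = lapply(splice_sum, attr, "n_differential"),
      by_type = splice_sum,
      by_class = as.list(conc$n_by_class),
      concordance_fraction = conc$concordance_fraction,
      n_contradictory = conc$n_contradictory),
    rna_motif = rna,
    ora_top = utils::head(ora_res, 5)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (prmt in cfg$prmts) {
      cols <- c("protein", "position", "methyl_type", "ratio_HL",
                "normalized_ratio", "status", "protein_explained")
      tab <- methylomes[[prmt]]$calls[, cols]
      tab$status <- as.character(tab$status)
      write_table(tab, file.path(outdir, paste0("methylome_", prmt, ".tsv")),
                  comments = paste("seed:", cfg$seed))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns",
                         pretty = TRUE, na = "null")
  }
  report
}
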