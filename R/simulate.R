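# Background amino-acid frequencies used by the proteome generator.
# Fixed, documented constants approximating the composition of a vertebrate
# proteome; normalised to sum to 1 at load time.
.aa_background <- local({
  f <- c(A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.048,
         E = 0.071, G = 0.066, H = 0.026, I = 0.044, L = 0.100, K = 0.058,
         M = 0.021, F = 0.037, P = 0.063, S = 0.083, T = 0.054, W = 0.011,
         Y = 0.027, V = 0.060)
  f / sum(f)
})

#' Configuration for the synthetic multi-omics generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate the
#' downstream table structure of a three-enzyme knockdown study: three
#' PRMTs with 200 substrate proteins each sharing a designed by-1/by-2/by-3
#' overlap, a GAR-dominated motif mix, a strong knockdown effect with
#' log-normal measurement noise and a fraction of fully abolished sites, a
#' protein-abundance confound, clustered phosphosites and mutation
#' hotspots, and shared differential splicing events with one latent
#' direction per event. The master seed feeds one derived stream per
#' generated table (fixed offsets), so regenerating one table never
#' perturbs another.
#'
#' @param seed Master seed (integer).
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param protein_length_mean,protein_length_shape,protein_length_min Gamma
#'   length model for protein lengths (residues).
#' @param n_shared3 Substrate proteins regulated by all three enzymes.
#' @param n_shared2 Substrate proteins per enzyme pair (3 pairs).
#' @param n_substrates Substrate proteins per enzyme; uniques are
#'   `n_substrates - n_shared3 - 2 n_shared2`.
#' @param sites_per_protein_probs Probabilities for 1..4 planted sites per
#'   substrate protein.
#' @param motif_mix Named fractions (`GAR`, `RXR`, `other`) of planted site
#'   contexts.
#' @param effect_ratio True heavy/light ratio of regulated sites.
#' @param abolished_fraction Fraction of regulated sites with no heavy
#'   signal at all.
#' @param noise_sd Measurement noise: sd of the log2 ratio.
#' @param confound_fraction Sites that decrease only because their protein
#'   does, as a fraction of the regulated-site count.
#' @param n_background_sites Unregulated arginine sites per site table.
#' @param fold_change Fold-change threshold the calling stage will use
#'   (echoed into reports).
#' @param n_phospho,phospho_enrichment,phospho_window Phosphosite table:
#'   total sites, density multiplier within `phospho_window` of planted
#'   methyl sites.
#' @param n_mutations,mutation_enrichment,mutation_window Somatic-mutation
#'   table: total mutated positions, density multiplier at/near planted
#'   sites.
#' @param n_events_null,n_events_unique,n_events_shared2,n_events_shared3
#'   Splice-event design: unregulated events, events unique to each enzyme,
#'   events per enzyme pair, events shared by all three.
#' @param true_delta_psi Planted |delta PSI| for regulated events.
#' @param psi_low Control PSI of a regulated exon-inclusion event
#'   (`psi_low + true_delta_psi` is the high state).
#' @param depth Junction reads per event per condition.
#' @param inc_len,skip_len Effective lengths of the inclusion/skipping
#'   isoforms.
#' @param seq_len Length (bp) of the upstream sequences in the event
#'   sequence table.
#' @param rna_motif IUPAC motif planted centrally in regulated events'
#'   upstream sequences.
#' @param prmts Labels of the three perturbed enzymes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_proteins = 600,
                       protein_length_mean = 400,
                       protein_length_shape = 4,
                       protein_length_min = 80,
                       n_substrates = 200,
                       n_shared3 = 60,
                       n_shared2 = 30,
                       sites_per_protein_probs = c(0.63, 0.20, 0.12, 0.05),
                       motif_mix = c(GAR = 0.6, RXR = 0.2, other = 0.2),
                       effect_ratio = 0.2,
                       abolished_fraction = 0.5,
                       noise_sd = 0.3,
                       confound_fraction = 0.1,
                       n_background_sites = 600,
                       fold_change = 2,
                       n_phospho = 4000,
                       phospho_enrichment = 5,
                       phospho_window = 3,
                       n_mutations = 3000,
                       mutation_enrichment = 5,
                       mutation_window = 5,
                       n_events_null = 200,
                       n_events_unique = 60,
                       n_events_shared2 = 20,
                       n_events_shared3 = 40,
                       true_delta_psi = 0.7,
                       psi_low = 0.15,
                       depth = 1000,
                       inc_len = 2,
                       skip_len = 1,
                       seq_len = 575,
                       rna_motif = "TAGGGW",
                       prmts = c("PRMT4", "PRMT5", "PRMT7")) {
  cfg <- as.list(environment())
  stopifnot(n_proteins > 0,
            effect_ratio > 0, effect_ratio < 1,
            abolished_fraction >= 0, abolished_fraction <= 1,
            confound_fraction >= 0, confound_fraction <= 1,
            noise_sd >= 0, fold_change > 1,
            true_delta_psi > 0, true_delta_psi <= 1,
            psi_low + true_delta_psi <= 1,
            length(prmts) == 3, !anyDuplicated(prmts),
            abs(sum(motif_mix) - 1) < 1e-8,
            abs(sum(sites_per_protein_probs) - 1) < 1e-8)
  n_unique <- n_substrates - n_shared3 - 2 * n_shared2
  stopifnot(n_unique >= 0)
  need <- n_shared3 + 3 * n_shared2 + 3 * n_unique
  if (need + 50 > n_proteins) {
    stop("n_proteins too small for the substrate overlap design (needs > ",
         need + 50, ")")
  }
  cfg$n_unique <- n_unique
  structure(cfg, class = "sim_config")
}

# stream offsets for the per-table seeds (documented key scheme)
.seed_offsets <- c(proteome = 101L, methyl = 210L, context = 301L,
                   splice = 401L)

#' Generate a synthetic proteome with planted methyl-site contexts
#'
#' Draws random protein sequences from the fixed background amino-acid
#' frequency table, assigns substrate proteins to the by-1/by-2/by-3
#' regulator design, and plants one to four arginine methyl sites per
#' substrate protein with the configured GAR/RXR/other context mix (GAR
#' sites get the G-R-G-G context found inside RGG repeats; RXR sites an
#' arginine two residues downstream with non-glycine neighbours; `other`
#' sites a context matching neither pattern). Sites are spaced so planted
#' contexts never overlap.
#'
#' @param cfg A [sim_config()].
#' @return List with `proteome` (named character vector) and `truth`
#'   (list: `substrate_sites` data frame with `protein`, `position`,
#'   `motif_class`, `regulators`; `design` data frame with `protein`,
#'   `regulators`).
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + .seed_offsets[["proteome"]])
  n <- cfg$n_proteins
  lens <- pmax(cfg$protein_length_min,
               round(stats::rgamma(n, shape = cfg$protein_length_shape,
                                   scale = cfg$protein_length_mean /
                                     cfg$protein_length_shape)))
  ids <- sprintf("P%04d", seq_len(n))
  chars <- sample(names(.aa_background), sum(lens), replace = TRUE,
                  prob = .aa_background)
  ends <- cumsum(lens)
  starts <- c(1, utils::head(ends, -1) + 1)
  seqs <- vapply(seq_len(n), function(i)
    paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
  names(seqs) <- ids

  p <- cfg$prmts
  pairs <- list(c(p[1], p[2]), c(p[1], p[3]), c(p[2], p[3]))
  reg_sets <- c(list(p), pairs, list(p[1], p[2], p[3]))
  reg_counts <- c(cfg$n_shared3, rep(cfg$n_shared2, 3),
                  rep(cfg$n_unique, 3))
  regulators <- rep(vapply(reg_sets, paste, character(1), collapse = ","),
                    reg_counts)
  design <- data.frame(protein = ids[seq_along(regulators)],
                       regulators = regulators)

  non_g <- setdiff(.aa20, "G")
  non_gr <- setdiff(.aa20, c("G", "R"))
  site_rows <- list()
  for (i in seq_len(nrow(design))) {
    id <- design$protein[i]
    len <- lens[i]
    grid <- seq(8, len - 8, by = 13)  # spacing keeps planted windows apart
    n_sites <- sample(seq_along(cfg$sites_per_protein_probs), 1,
                      prob = cfg$sites_per_protein_probs)
    n_sites <- min(n_sites, length(grid))
    pos <- sort(sample(grid, n_sites))
    cls <- sample(names(cfg$motif_mix), n_sites, replace = TRUE,
                  prob = cfg$motif_mix)
    s <- strsplit(seqs[[id]], "")[[1]]
    for (j in seq_len(n_sites)) {
      pj <- pos[j]
      s[pj] <- "R"
      if (cls[j] == "GAR") {            # G R G G, as inside RGG repeats
        s[pj - 1] <- "G"
        s[pj + 1] <- "G"
        s[pj + 2] <- "G"
      } else if (cls[j] == "RXR") {     # R x R with non-G neighbours
        s[pj - 1] <- sample(non_gr, 1)
        s[pj + 1] <- sample(non_gr, 1)
        s[pj + 2] <- "R"
      } else {                          # neither G adjacent nor R at +/-2
        s[pj - 2] <- sample(non_gr, 1)
        s[pj - 1] <- sample(non_gr, 1)
        s[pj + 1] <- sample(non_gr, 1)
        s[pj + 2] <- sample(non_g, 1)
        if (s[pj + 2] == "R") s[pj + 2] <- "A"
      }
      site_rows[[length(site_rows) + 1]] <-
        data.frame(protein = id, position = pj, motif_class = cls[j],
                   regulators = design$regulators[i])
    }
    seqs[[id]] <- paste(s, collapse = "")
  }
  truth_sites <- do.call(rbind, site_rows)
  list(proteome = seqs,
       truth = list(substrate_sites = truth_sites, design = design))
}

.has_regulator <- function(regulators, prmt) {
  vapply(strsplit(regulators, ",", fixed = TRUE),
         function(r) prmt %in% r, logical(1))
}

#' Generate SILAC site and protein quantification tables
#'
#' Emits one `site_quant` and one `protein_quant` table per perturbation.
#' Sites regulated by the perturbed enzyme receive the configured effect
#' ratio times log-normal noise, with a fraction losing the heavy channel
#' entirely (abolished); planted sites regulated only by the other enzymes
#' and randomly sampled background arginines get ratios around 1. A
#' configured fraction of additional sites on non-substrate proteins
#' decreases together with its protein (the protein-abundance confound the
#' normalization step must catch).
#'
#' @param cfg A [sim_config()].
#' @param proteome Named character vector from [generate_proteome()].
#' @param truth Truth list from [generate_proteome()] (extended in place).
#' @return List with `tables` (per enzyme: `sites`, `proteins` data
#'   frames) and `truth` (extended with `regulated_sites` and
#'   `confounded_sites` per enzyme).
#' @export
generate_methyl_tables <- function(cfg, proteome, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  all_r <- arginine_positions(proteome)
  planted_key <- paste(truth$substrate_sites$protein,
                       truth$substrate_sites$position)
  free_r <- all_r[!(paste(all_r$protein, all_r$position) %in% planted_key) &
                    !(all_r$protein %in% truth$design$protein), ]
  modality <- list()
  modality[[cfg$prmts[1]]] <- c("MMA", "aDMA")
  modality[[cfg$prmts[2]]] <- c("MMA", "sDMA")
  modality[[cfg$prmts[3]]] <- "MMA"

  tables <- list()
  truth$regulated_sites <- list()
  truth$confounded_sites <- list()
  for (i in seq_along(cfg$prmts)) {
    prmt <- cfg$prmts[i]
    set.seed(cfg$seed + .seed_offsets[["methyl"]] + i)
    reg <- .has_regulator(truth$substrate_sites$regulators, prmt)
    planted <- truth$substrate_sites[, c("protein", "position")]
    n_planted <- nrow(planted)

    n_conf <- round(cfg$confound_fraction * sum(reg))
    conf_idx <- if (n_conf > 0) sample.int(nrow(free_r), n_conf)
                else integer(0)
    conf <- free_r[conf_idx, , drop = FALSE]
    pool <- free_r[setdiff(seq_len(nrow(free_r)), conf_idx), , drop = FALSE]
    bg <- pool[sample.int(nrow(pool), cfg$n_background_sites), , drop = FALSE]

    sites <- rbind(planted, conf[, c("protein", "position")],
                   bg[, c("protein", "position")])
    n <- nrow(sites)
    is_reg <- c(reg, rep(FALSE, nrow(conf) + nrow(bg)))
    is_conf <- c(rep(FALSE, n_planted), rep(TRUE, nrow(conf)),
                 rep(FALSE, nrow(bg)))
    mods <- modality[[prmt]]
    sites$methyl_type <- sample(mods, n, replace = TRUE,
                                prob = if (length(mods) == 2) c(0.7, 0.3)
                                       else 1)
    L <- round(10^stats::runif(n, 4.5, 7))
    ratio <- 2^stats::rnorm(n, 0, cfg$noise_sd)
    ratio[is_reg | is_conf] <- cfg$effect_ratio *
      2^stats::rnorm(sum(is_reg | is_conf), 0, cfg$noise_sd)
    H <- pmax(1, round(L * ratio))
    abolished <- is_reg &
      stats::runif(n) < cfg$abolished_fraction
    H[abolished] <- NA_real_
    sites$intensity_L <- L
    sites$intensity_H <- H

    prot <- data.frame(protein = names(proteome))
    pL <- round(10^stats::runif(length(proteome), 5, 7.5))
    pratio <- 2^stats::rnorm(length(proteome), 0, cfg$noise_sd)
    confp <- prot$protein %in% conf$protein
    pratio[confp] <- cfg$effect_ratio *
      2^stats::rnorm(sum(confp), 0, cfg$noise_sd)
    prot$intensity_L <- pL
    prot$intensity_H <- round(pL * pratio)

    tables[[prmt]] <- list(sites = sites, proteins = prot)
    truth$regulated_sites[[prmt]] <-
      truth$substrate_sites[reg, c("protein", "position")]
    truth$confounded_sites[[prmt]] <- conf[, c("protein", "position")]
  }
  list(tables = tables, truth = truth)
}

#' Generate phosphosite and somatic-mutation tables
#'
#' Phosphosites are sampled (without replacement) from the proteome's
#' serine/threonine/tyrosine positions, with positions within the
#' configured window of a planted methyl site upweighted by the enrichment
#' factor (factor 1 = uniform, the calibration null). Mutated positions are
#' sampled from all residue positions with the same weighting scheme around
#' planted sites.
#'
#' @param cfg A [sim_config()].
#' @param proteome Named character vector.
#' @param truth Truth list containing `substrate_sites`.
#' @return List with `phospho` and `mutations` data frames.
#' @export
generate_context_tables <- function(cfg, proteome, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + .seed_offsets[["context"]])
  sites_by_pro <- split(truth$substrate_sites$position,
                        truth$substrate_sites$protein)
  near_site <- function(id, pos, w) {
    sp <- sites_by_pro[[id]]
    if (is.null(sp)) return(rep(FALSE, length(pos)))
    vapply(pos, function(x) any(abs(sp - x) <= w), logical(1))
  }

  sty <- do.call(rbind, lapply(names(proteome), function(id) {
    pos <- gregexpr("[STY]", proteome[[id]])[[1]]
    if (pos[1] == -1L) return(NULL)
    data.frame(protein = id, position = as.integer(pos))
  }))
  wts <- rep(1, nrow(sty))
  for (id in names(sites_by_pro)) {
    sel <- which(sty$protein == id)
    if (!length(sel)) next
    hot <- near_site(id, sty$position[sel], cfg$phospho_window)
    wts[sel][hot] <- cfg$phospho_enrichment
  }
  pick <- sample.int(nrow(sty), min(cfg$n_phospho, nrow(sty)), prob = wts)
  phospho <- sty[sort(pick), , drop = FALSE]
  rownames(phospho) <- NULL

  lens <- nchar(proteome)
  allpos <- data.frame(protein = rep(names(proteome), lens),
                       position = unlist(lapply(lens, seq_len),
                                         use.names = FALSE))
  mwts <- rep(1, nrow(allpos))
  for (id in names(sites_by_pro)) {
    sel <- which(allpos$protein == id)
    hot <- near_site(id, allpos$position[sel], cfg$mutation_window)
    mwts[sel][hot] <- cfg$mutation_enrichment
  }
  mpick <- sample.int(nrow(allpos), min(cfg$n_mutations, nrow(allpos)),
                      prob = mwts)
  mutations <- allpos[sort(mpick), , drop = FALSE]
  mutations$count <- 1L
  rownames(mutations) <- NULL

  list(phospho = phospho, mutations = mutations)
}

#' Generate splice-event junction counts and upstream sequences
#'
#' Builds the event universe from the configured regulator design (null
#' events, events unique to each enzyme, per-pair events, events shared by
#' all three), assigns each regulated event one latent direction shared by
#' all its regulators, and draws junction counts binomially from the true
#' condition-specific PSI at the configured depth, with effective-length
#' weighting of the inclusion isoform. Upstream sequences are uniform
#' random nucleotides; regulated events get one motif instance written at
#' a central position.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list (extended with `splice_events`).
#' @return List with `splice_counts` (long data frame over conditions,
#'   control first), `event_seq` data frame and `truth`.
#' @export
generate_splice_tables <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + .seed_offsets[["splice"]])
  p <- cfg$prmts
  reg_sets <- c(list(character(0)), as.list(p),
                list(c(p[1], p[2]), c(p[1], p[3]), c(p[2], p[3])), list(p))
  reg_counts <- c(cfg$n_events_null, rep(cfg$n_events_unique, 3),
                  rep(cfg$n_events_shared2, 3), cfg$n_events_shared3)
  regulators <- rep(vapply(reg_sets, paste, character(1), collapse = ","),
                    reg_counts)
  n <- length(regulators)
  events <- data.frame(
    event_id = sprintf("E%04d", seq_len(n)),
    event_type = rep_len(.event_types, n),
    regulators = regulators
  )
  is_reg <- events$regulators != ""
  events$direction <- ifelse(is_reg, sample(c("EI", "ES"), n, replace = TRUE),
                             "none")
  psi_hi <- cfg$psi_low + cfg$true_delta_psi
  events$psi_ctl <- ifelse(!is_reg, stats::runif(n, 0.2, 0.8),
                           ifelse(events$direction == "EI", cfg$psi_low,
                                  psi_hi))

  conditions <- c("siCTL", paste0("si", p))
  rows <- list()
  for (cond in conditions) {
    psi <- events$psi_ctl
    if (cond != "siCTL") {
      prmt <- sub("^si", "", cond)
      hit <- .has_regulator(events$regulators, prmt)
      psi[hit] <- ifelse(events$direction[hit] == "EI",
                         events$psi_ctl[hit] + cfg$true_delta_psi,
                         events$psi_ctl[hit] - cfg$true_delta_psi)
    }
    theta <- psi * cfg$inc_len / (psi * cfg$inc_len +
                                    (1 - psi) * cfg$skip_len)
    inc <- stats::rbinom(n, cfg$depth, theta)
    rows[[cond]] <- data.frame(
      event_id = events$event_id, event_type = events$event_type,
      condition = cond, inc_count = inc, skip_count = cfg$depth - inc,
      inc_len = cfg$inc_len, skip_len = cfg$skip_len)
  }
  splice_counts <- do.call(rbind, rows)
  rownames(splice_counts) <- NULL

  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, cfg$seq_len, replace = TRUE), collapse = ""),
    character(1))
  motif_inst <- function() {
    m <- strsplit(cfg$rna_motif, "")[[1]]
    m[m == "W"] <- sample(c("A", "T"), sum(m == "W"), replace = TRUE)
    paste(m, collapse = "")
  }
  for (i in which(is_reg)) {
    start <- round(cfg$seq_len / 2) +
      sample(-10:10, 1) - floor(nchar(cfg$rna_motif) / 2)
    inst <- motif_inst()
    substr(seqs[i], start, start + nchar(inst) - 1) <- inst
  }
  event_seq <- data.frame(event_id = events$event_id,
                          upstream_sequence = seqs)
  truth$splice_events <- events
  list(splice_counts = splice_counts, event_seq = event_seq, truth = truth)
}

#' Generate every pipeline input with recorded ground truth
#'
#' Runs the four generators in order and optionally writes all inputs to
#' disk (FASTA, tab-delimited tables with the master seed recorded in a
#' header comment, and `truth.json`).
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional output directory (created if needed).
#' @return List with `config`, `proteome`, `truth`, `methyl` (per-enzyme
#'   `sites`/`proteins` tables), `phospho`, `mutations`, `splice_counts`,
#'   `event_seq`.
#' @export
simulate_all <- function(cfg = sim_config(), outdir = NULL) {
  gp <- generate_proteome(cfg)
  gm <- generate_methyl_tables(cfg, gp$proteome, gp$truth)
  gc_ <- generate_context_tables(cfg, gp$proteome, gm$truth)
  gs <- generate_splice_tables(cfg, gm$truth)
  sim <- list(config = cfg, proteome = gp$proteome, truth = gs$truth,
              methyl = gm$tables, phospho = gc_$phospho,
              mutations = gc_$mutations, splice_counts = gs$splice_counts,
              event_seq = gs$event_seq)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste("seed:", cfg$seed)
    write_fasta(sim$proteome, file.path(outdir, "proteome.fa"))
    for (prmt in names(sim$methyl)) {
      write_table(sim$methyl[[prmt]]$sites,
                  file.path(outdir, paste0("sites_", prmt, ".tsv")), hdr)
      write_table(sim$methyl[[prmt]]$proteins,
                  file.path(outdir, paste0("proteins_", prmt, ".tsv")), hdr)
    }
    write_table(sim$phospho, file.path(outdir, "phospho.tsv"), hdr)
    write_table(sim$mutations, file.path(outdir, "mutations.tsv"), hdr)
    write_table(sim$splice_counts,
                file.path(outdir, "splice_counts.tsv"), hdr)
    write_table(sim$event_seq, file.path(outdir, "event_seq.tsv"), hdr)
    jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
  }
  sim
}
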