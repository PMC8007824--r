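#' Percent spliced in (PSI) from junction counts
#'
#' PSI is the fraction of transcripts that include the alternative element:
#' the inclusion isoform's count divided by the sum of both isoforms'
#' counts, after normalising each count by its effective length (more
#' junction positions yield more reads per transcript). With equal
#' effective lengths this reduces to `inc / (inc + skip)`, the plain
#' long-isoform-over-both definition. Events with total coverage below
#' `min_total` (or with both counts zero) are not testable and get `NA`.
#'
#' @param inc_count,skip_count Non-negative inclusion/skipping junction
#'   counts (vectorised).
#' @param inc_len,skip_len Positive effective lengths.
#' @param min_total Minimum `inc_count + skip_count` to report a PSI.
#' @return Numeric vector of PSI values in `[0, 1]`, `NA` where not
#'   testable.
#' @export
compute_psi <- function(inc_count, skip_count, inc_len = 1, skip_len = 1,
                        min_total = 10) {
  if (any(inc_count < 0, na.rm = TRUE) || any(skip_count < 0, na.rm = TRUE)) {
    stop("negative junction counts")
  }
  stopifnot(all(inc_len > 0), all(skip_len > 0))
  ni <- inc_count / inc_len
  ns <- skip_count / skip_len
  psi <- ni / (ni + ns)
  low <- (inc_count + skip_count) < min_total | (inc_count + skip_count) == 0
  psi[low] <- NA_real_
  psi
}

#' Call differential splicing between control and knockdown
#'
#' `delta_psi = psi_ctl - psi_kd`; an event is differential when
#' `|delta_psi|` reaches the threshold (inclusive boundary). Direction
#' describes the change induced by the knockdown: `EI` (exon inclusion)
#' when PSI rises upon knockdown, `ES` (exon skipping) when it falls,
#' `none` for non-differential events. Events with either PSI absent get an
#' `NA` call and are excluded from tallies.
#'
#' @param psi_ctl,psi_kd PSI in control and knockdown (vectorised).
#' @param threshold Absolute delta-PSI threshold, default 0.5.
#' @return Data frame with `psi_ctl`, `psi_kd`, `delta_psi`, `differential`,
#'   `direction` (factor `EI`/`ES`/`none`).
#' @export
call_delta_psi <- function(psi_ctl, psi_kd, threshold = 0.5) {
  delta <- psi_ctl - psi_kd
  differential <- abs(delta) >= threshold
  direction <- ifelse(!differential, "none",
                      ifelse(psi_kd > psi_ctl, "EI", "ES"))
  data.frame(psi_ctl = psi_ctl, psi_kd = psi_kd, delta_psi = delta,
             differential = differential,
             direction = factor(direction, levels = c("EI", "ES", "none")))
}

#' Differential-splicing calls for every knockdown in a counts table
#'
#' Takes the long-format junction-count table (one row per event per
#' condition), computes PSI per event and condition, and calls each
#' knockdown against the control.
#'
#' @param counts `splice_counts` data frame: `event_id`, `event_type`,
#'   `condition`, `inc_count`, `skip_count`, `inc_len`, `skip_len`.
#' @param control Name of the control condition.
#' @param threshold Absolute delta-PSI threshold.
#' @param min_total Coverage filter passed to [compute_psi()].
#' @return Named list (one per knockdown condition) of data frames with
#'   `event_id`, `event_type` and the [call_delta_psi()] columns.
#' @export
splice_calls <- function(counts, control = "siCTL", threshold = 0.5,
                         min_total = 10) {
  conds <- unique(counts$condition)
  if (!control %in% conds) stop("control condition '", control,
                                "' not in counts table")
  counts$psi <- compute_psi(counts$inc_count, counts$skip_count,
                            counts$inc_len, counts$skip_len, min_total)
  ctl <- counts[counts$condition == control, ]
  ctl <- ctl[order(ctl$event_id), ]
  out <- list()
  for (cond in setdiff(conds, control)) {
    kd <- counts[counts$condition == cond, ]
    kd <- kd[order(kd$event_id), ]
    if (!identical(ctl$event_id, kd$event_id)) {
      stop("event universe of '", cond, "' differs from control")
    }
    calls <- call_delta_psi(ctl$psi, kd$psi, threshold)
    out[[cond]] <- cbind(data.frame(event_id = ctl$event_id,
                                    event_type = ctl$event_type),
                         calls)
  }
  out
}

#' Tally differential events by type and direction
#'
#' @param calls Data frame from one element of [splice_calls()].
#' @return Data frame `event_type` x `direction` counts for differential
#'   events, plus a `total` row attribute via `attr(,"n_differential")`.
#' @export
summarize_events <- function(calls) {
  diff <- calls[!is.na(calls$differential) & calls$differential, ]
  tab <- table(factor(diff$event_type, levels = .event_types),
               factor(as.character(diff$direction), levels = c("EI", "ES")))
  out <- as.data.frame.matrix(tab)
  out$event_type <- rownames(out)
  rownames(out) <- NULL
  out <- out[, c("event_type", "EI", "ES")]
  attr(out, "n_differential") <- nrow(diff)
  out
}

#' Cross-PRMT regulation classes and direction concordance
#'
#' Partitions the shared event universe by how many knockdowns call each
#' event differential (1, 2 or 3 regulators), and checks whether events
#' regulated by several enzymes move in the same direction. An event is
#' concordant when all its regulators call the same direction. The
#' contradiction count tallies events called EI by one regulator and ES by
#' another.
#'
#' @param calls_list Named list of call data frames (one per knockdown)
#'   over the same event universe; an error lists missing event IDs
#'   otherwise.
#' @return List with `events` (per-event class/direction table),
#'   `n_by_class` (events with 1/2/3 regulators), `n_concordant`,
#'   `n_discordant`, `concordance_fraction` (over events with >=2
#'   regulators) and `n_contradictory`.
#' @export
concordance_analysis <- function(calls_list) {
  stopifnot(length(calls_list) >= 2)
  ids <- lapply(calls_list, function(x) sort(x$event_id))
  for (i in seq_along(ids)[-1]) {
    miss <- c(setdiff(ids[[1]], ids[[i]]), setdiff(ids[[i]], ids[[1]]))
    if (length(miss)) {
      stop("event universes differ between '", names(calls_list)[1],
           "' and '", names(calls_list)[i], "': ",
           paste(utils::head(miss, 10), collapse = ", "))
    }
  }
  universe <- ids[[1]]
  dirs <- sapply(calls_list, function(x) {
    as.character(x$direction[match(universe, x$event_id)])
  })
  dirs <- matrix(dirs, nrow = length(universe),
                 dimnames = list(universe, names(calls_list)))
  is_reg <- !is.na(dirs) & dirs != "none"
  n_reg <- rowSums(is_reg)
  concord <- vapply(seq_along(universe), function(i) {
    d <- dirs[i, is_reg[i, ]]
    length(unique(d)) == 1L
  }, logical(1))
  concord[n_reg < 2] <- NA
  events <- data.frame(event_id = universe, n_regulators = n_reg,
                       regulators = apply(is_reg, 1, function(r)
                         paste(names(calls_list)[r], collapse = ",")),
                       direction = apply(dirs, 1, function(d) {
                         d <- d[!is.na(d) & d != "none"]
                         paste(d, collapse = ",")
                       }),
                       concordant = concord)
  shared <- events[events$n_regulators >= 2, ]
  list(events = events,
       n_by_class = c(`1` = sum(n_reg == 1), `2` = sum(n_reg == 2),
                      `3` = sum(n_reg == 3)),
       n_concordant = sum(shared$concordant, na.rm = TRUE),
       n_discordant = sum(!shared$concordant, na.rm = TRUE),
       concordance_fraction = if (nrow(shared)) mean(shared$concordant)
                              else NA_real_,
       n_contradictory = sum(!shared$concordant, na.rm = TRUE))
}

#' FPKM and the expression-inclusion filter
#'
#' FPKM = mapped reads on exons / (exonic length in kb) / (total mapped
#' reads in millions). Genes are kept when FPKM exceeds `keep_threshold`
#' (strictly) in at least one condition.
#'
#' @param mapped_reads_on_exons Reads mapped to the gene's exons
#'   (vectorised).
#' @param exonic_length_bp Exonic length in base pairs (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return Numeric FPKM vector.
#' @export
fpkm <- function(mapped_reads_on_exons, exonic_length_bp,
                 total_mapped_reads) {
  if (any(exonic_length_bp <= 0) || any(total_mapped_reads <= 0)) {
    stop("exonic length and total mapped reads must be positive")
  }
  mapped_reads_on_exons / (exonic_length_bp / 1000) /
    (total_mapped_reads / 1e6)
}

#' @rdname fpkm
#' @param fpkm_matrix Matrix of FPKM values, genes x conditions.
#' @param keep_threshold Strict lower bound for inclusion, default 0.5.
#' @return `fpkm_keep`: logical vector, `TRUE` for genes with
#'   `FPKM > keep_threshold` in any condition.
#' @export
fpkm_keep <- function(fpkm_matrix, keep_threshold = 0.5) {
  apply(as.matrix(fpkm_matrix) > keep_threshold, 1, any)
}

#' Central positional enrichment of a motif in upstream sequences
#'
#' Tests whether matches of an IUPAC motif concentrate in the central
#' window of a set of equal-purpose sequences (e.g. the region upstream of
#' alternatively spliced exons), a simplified local-enrichment analogue of
#' centrally-biased motif scanning. All match start positions are pooled;
#' under the null of uniform placement a match falls in the central window
#' of its sequence with probability `p0 = window positions / usable
#' positions`, and the one-sided binomial tail of the central count against
#' `p0` is the p-value.
#'
#' @param sequences Character vector of nucleotide sequences (ACGTU; U is
#'   treated as T).
#' @param motif IUPAC motif string (e.g. `"TAGGGW"`).
#' @param center_window Width in bp of the central window.
#' @return List with `n_matches`, `n_central`, `p0` and `p_value`.
#' @export
central_motif_enrichment <- function(sequences, motif, center_window = 100) {
  if (!length(sequences)) stop("empty sequence set")
  seqs <- chartr("Uu", "Tt", toupper(sequences))
  if (any(nchar(seqs) < nchar(motif))) {
    stop("motif longer than the shortest sequence")
  }
  set <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern(motif, set, fixed = FALSE)
  mlen <- nchar(motif)
  n_total <- 0L
  n_central <- 0L
  p0_num <- 0
  p0_den <- 0
  half <- center_window / 2
  for (i in seq_along(seqs)) {
    usable <- nchar(seqs[i]) - mlen + 1L  # possible start positions
    center <- (usable + 1) / 2
    in_win <- function(s) abs(s - center) <= half
    win_n <- sum(in_win(seq_len(usable)))
    p0_num <- p0_num + win_n
    p0_den <- p0_den + usable
    starts <- Biostrings::startIndex(hits)[[i]]
    if (length(starts)) {
      n_total <- n_total + length(starts)
      n_central <- n_central + sum(in_win(starts))
    }
  }
  p0 <- p0_num / p0_den
  p <- if (n_total == 0L) 1 else
    stats::pbinom(n_central - 1, n_total, p0, lower.tail = FALSE)
  list(n_matches = n_total, n_central = n_central, p0 = p0, p_value = p)
}
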