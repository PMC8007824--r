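#' Phosphosite counts in the vicinity of methyl sites
#'
#' For each methyl-arginine, counts the phosphosites on the same protein
#' within `w` residues (the site position itself is excluded: an arginine
#' cannot itself be phosphorylated). The per-site counts are summarised
#' into the bins 0, 1, 2, 3, >=4.
#'
#' @param methyl_sites Data frame with `protein`, `position`.
#' @param phospho_sites Data frame with `protein`, `position`. Phosphosites
#'   on proteins absent from `methyl_sites` are simply never consulted;
#'   methyl sites on proteins with no phosphosites get count 0.
#' @param w Half-width of the proximity window in residues (3 or 5 are the
#'   conventional choices).
#' @return List with `counts` (integer per methyl site), `bins` (named
#'   fractions over `0,1,2,3,>=4`, summing to 1) and `frac_ge1`.
#' @export
phospho_proximity <- function(methyl_sites, phospho_sites, w = 3) {
  stopifnot(w >= 1)
  bypro <- lapply(split(phospho_sites$position, phospho_sites$protein),
                  function(p) sort(unique(p)))
  counts <- integer(nrow(methyl_sites))
  for (id in unique(methyl_sites$protein)) {
    sel <- methyl_sites$protein == id
    pp <- bypro[[id]]
    if (is.null(pp)) next
    pos <- methyl_sites$position[sel]
    # phosphosites in [pos - w, pos + w], excluding the position itself
    n_win <- findInterval(pos + w, pp) - findInterval(pos - w - 1, pp)
    counts[sel] <- n_win - (pos %in% pp)
  }
  list(counts = counts, bins = .bin_counts(counts),
       frac_ge1 = mean(counts >= 1))
}

.bin_counts <- function(counts) {
  b <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
         sum(counts == 3), sum(counts >= 4))
  setNames(b / length(counts), c("0", "1", "2", "3", ">=4"))
}

#' Null distribution of phospho proximity over random arginines
#'
#' Draws `n_resamples` random sets of `n_fg` arginine positions from the
#' proteome (uniformly, without replacement) and computes for each the
#' fraction of positions with at least one phosphosite within `w` residues.
#' The empirical p-value for the observed foreground fraction uses the
#' add-one correction `(1 + #{resamples >= observed}) / (1 + n_resamples)`,
#' so it is never zero.
#'
#' @param proteome Named character vector of sequences.
#' @param phospho_sites Data frame with `protein`, `position`.
#' @param n_fg Number of positions per resample (match the foreground size).
#' @param observed_ge1 Observed foreground ">=1 phospho in window" fraction
#'   (see [phospho_proximity()]).
#' @param w Window half-width.
#' @param n_resamples Number of resamples.
#' @param seed Seed for the resampling.
#' @param exclude Optional data frame of `protein`, `position` to remove
#'   from the sampling pool (e.g. the foreground sites themselves).
#' @return List with `p_value`, `bg_ge1` (vector of resample fractions),
#'   `bg_bins_mean` and `bg_bins_sd` (distribution over the 0..>=4 bins).
#' @export
phospho_background <- function(proteome, phospho_sites, n_fg, observed_ge1,
                               w = 3, n_resamples = 999, seed = 1,
                               exclude = NULL) {
  pool <- arginine_positions(proteome)
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(pool$protein, pool$position) %in%
      paste(exclude$protein, exclude$position)
    pool <- pool[!drop, , drop = FALSE]
  }
  if (nrow(pool) < n_fg) {
    stop("proteome has fewer arginines (", nrow(pool), ") than n_fg (",
         n_fg, ")")
  }
  # precompute the proximity count of every pool position once
  pool_counts <- phospho_proximity(pool, phospho_sites, w)$counts

  set.seed(seed)
  ge1 <- numeric(n_resamples)
  bins <- matrix(0, nrow = n_resamples, ncol = 5)
  for (r in seq_len(n_resamples)) {
    idx <- sample.int(nrow(pool), n_fg)
    cc <- pool_counts[idx]
    ge1[r] <- mean(cc >= 1)
    bins[r, ] <- .bin_counts(cc)
  }
  p <- (1 + sum(ge1 >= observed_ge1)) / (1 + n_resamples)
  list(p_value = p, bg_ge1 = ge1,
       bg_bins_mean = setNames(colMeans(bins), c("0", "1", "2", "3", ">=4")),
       bg_bins_sd = setNames(apply(bins, 2, stats::sd),
                             c("0", "1", "2", "3", ">=4")))
}

# positions considered for a mutation-rate computation: the sites themselves,
# or the deduplicated union of +/-w windows clipped to protein bounds
.considered_positions <- function(sites, proteome, w, mode) {
  if (mode == "at_site") {
    out <- unique(sites[, c("protein", "position")])
    return(out)
  }
  bypro <- split(sites$position, sites$protein)
  chunks <- lapply(names(bypro), function(id) {
    len <- nchar(proteome[[id]])
    pos <- unique(unlist(lapply(bypro[[id]], function(p) {
      seq(max(1, p - w), min(len, p + w))
    })))
    data.frame(protein = id, position = sort(pos))
  })
  do.call(rbind, chunks)
}

#' Somatic-mutation rate at or around a set of residue positions
#'
#' The mutation table is collapsed to a binary "position mutated at least
#' once"; the rate is the fraction of considered positions that are
#' mutated. In `at_site` mode the considered positions are the sites
#' themselves; in `vicinity` mode they are the union of the +/-`w` windows
#' around the sites (center included, overlapping windows deduplicated,
#' clipped to the protein termini).
#'
#' @param sites Data frame with `protein`, `position`.
#' @param mutations Data frame with `protein`, `position` (and optionally
#'   `count`; any row marks the position as mutated).
#' @param proteome Named character vector (needed in vicinity mode to clip
#'   windows to protein bounds).
#' @param w Window half-width (ignored in `at_site` mode).
#' @param mode `"at_site"` or `"vicinity"`.
#' @return List with `rate`, `n_mutated`, `n_positions` and the considered
#'   `positions` data frame.
#' @export
mutation_rate <- function(sites, mutations, proteome = NULL, w = 5,
                          mode = c("at_site", "vicinity")) {
  mode <- match.arg(mode)
  if (mode == "vicinity" && is.null(proteome)) {
    stop("vicinity mode needs the proteome to clip windows to bounds")
  }
  pos <- .considered_positions(sites, proteome, w, mode)
  mutated_keys <- unique(paste(mutations$protein, mutations$position))
  hit <- paste(pos$protein, pos$position) %in% mutated_keys
  list(rate = mean(hit), n_mutated = sum(hit), n_positions = nrow(pos),
       positions = pos)
}

#' Mutation enrichment at methyl sites vs background arginines
#'
#' Builds the 2x2 table (foreground/background positions x mutated/not) and
#' tests it with the two-sided Fisher's exact test. Background positions
#' overlapping the foreground are removed automatically so the rows stay
#' disjoint.
#'
#' @param fg_sites Data frame of foreground sites (`protein`, `position`).
#' @param bg_sites Data frame of background sites; e.g. all proteome
#'   arginines from [arginine_positions()].
#' @param mutations Mutation table (`protein`, `position`).
#' @param proteome Proteome (for vicinity clipping).
#' @param w Window half-width for vicinity mode.
#' @param mode `"at_site"` or `"vicinity"`.
#' @return List with `rate_fg`, `rate_bg`, `odds_ratio`, `p_value` and
#'   `table` (the 2x2 matrix).
#' @export
mutation_enrichment <- function(fg_sites, bg_sites, mutations,
                                proteome = NULL, w = 5,
                                mode = c("at_site", "vicinity")) {
  mode <- match.arg(mode)
  fg <- mutation_rate(fg_sites, mutations, proteome, w, mode)
  bgp <- .considered_positions(bg_sites, proteome, w, mode)
  drop <- paste(bgp$protein, bgp$position) %in%
    paste(fg$positions$protein, fg$positions$position)
  bgp <- bgp[!drop, , drop = FALSE]
  mutated_keys <- unique(paste(mutations$protein, mutations$position))
  bg_hit <- paste(bgp$protein, bgp$position) %in% mutated_keys
  a <- fg$n_mutated
  b <- fg$n_positions - fg$n_mutated
  c_ <- sum(bg_hit)
  d <- nrow(bgp) - sum(bg_hit)
  ft <- fisher_exact(matrix(c(a, c_, b, d), nrow = 2))
  list(rate_fg = fg$rate, rate_bg = mean(bg_hit),
       odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       table = matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                      dimnames = list(c("fg", "bg"),
                                      c("mutated", "not_mutated"))))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test: with all margins fixed, the count in the first
#' cell follows a hypergeometric distribution; the two-sided p-value is the
#' total probability of all tables whose point probability does not exceed
#' the observed table's (with a small relative tolerance guarding
#' floating-point ties). The odds ratio is the sample odds ratio
#' `(a d) / (b c)`. A table with a zero margin carries no information:
#' p = 1 and the odds ratio is reported as `NA` with a warning.
#'
#' @param tab 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`.
#' @return List with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("negative count in contingency table")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_      # first-column margin
  n <- b + d       # second-column margin
  k <- a + b       # first-row margin
  if (m == 0 || n == 0 || k == 0 || c_ + d == 0) {
    warning("degenerate margin in contingency table; p = 1")
    return(list(p_value = 1, odds_ratio = NA_real_))
  }
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c_)
  list(p_value = p, odds_ratio = or)
}
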