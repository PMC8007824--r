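#' Extract the residue window around one methyl-arginine
#'
#' Returns the `2k+1`-residue window centered on the site (default k = 5,
#' i.e. an 11-residue window). Offsets beyond the protein termini are
#' padded with `-`. The center must be an arginine: any other residue
#' indicates a coordinate error and is a hard failure.
#'
#' @param proteome Named character vector (see [read_fasta()]).
#' @param protein Protein ID.
#' @param position 1-based residue position of the methyl-arginine.
#' @param k Half-width of the window.
#' @param require_R Require the center residue to be `R` (default TRUE).
#' @return Character scalar of length `2k+1`.
#' @export
extract_window <- function(proteome, protein, position, k = 5,
                           require_R = TRUE) {
  if (!protein %in% names(proteome)) stop("unknown protein: ", protein)
  seq <- proteome[[protein]]
  len <- nchar(seq)
  if (position < 1 || position > len) {
    stop("position ", position, " out of range for ", protein,
         " (length ", len, ")")
  }
  if (require_R && substr(seq, position, position) != "R") {
    stop("center residue at ", protein, ":", position, " is '",
         substr(seq, position, position), "', not 'R'")
  }
  core <- substr(seq, max(1, position - k), min(len, position + k))
  paste0(strrep("-", max(0, k - position + 1)),
         core,
         strrep("-", max(0, position + k - len)))
}

#' Extract windows for a table of methyl sites
#'
#' @param proteome Named character vector of sequences.
#' @param sites Data frame with `protein` and `position` columns.
#' @param k Half-width.
#' @param require_R Require arginine centers.
#' @return Character vector of windows, one per row of `sites`.
#' @export
extract_windows <- function(proteome, sites, k = 5, require_R = TRUE) {
  vapply(seq_len(nrow(sites)), function(i) {
    extract_window(proteome, sites$protein[i], sites$position[i], k,
                   require_R = require_R)
  }, character(1))
}

#' All arginine positions in a proteome
#'
#' Enumerates every arginine residue; this is the sampling pool for the
#' arginine-anchored backgrounds used by [positional_enrichment()] and
#' [phospho_background()].
#'
#' @param proteome Named character vector of sequences.
#' @return Data frame with `protein` and `position`.
#' @export
arginine_positions <- function(proteome) {
  hits <- lapply(names(proteome), function(id) {
    pos <- gregexpr("R", proteome[[id]], fixed = TRUE)[[1]]
    if (pos[1] == -1L) return(NULL)
    data.frame(protein = id, position = as.integer(pos))
  })
  do.call(rbind, hits)
}

#' Classify methyl-site windows into GAR / RXR / other motifs
#'
#' GAR (glycine-and-arginine-rich, covering RG/RGG contexts): a glycine
#' immediately adjacent to the methyl-arginine (offset -1 or +1). RXR: an
#' arginine two residues away (offset -2 or +2). GAR takes precedence when
#' both patterns are present, so the classes are mutually exclusive and
#' exhaustive. Only offsets within +/-2 are consulted, so any window with
#' k >= 2 works.
#'
#' @param windows Character vector of odd-length windows centered on `R`.
#' @return Factor with levels `GAR`, `RXR`, `other`.
#' @export
classify_motif <- function(windows) {
  n <- nchar(windows)
  stopifnot(all(n %% 2 == 1), all(n >= 5))
  c0 <- (n + 1) / 2
  at <- function(off) substr(windows, c0 + off, c0 + off)
  gar <- at(-1) == "G" | at(1) == "G"
  rxr <- !gar & (at(-2) == "R" | at(2) == "R")
  factor(ifelse(gar, "GAR", ifelse(rxr, "RXR", "other")),
         levels = c("GAR", "RXR", "other"))
}

#' Motif-class fractions of a window set
#'
#' @param windows Character vector of windows (or a factor from
#'   [classify_motif()]).
#' @return Named numeric vector of fractions over `GAR`, `RXR`, `other`
#'   (sums to 1).
#' @export
motif_fractions <- function(windows) {
  stopifnot(length(windows) >= 1)
  cls <- if (is.factor(windows)) windows else classify_motif(windows)
  tab <- table(cls)
  setNames(as.numeric(tab) / length(cls), names(tab))
}

# per-offset residue frequency matrix for a set of windows (pads excluded
# from the denominators)
.window_freq <- function(windows, k) {
  m <- matrix(0, nrow = length(.aa20), ncol = 2 * k + 1,
              dimnames = list(.aa20, as.character(-k:k)))
  chars <- strsplit(windows, "", fixed = TRUE)
  cm <- matrix(unlist(chars), nrow = length(windows), byrow = TRUE)
  for (j in seq_len(2 * k + 1)) {
    col <- cm[, j]
    col <- col[col != "-"]
    if (!length(col)) next
    tab <- table(factor(col, levels = .aa20))
    m[, j] <- as.numeric(tab) / length(col)
  }
  m
}

#' Position-specific residue enrichment against a sampled proteome background
#'
#' Measures which residues are over- or under-represented at each offset
#' around the methyl-arginines, relative to random arginine-centered windows
#' from the proteome (the background is arginine-anchored because the
#' foreground is). `n_samples` random window sets of `sample_size` arginines
#' are drawn; for every (offset, residue) cell the background mean and sd of
#' the frequency give a Z-score for the foreground frequency, a two-sided
#' normal p-value, and the percent difference. Cells with `p < alpha` are
#' flagged. When the background sd is zero the Z is reported as +/-Inf if
#' the foreground differs from the background mean and 0 otherwise.
#'
#' @param foreground Character vector of equal-width windows (see
#'   [extract_windows()]).
#' @param proteome Named character vector of sequences.
#' @param n_samples Number of background window sets.
#' @param sample_size Arginines per background set; defaults to the
#'   foreground size.
#' @param seed Seed for the background sampling (recorded in the output).
#' @param alpha Flagging threshold on the two-sided p-value.
#' @return Data frame with one row per (offset, residue): `offset`,
#'   `residue`, `freq_fg`, `mean_bg`, `sd_bg`, `z`, `p_value`, `pct_diff`,
#'   `flagged`; attributes `seed`, `n_samples`, `sample_size`.
#' @export
positional_enrichment <- function(foreground, proteome, n_samples = 200,
                                  sample_size = length(foreground),
                                  seed = 1, alpha = 0.01) {
  stopifnot(length(foreground) >= 1)
  k <- (nchar(foreground[1]) - 1) / 2
  stopifnot(all(nchar(foreground) == 2 * k + 1))
  pool <- arginine_positions(proteome)
  if (nrow(pool) < sample_size) {
    stop("proteome has fewer arginines (", nrow(pool),
         ") than sample_size (", sample_size, ")")
  }
  pool_windows <- extract_windows(proteome, pool, k = k)
  fg <- .window_freq(foreground, k)

  set.seed(seed)
  bg <- array(0, dim = c(length(.aa20), 2 * k + 1, n_samples))
  for (s in seq_len(n_samples)) {
    idx <- sample.int(nrow(pool), sample_size)
    bg[, , s] <- .window_freq(pool_windows[idx], k)
  }
  mean_bg <- apply(bg, c(1, 2), mean)
  sd_bg <- apply(bg, c(1, 2), stats::sd)

  z <- (fg - mean_bg) / sd_bg
  zero_sd <- sd_bg == 0
  z[zero_sd] <- ifelse(fg[zero_sd] > mean_bg[zero_sd], Inf,
                       ifelse(fg[zero_sd] < mean_bg[zero_sd], -Inf, 0))
  p <- 2 * stats::pnorm(-abs(z))
  p[is.infinite(z)] <- 0

  out <- data.frame(
    offset = rep(-k:k, each = length(.aa20)),
    residue = rep(.aa20, times = 2 * k + 1),
    freq_fg = as.vector(fg),
    mean_bg = as.vector(mean_bg),
    sd_bg = as.vector(sd_bg),
    z = as.vector(z),
    p_value = as.vector(p),
    pct_diff = as.vector((fg - mean_bg) * 100)
  )
  out$flagged <- out$p_value < alpha
  attr(out, "seed") <- seed
  attr(out, "n_samples") <- n_samples
  attr(out, "sample_size") <- sample_size
  out
}
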