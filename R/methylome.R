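#' Compute heavy/light SILAC ratios for methyl sites
#'
#' In the SILAC design the light channel is the control and the heavy
#' channel is the perturbed (knockdown or inhibitor-treated) state, so the
#' heavy/light ratio directly reads out the effect of the perturbation on
#' each methyl site. Zero intensities are coerced to absent: a signal at the
#' detector floor is indistinguishable from no signal, and an absent heavy
#' channel is what defines an abolished site.
#'
#' @param sites Data frame with columns `protein`, `position`, `methyl_type`,
#'   `intensity_L`, `intensity_H` (the `site_quant` schema).
#' @return `sites` with added columns `ratio_HL` and `log2_ratio` (`NA` when
#'   not computable) and logical `light_only` (light present, heavy absent).
#' @export
compute_site_ratio <- function(sites) {
  L <- sites$intensity_L
  H <- sites$intensity_H
  L[!is.na(L) & L <= 0] <- NA_real_
  H[!is.na(H) & H <= 0] <- NA_real_
  ratio <- ifelse(!is.na(L) & !is.na(H), H / L, NA_real_)
  sites$ratio_HL <- ratio
  sites$log2_ratio <- log2(ratio)
  sites$light_only <- !is.na(L) & is.na(H)
  sites$intensity_L <- L
  sites$intensity_H <- H
  sites
}

#' Classify methyl sites from their SILAC ratios
#'
#' Applies the fold-change cascade: a site whose heavy channel is absent
#' while the light channel was detected is `abolished`; a quantified site
#' with ratio at or below `1/fold_change` is `decreased` ("at least" a
#' fold-change reduction, so the boundary is inclusive); at or above
#' `fold_change` it is `increased`; otherwise `unchanged`. Sites without a
#' light signal are `not_quantified`. Abolished sites count as decreased in
#' every tally (see [call_methylome()]).
#'
#' @param sites Data frame as returned by [compute_site_ratio()].
#' @param fold_change Fold-change threshold (> 1), default 2.
#' @return `sites` with an added `status` column (factor with levels
#'   `not_quantified`, `unchanged`, `decreased`, `abolished`, `increased`).
#' @export
classify_site <- function(sites, fold_change = 2) {
  stopifnot(fold_change > 1)
  if (!"ratio_HL" %in% names(sites)) sites <- compute_site_ratio(sites)
  status <- rep("not_quantified", nrow(sites))
  quant <- !is.na(sites$ratio_HL)
  status[quant] <- "unchanged"
  status[quant & sites$ratio_HL <= 1 / fold_change] <- "decreased"
  status[quant & sites$ratio_HL >= fold_change] <- "increased"
  status[sites$light_only] <- "abolished"
  sites$status <- factor(status, levels = .site_statuses)
  sites
}

#' Flag sites whose apparent regulation is explained by protein abundance
#'
#' A decrease in a methyl site's signal can reflect a decrease in the
#' protein's abundance rather than a change in methylation stoichiometry.
#' Dividing the site ratio by the protein ratio gives the normalized ratio;
#' a site called decreased on the raw ratio whose normalized ratio no longer
#' clears the fold-change cut is flagged `protein_explained`. The flag does
#' not delete the site: reports carry both the raw and the normalized view,
#' and [call_methylome()] excludes flagged sites from the methylome. Sites
#' on proteins without protein-level quantification are retained unflagged.
#'
#' @param sites Data frame as returned by [classify_site()].
#' @param protein_ratios Named numeric vector: protein ID -> heavy/light
#'   protein-abundance ratio (`NA` or missing name = not quantified).
#' @param fold_change Fold-change threshold used for the raw calls.
#' @return `sites` with added `normalized_ratio` and logical
#'   `protein_explained` columns.
#' @export
normalize_to_protein <- function(sites, protein_ratios, fold_change = 2) {
  pr <- protein_ratios[sites$protein]
  zero <- !is.na(pr) & pr == 0
  if (any(zero)) {
    warning("protein ratio of zero for ",
            paste(unique(sites$protein[zero]), collapse = ", "),
            "; normalized ratio set to absent")
    pr[zero] <- NA_real_
  }
  sites$normalized_ratio <- sites$ratio_HL / as.numeric(pr)
  sites$protein_explained <- !is.na(sites$normalized_ratio) &
    sites$status == "decreased" &
    sites$normalized_ratio > 1 / fold_change
  sites
}

.protein_ratio_vector <- function(protein_table) {
  if (is.null(protein_table) || nrow(protein_table) == 0L) {
    return(setNames(numeric(0), character(0)))
  }
  L <- protein_table$intensity_L
  H <- protein_table$intensity_H
  L[!is.na(L) & L <= 0] <- NA_real_
  H[!is.na(H) & H <= 0] <- NA_real_
  setNames(H / L, protein_table$protein)
}

#' Call the methylome of one PRMT from SILAC tables
#'
#' Runs the full calling cascade for one perturbation: deduplicate sites by
#' (protein, position, methyl type) so a site recovered from several
#' enrichment experiments is counted once, restrict to the methyl
#' modalities profiled for this enzyme, compute ratios, classify against
#' the fold-change threshold, and apply the protein-abundance control. The
#' methylome is the set of decreased-or-abolished sites not explained by a
#' protein-level change, together with the proteins carrying them (the
#' putative substrates).
#'
#' The tally reports the cascade at site and protein level. Because an
#' abolished site has no heavy signal, "quantified" is reported under both
#' conventions: `n_quantified` (both channels measured) and
#' `n_quantified_incl_abolished`.
#'
#' @param site_table `site_quant` data frame for one perturbation.
#' @param protein_table Optional `protein_quant` data frame measured in
#'   parallel; `NULL` disables the protein-abundance control.
#' @param modalities Character vector of methyl types to keep, e.g.
#'   `c("MMA")` for a type III enzyme, `c("MMA", "aDMA")` for type I,
#'   `c("MMA", "sDMA")` for type II.
#' @param fold_change Fold-change threshold, default 2.
#' @param prmt_label Label for the perturbed enzyme.
#' @return A `methylome` object: list with `prmt_label`, `calls` (the full
#'   annotated site table), `sites` (the regulated subset), `proteins`
#'   (substrate IDs) and `tally`.
#' @export
call_methylome <- function(site_table, protein_table = NULL,
                           modalities = .methyl_types, fold_change = 2,
                           prmt_label = "PRMT") {
  stopifnot(all(modalities %in% .methyl_types))
  if (nrow(site_table) == 0L) {
    warning("empty site table for ", prmt_label, "; empty methylome")
  }
  x <- site_table[site_table$methyl_type %in% modalities, , drop = FALSE]
  key <- paste(x$protein, x$position, x$methyl_type, sep = "|")
  x <- x[!duplicated(key), , drop = FALSE]
  x <- classify_site(compute_site_ratio(x), fold_change)
  x <- normalize_to_protein(x, .protein_ratio_vector(protein_table),
                            fold_change)
  regulated <- x$status %in% c("decreased", "abolished") &
    !x$protein_explained
  sites <- x[regulated, , drop = FALSE]
  decreased_all <- x$status %in% c("decreased", "abolished")
  tally <- list(
    n_detected = nrow(x),
    n_quantified = sum(!is.na(x$ratio_HL)),
    n_quantified_incl_abolished =
      sum(!is.na(x$ratio_HL)) + sum(x$status == "abolished"),
    n_decreased = sum(decreased_all),
    n_abolished = sum(x$status == "abolished"),
    n_increased = sum(x$status == "increased"),
    n_protein_explained = sum(x$protein_explained),
    n_regulated = nrow(sites),
    proteins_detected = length(unique(x$protein)),
    proteins_decreased = length(unique(x$protein[decreased_all])),
    proteins_abolished = length(unique(x$protein[x$status == "abolished"])),
    proteins_protein_explained =
      length(unique(x$protein[x$protein_explained])),
    proteins_regulated = length(unique(sites$protein))
  )
  structure(list(prmt_label = prmt_label, calls = x, sites = sites,
                 proteins = sort(unique(sites$protein)), tally = tally),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat("Methylome:", x$prmt_label, "\n")
  cat("  ", x$tally$n_regulated, "regulated sites on",
      length(x$proteins), "proteins\n")
  cat("  cascade: detected", x$tally$n_detected,
      ">= quantified(+abolished)", x$tally$n_quantified_incl_abolished,
      ">= decreased", x$tally$n_decreased,
      ">= abolished", x$tally$n_abolished, "\n")
  invisible(x)
}

#' Partition substrates by how many PRMTs regulate them
#'
#' Compares two or more methylomes and assigns each element (protein, or
#' protein+position) to the class of substrates regulated by exactly 1, 2,
#' ... of the enzymes. At position level the methyl type is ignored, since
#' the same arginine can carry mono- and di-methyl marks installed by
#' different enzymes.
#'
#' @param methylomes List of `methylome` objects with distinct labels.
#' @param level `"protein"` or `"position"`.
#' @return Data frame with `key`, `protein` (and `position` at position
#'   level), `regulators` (comma-separated labels) and `n_regulators`; the
#'   classes are disjoint and cover the union of the inputs.
#' @export
intersect_methylomes <- function(methylomes, level = c("protein", "position")) {
  level <- match.arg(level)
  stopifnot(length(methylomes) >= 2)
  labels <- vapply(methylomes, `[[`, character(1), "prmt_label")
  if (anyDuplicated(labels)) stop("duplicate prmt_label in methylomes")
  keysets <- lapply(methylomes, function(m) {
    if (level == "protein") unique(m$sites$protein)
    else unique(paste(m$sites$protein, m$sites$position, sep = "|"))
  })
  all_keys <- sort(unique(unlist(keysets)))
  member <- vapply(keysets, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(NULL, labels))
  out <- data.frame(key = all_keys, stringsAsFactors = FALSE)
  if (level == "position") {
    parts <- strsplit(all_keys, "|", fixed = TRUE)
    out$protein <- vapply(parts, `[`, character(1), 1)
    out$position <- as.integer(vapply(parts, `[`, character(1), 2))
  } else {
    out$protein <- all_keys
  }
  out$regulators <- apply(member, 1, function(r)
    paste(labels[r], collapse = ","))
  out$n_regulators <- rowSums(member)
  out
}

#' Distribution of regulated-site counts per substrate
#'
#' @param methylome A `methylome` object with at least one substrate.
#' @return Data frame `n_sites`, `n_proteins`, `fraction` (fractions sum
#'   to 1).
#' @export
sites_per_protein <- function(methylome) {
  stopifnot(length(methylome$proteins) > 0)
  counts <- table(table(methylome$sites$protein))
  data.frame(n_sites = as.integer(names(counts)),
             n_proteins = as.integer(counts),
             fraction = as.integer(counts) / sum(counts))
}

#' Cross-validate two substrate sets against each other
#'
#' Measures what fraction of methylome A's substrates were recovered in
#' methylome B (e.g. knockdown vs inhibitor of the same enzyme), and how
#' surprising the overlap is under random draws from the detected universe
#' (one-sided hypergeometric, via [hypergeom_overlap()]).
#'
#' @param methylome_a,methylome_b `methylome` objects (or character vectors
#'   of protein IDs).
#' @param universe Character vector of protein IDs both sets are drawn from.
#' @return List with `fraction` (|A n B| / |A|), `overlap` and `p_value`.
#' @export
crossvalidate_calls <- function(methylome_a, methylome_b, universe) {
  a <- if (inherits(methylome_a, "methylome")) methylome_a$proteins
       else unique(methylome_a)
  b <- if (inherits(methylome_b, "methylome")) methylome_b$proteins
       else unique(methylome_b)
  if (!all(union(a, b) %in% universe)) {
    stop("universe smaller than the union of the two methylomes")
  }
  ov <- hypergeom_overlap(a, b, universe)
  list(fraction = ov$overlap / length(a), overlap = ov$overlap,
       p_value = ov$p_value)
}
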