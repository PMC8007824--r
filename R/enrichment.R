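#' One-sided hypergeometric overlap test
#'
#' Significance of the overlap between two identifier sets drawn from a
#' stated universe: the enrichment (upper) tail
#' `P[X >= |a n b|]` for `X ~ Hypergeometric(|U|, |a|, |b|)`. The universe
#' must be supplied explicitly; both sets must be contained in it.
#'
#' @param a,b Character vectors of identifiers.
#' @param universe Character vector containing both sets.
#' @return List with `overlap`, `expected` (|a||b|/|U|), `p_value`,
#'   `n_a`, `n_b`, `n_universe`.
#' @export
hypergeom_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  off <- setdiff(union(a, b), universe)
  if (length(off)) {
    stop("identifiers outside the universe: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  q <- length(intersect(a, b))
  N <- length(universe); m <- length(a); n <- length(b)
  p <- stats::phyper(q - 1, m, N - m, n, lower.tail = FALSE)
  list(overlap = q, expected = m * n / N, p_value = p,
       n_a = m, n_b = n, n_universe = N)
}

#' Gene-set over-representation analysis
#'
#' Tests a query set against every set of a GMT collection with the
#' one-sided hypergeometric overlap test, within an explicit universe, and
#' applies Benjamini-Hochberg correction across the tested sets. Gene sets
#' are intersected with the universe before testing.
#'
#' @param query Character vector of identifiers (must be non-empty and
#'   contained in `universe`).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector.
#' @return Data frame ordered by p-value: `set`, `set_size`, `overlap`,
#'   `expected`, `p_value`, `bh_q`.
#' @export
ora <- function(query, gene_sets, universe) {
  if (!length(query)) stop("empty query set")
  query <- unique(query)
  off <- setdiff(query, universe)
  if (length(off)) {
    stop("query identifiers outside the universe: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    ov <- hypergeom_overlap(query, s, universe)
    data.frame(set = nm, set_size = length(s), overlap = ov$overlap,
               expected = ov$expected, p_value = ov$p_value)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
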