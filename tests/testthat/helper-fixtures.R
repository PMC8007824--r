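# Small fixtures built in code.

# minimal methylome object from vectors of regulated sites
make_methylome <- function(label, protein, position) {
  sites <- data.frame(protein = protein, position = position)
  structure(list(prmt_label = label, calls = sites, sites = sites,
                 proteins = sort(unique(protein)),
                 tally = list(n_regulated = nrow(sites))),
            class = "methylome")
}

# site_quant rows with sensible defaults
site_rows <- function(protein, position, L, H, methyl_type = "MMA") {
  data.frame(protein = protein, position = position,
             methyl_type = methyl_type, intensity_L = L, intensity_H = H)
}

# a deterministic toy proteome: a 240-residue RGG-domain carrier with
# methyl-arginines at the canonical positions, plus a glycine-free partner
toy_proteome <- function() {
  s <- strsplit(strrep("G", 240), "")[[1]]
  for (p in c(194, 196, 206, 218, 225, 232)) s[p] <- "R"
  c(HNRNPA1 = paste(s, collapse = ""),
    PLAIN = paste0(strrep("A", 50), "R", strrep("L", 50)))
}
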