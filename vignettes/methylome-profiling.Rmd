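---
title: "Methods: calling and characterising PRMT-regulated methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterising PRMT-regulated methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `methylomap`, the parameters
that matter, the design decisions taken where several reasonable choices
existed, and what the synthetic validation does and does not demonstrate.

## Substrate calling from SILAC ratios

The unit of analysis is one methyl site — a (protein, residue position,
methyl type) triple — with light (control) and heavy (perturbed) channel
intensities. The heavy/light ratio $r = I_H / I_L$ is compared to a
fold-change threshold $t$ (default **2**, dimensionless):

* $r \le 1/t$: **decreased** (the boundary is inclusive — "at least
  $t$-fold" means the boundary counts);
* heavy absent, light detected: **abolished** — the extreme of decreased,
  and counted inside every decreased tally;
* $r \ge t$: **increased**; otherwise **unchanged**;
* light absent: **not quantified**.

Two conventions interact here. First, *absent is not zero but zero is
absent*: a reported zero intensity sits at the detector floor and cannot
be distinguished from a failure to detect, so `compute_site_ratio()`
coerces non-positive intensities to absent. This is what makes "abolished"
a well-defined state rather than a division by zero. Second, because an
abolished site has no ratio, "quantified" is ambiguous; tallies report
both `n_quantified` (both channels measured) and
`n_quantified_incl_abolished`, and the cascade invariant
(detected ≥ quantified(+abolished) ≥ decreased ≥ abolished) is asserted on
the inclusive form.

A site-level decrease can be an artefact of the protein simply being less
abundant. The protein-abundance control divides the site ratio by the
protein ratio; a raw-decreased site whose normalized ratio no longer
clears $1/t$ is flagged `protein_explained`. Two open choices were
resolved as follows: the fold-change cut is applied to the **raw** ratio
and the normalization acts as a **flag** (raw-then-flag), not as the
primary statistic — this keeps the cascade interpretable and reports both
views; and sites on proteins without protein-level quantification are
**retained** unflagged, since discarding them would silently shrink the
methylome wherever proteome coverage is thinner than methylome coverage.

Enzyme classes determine the modality filter: a type I enzyme is profiled
with MMA+aDMA, type II with MMA+sDMA, and the sole type III enzyme with
MMA only. Duplicate site records (the same site recovered from several
enrichment experiments) are counted once; there is no replicate model —
inputs are one SILAC swap per perturbation.

## Sequence context

Windows of $2k+1$ residues (default $k = 5$, an 11-residue window) are
extracted around each methyl-arginine, padded with `-` at the termini;
a non-arginine center is a hard error because it always indicates a
coordinate-system bug (off-by-one, wrong isoform), never valid data.

Motif classes are defined on offsets within ±2 only: **GAR** if a glycine
is immediately adjacent (covering RG/RGG contexts), else **RXR** if an
arginine sits two residues away, else **other**. When both patterns
overlap (e.g. R-G-R), GAR wins. The precedence rule is this package's
decision: the two classes are reported as disjoint percentages, and the
glycine-adjacent signal is the dominant, more specific one.

Positional enrichment follows a sampling-logo scheme: `n_samples` random
sets of `sample_size` arginine-centered windows are drawn from the
proteome (arginine-anchored, because the foreground is), giving a
background mean and sd per (offset, residue) cell, hence
$Z = (f_{fg} - \bar f_{bg}) / s_{bg}$, a two-sided normal p-value and a
percent difference. Cells with $p < \alpha$ (default 0.01) are flagged.
When $s_{bg} = 0$ (e.g. the center cell, which is always R in both
foreground and background) the Z is 0 when the frequencies agree and a
±Inf sentinel otherwise. The sampling seed is recorded in the output
attributes.

## Phosphosite proximity and mutation enrichment

Proximity counts phosphosites within ±`w` residues of each methyl site
(`w` = 3 by default, 5 as the wider variant), excluding the site position
itself — an arginine cannot carry the phosphate. The null distribution
resamples `n_fg` arginine positions uniformly without replacement from
the proteome and recomputes the "≥1 phosphosite in window" fraction; the
empirical p-value uses the add-one correction
$(1 + \#\{bg \ge obs\}) / (1 + R)$ so it is never zero and stays valid
for small $R$.

Mutation rates collapse the mutation table to a binary "position mutated
at least once" (raw counts are kept for reporting only, so one recurrent
hotspot cannot dominate a rate). `at_site` mode considers the site
positions themselves; `vicinity` mode the union of ±`w` windows, center
included, deduplicated, clipped at protein termini. The window unit is
**amino acids** (default ±5): where source material mixes residue- and
nucleotide-unit phrasings for this window, the residue interpretation is
used and the width is an explicit parameter. Foreground positions are
removed from the background automatically so the 2×2 rows are disjoint.

Fisher's exact test is implemented directly as the conditional
hypergeometric sum: the two-sided p is the total probability of all
tables (margins fixed) whose point probability does not exceed the
observed one, with a relative tie-guard of $1 + 10^{-7}$ against
floating-point near-ties. The test suite checks it against full
enumeration of all 635,376 tables with total ≤ 60 (agreement ~1e-14) and
against `stats::fisher.test`. The odds ratio is the sample odds ratio
$ad/bc$, not the conditional MLE.

## Splicing

PSI uses effective-length normalization because the inputs are junction
counts: $\mathrm{PSI} = (n_i/l_i) / (n_i/l_i + n_s/l_s)$. With equal
effective lengths this reduces to the plain long-isoform share
$n_i/(n_i+n_s)$, asserted as a limit property in the tests. Events with
total coverage below `min_total` (default **10** reads per condition) are
"not testable" and excluded rather than called — a guard this package
adds, exposed as a parameter, because PSI from a handful of reads is
noise.

$\Delta\mathrm{PSI} = \mathrm{PSI}_{ctl} - \mathrm{PSI}_{kd}$; an event
is differential when $|\Delta\mathrm{PSI}| \ge 0.5$ (inclusive). The
direction names the change *induced by the knockdown*: EI when PSI rises
upon knockdown, ES when it falls. Cross-enzyme concordance requires a
common event universe across the compared experiments and errors with
the missing IDs otherwise — partitioning unions of differently filtered
universes would silently conflate "not regulated" with "not testable".

The FPKM filter keeps genes with
$\mathrm{FPKM} = n_{exon} / (L_{exon}/10^3) / (N_{total}/10^6) > 0.5$
in at least one condition, strictly.

The central-motif test is a simplified analogue of local motif-enrichment
scanning: all IUPAC-motif match starts are pooled, and the count falling
in a fixed central window (default 100 bp) is tested against the binomial
null $p_0 = $ window positions / usable positions. It tests *central
preference only* for a *given* window width — no window optimisation, no
motif database, no control-sequence mode.

## Set statistics

Overlap significance is the one-sided (enrichment) hypergeometric tail.
The universe must always be supplied explicitly; there is no silent
default, because overlap p-values are meaningless without a stated
universe. ORA runs one overlap test per GMT set (sets intersected with
the universe first) with Benjamini–Hochberg correction across sets.

## What the generator emulates — and what it does not

The generator's defaults define the study conditions used throughout the
tests: 600 proteins (gamma-distributed lengths, mean 400 residues, fixed
background amino-acid frequencies); three enzymes with 200 substrate
proteins each in a designed overlap of 60 shared-by-3, 30 per pair and 80
unique; 1–4 planted sites per substrate (37 % multi-site); a 60/20/20
GAR/RXR/other context mix (GAR planted as G-R-G-G, the context found
inside RGG repeats); true knockdown ratio 0.2 with log-normal noise of
sd 0.3 on the log2 ratio; 50 % of regulated sites fully abolished; a 10 %
protein-abundance confound; 600 unregulated background sites per table;
phosphosites at 5× density within ±3 of planted sites; mutations at 5×
density within ±5; and 480 splice events (200 null, 60 unique per
enzyme, 20 per pair, 40 shared) with |ΔPSI| = 0.7, one latent direction
per event, at depth 1000 reads with effective lengths 2:1. Each output
table draws from its own stream derived from the master seed by fixed
offsets, so regenerating one table never perturbs another, and the seed
is recorded in every table header.

Passing on these data shows that the statistics recover *planted* effects
at realistic effect sizes and depths and that the p-values are calibrated
under the generator's nulls. It does **not** show robustness to what the
generator omits: peptide-to-site localization ambiguity,
intensity-dependent missingness, correlated noise across sites of one
protein, replicate variance, compositional biases of real proteomes,
motif redundancy, linkage between splicing events, or annotation errors
in real mutation/phosphosite databases.

Problem sizes in the test suite (600-protein proteomes, 150–300
enrichment samples, 200-replicate calibrations with 199 resamples each,
depth-10^6 limit checks on one table) were chosen so the binomial and
resampling error bounds sit well inside the asserted tolerances.

## Numerical choices

* Fisher two-sided tie-guard $1+10^{-7}$ (relative), as above.
* Degenerate 2×2 margins: p = 1, odds ratio absent, with a warning.
* Zero-sd cells in positional enrichment: Z ∈ {0, ±Inf} sentinels.
* Empirical p-values use the add-one correction; never zero.
* PSI of a zero-coverage event is absent, not 0/0.
* Positions are 1-based residue coordinates throughout; window pads use
  `-` and are excluded from frequency denominators.
* All random stages take explicit seeds; the pipeline report contains no
  timestamps, so a rerun under one seed is byte-identical.

## Known limitations

Single SILAC swap per perturbation (no replicate averaging or variance
model); no peptide-level evidence handling; the central-motif test fixes
its window rather than optimising it; ORA ships no annotation content —
gene sets are the user's; and the generator's independence assumptions
make its calibration results a lower bound on what real, correlated data
would require.
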