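# methylomap

Integrative analysis of PRMT-regulated arginine methylomes in R.

Protein arginine methyltransferases (PRMTs) install mono- (MMA),
asymmetric di- (aDMA) and symmetric di-methyl (sDMA) marks on arginine
residues. Which proteins a given PRMT actually methylates can be read out
by quantitative proteomics: SILAC-label control (light) and
knockdown/inhibitor-treated (heavy) cells, enrich methylated peptides, and
compare channel intensities per site. `methylomap` implements the
downstream analysis of such experiments for users who have site-level
quantification tables in hand:

* **Substrate calling.** Per site, the heavy/light ratio
  *r* = I<sub>H</sub>/I<sub>L</sub> is classified against a fold-change
  threshold *t* (default 2): *decreased* if *r* ≤ 1/*t* (boundary
  inclusive), *abolished* if the heavy channel is absent while the light
  was detected, *increased* if *r* ≥ *t*. Decreases that disappear after
  dividing by the protein-abundance ratio are flagged as
  protein-explained and excluded from the methylome — the set of
  decreased-or-abolished sites and the proteins carrying them.
* **Sequence context.** 11-residue windows around each methyl-arginine
  are classified into GAR (glycine adjacent to the arginine) / RXR
  (arginine at ±2) / other, and position-specific residue enrichment is
  scored against randomly sampled arginine-centered proteome windows:
  *Z* = (f<sub>fg</sub> − mean<sub>bg</sub>)/sd<sub>bg</sub> per
  (offset, residue) cell.
* **Modification and mutation context.** Phosphosite counts within ±3
  (or ±5) residues of each methyl site, with an empirical null from
  resampled random arginines; somatic-mutation rates at or around methyl
  sites versus all proteome arginines, tested with a two-sided Fisher's
  exact test (exact hypergeometric point-probability sum).
* **Alternative splicing.** Percent spliced in from junction counts,
  PSI = (n<sub>inc</sub>/l<sub>inc</sub>) /
  (n<sub>inc</sub>/l<sub>inc</sub> + n<sub>skip</sub>/l<sub>skip</sub>);
  events with |ΔPSI| = |PSI<sub>ctl</sub> − PSI<sub>kd</sub>| ≥ 0.5 are
  called differential, with exon-inclusion/skipping direction relative to
  the knockdown, and shared events across several PRMTs are checked for
  direction concordance. A binomial central-enrichment test asks whether
  an RNA motif concentrates in the middle of upstream sequences.
* **Set statistics.** One-sided hypergeometric overlap tests with
  explicit universes, and GMT-based over-representation analysis with
  Benjamini–Hochberg correction.
* **Synthetic data.** A seeded generator plants substrates with a
  designed by-1/by-2/by-3 overlap across three enzymes, motif contexts,
  abolished sites, protein-abundance confounds, phospho/mutation hotspots
  and shared splicing effects — with the full ground truth recorded — so
  every stage can be validated end to end.

## Worked example

```r
library(methylomap)
cfg <- sim_config(seed = 1)          # three enzymes, 200 substrates each
sim <- simulate_all(cfg)             # all input tables + ground truth

m7 <- call_methylome(sim$methyl$PRMT7$sites, sim$methyl$PRMT7$proteins,
                     modalities = "MMA", prmt_label = "PRMT7")
m7
#> Methylome: PRMT7
#>    314 regulated sites on 200 proteins
#>   cascade: detected 1236 >= quantified(+abolished) 1236 >= decreased 345 >= abolished 147

round(motif_fractions(extract_windows(sim$proteome, m7$sites, k = 5)), 3)
#>   GAR   RXR other
#> 0.567 0.220 0.213

round(phospho_proximity(m7$sites, sim$phospho, w = 3)$bins, 3)
#>     0     1     2     3   >=4
#> 0.752 0.232 0.016 0.000 0.000

conc <- concordance_analysis(splice_calls(sim$splice_counts))
conc$n_by_class
#>   1   2   3
#> 180  60  40
conc$concordance_fraction
#> [1] 1
```

The cascade line reads: 1236 sites entered the table, all were
quantifiable, 345 dropped at least two-fold upon knockdown, 147 of those
lost the heavy channel entirely; after removing protein-explained
decreases, 314 sites on 200 proteins form the called methylome — exactly
the planted substrate set at this seed. The motif fractions recover the
planted 60/20/20 GAR/RXR/other mix; about 25 % of called sites have a
phosphosite within ±3 residues (phosphosites were planted at 5× density
near methyl sites); and the splicing stage recovers the designed
180/60/40 regulated-by-1/2/3 event classes, with all shared events moving
in the same direction.

`run_pipeline(cfg, outdir = "run")` executes all stages in order and
writes per-stage tables plus a byte-stable `report.json`. A thin shell
wrapper with subcommands (`simulate`, `call`, `motif`, `context`,
`splice`, `rna-motif`, `ora`, `report`) is installed at
`inst/scripts/methylomap`.

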