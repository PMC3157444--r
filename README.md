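# mycnet

Integrative reconstruction of a two-arm c-Myc regulatory network from
paired miRNA qPCR-array and mRNA microarray profiling of a knockdown
versus wild-type comparison.

c-Myc acts on its targets through two mechanisms: directly, by binding
E-box elements (CACGTG) in promoters together with Max, and indirectly,
by regulating miRNAs that repress their own targets. Given a log2 mRNA
probe matrix and a TaqMan low-density-array CT matrix for the two
conditions, this package rebuilds both arms and their overlap:

* **TaqMan preprocessing** — censoring of undetected wells and CT > 35
  to 35 cycles; per-sample normalization against U6
  (ΔC\_T = C\_T^miR − C\_T^U6, greater ΔC\_T = lower expression);
  detection filter min ΔC\_T < 10; per-cell copy numbers from the
  dilution calibration 10^((40 − C\_T)/3.34)/22.
* **Differential filtering** — per-feature two-group ANOVA (with two
  groups, F = t²), geometric fold change from log2 group means (sign
  inverted on ΔC\_T data), strict cut-offs |FC| > 2 and p < 0.05, and
  probe→gene collapsing with discordant-direction genes excluded.
* **Seed-match target prediction** — 8mer / 7mer-m8 / 7mer-A1 sites of
  the miRNA seed (positions 2–8) in 3'UTRs, at two stringencies (exact
  Watson–Crick, or additionally one G:U wobble), intersected with
  anti-correlated expression directions.
* **MATCH-style PWM scanning** — information-weighted matrix and core
  similarity scores normalized to [0, 1] (consensus = 1), an MSS cutoff
  calibrated to a per-window false-positive rate (exact enumeration for
  widths ≤ 8, seeded Monte-Carlo above), and both-strand scanning of
  promoter regions spanning 2 kb upstream of the TSS through the first
  exon, with TRANSFAC and JASPAR text parsers.
* **Enrichment** — one-sided hypergeometric tail P(X ≥ k), fold
  enrichment (k/n)/(K/N), reported at p < 0.05 and fold > 2 ranked by
  count (EASE-style penalized tail behind a flag).
* **Network assembly** — motif arm ∩ miRNA arm with evidence-carrying
  edge export (TSV + JSON).
* **Synthetic studies** — `generate_study()` produces a complete study
  with known planted truth (DE genes/miRNAs, promoter motif instances,
  UTR seed sites, one enriched gene set), with background sequence
  actively scrubbed of chance matches so the planted truth is exact.
  Every stage is testable without any external download.

## Worked example

```r
library(mycnet)
cfg   <- simulation_config(seed = 1, n_replicates_per_group = 3)
study <- generate_study(cfg)
res   <- run_pipeline(study)
res$network
#> Regulatory network: 12 motif-arm gene(s), 9 miRNA-arm gene(s), 4 overlapping
identical(res$network$motif_arm, study$truth$motif_arm)
#> [1] TRUE
```

The same run, decomposed into numbered stages that communicate through
plain-text files under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess_mirna.R
Rscript analysis/03_differential.R
Rscript analysis/04_targets.R
Rscript analysis/05_promoter_scan.R
Rscript analysis/06_enrichment.R
Rscript analysis/07_network.R
```

which prints, stage by stage:

```
detected 28 of 40 miRNAs (min dCT < 10)
most abundant: miR-030 (14,855.7 copies/cell)
42 significant probes -> 32 unique genes ( 16 up, 16 down )
8 significant miRNAs ( 6 up, 2 down )
largest miRNA fold change: miR-023 (11.3-fold up)
moderate: 16 anti-correlated pairs involving 9 unique genes
PWM 'EBOX_SYN' (consensus ACACGTGG), MSS cutoff 0.6904 at alpha 0.01
44 binding sites found in 12 of 32 significant gene promoters
all: 2 term(s) pass p<0.05 & fold>2; top: GS01 (count 12, fold 5.00, p 1.2e-08)
Regulatory network: 12 motif-arm gene(s), 9 miRNA-arm gene(s), 4 overlapping
overlap fraction of motif arm: 33.3%
matches planted truth: motif arm TRUE, miRNA arm TRUE, overlap TRUE
```

Here 28/40 miRNAs pass detection, 32 genes and 8 miRNAs pass the
differential cut-offs (exactly the planted sets), the calibrated scan
finds sites in exactly the 12 planted motif-arm promoters, the planted
gene set GS01 tops the enrichment report, and the assembled network
reproduces the planted arms and their 4-gene overlap exactly.

## The methods vignette

`vignettes/myc-network-reconstruction.Rmd` documents the models and
their assumptions, the generator's design (including why backgrounds
are scrubbed and why exact-recovery experiments use three replicates
per group), numerical conventions, and known limitations.
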