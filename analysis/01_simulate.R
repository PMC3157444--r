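#!/usr/bin/env Rscript

# Stage 1 — simulate the study.
#
# Generates a knockdown-vs-wild-type synthetic study with known planted
# truth (DE genes and miRNAs, promoter E-box instances, UTR seed sites, one
# enriched gene set) and writes it as plain-text files under results/study/.
# Every later stage works from those files only, the way a real analysis
# would start from deposited matrices and sequence files.

suppressPackageStartupMessages(library(mycnet))

seed <- as.integer(Sys.getenv("MYCNET_SEED", "1"))
cfg <- simulation_config(seed = seed, n_replicates_per_group = 3)
study <- generate_study(cfg)
write_study(study, "results/study")

tr <- study$truth
cat("study written to results/study (seed ", seed, ")\n", sep = "")
cat("  genes: ", cfg$n_genes, " (", length(tr$de_genes_up), " planted up, ",
    length(tr$de_genes_down), " planted down)\n", sep = "")
cat("  miRNAs: ", cfg$n_mirnas, " (", length(tr$de_mirnas_up), " up, ",
    length(tr$de_mirnas_down), " down, ",
    length(tr$undetected_mirnas), " undetected)\n", sep = "")
cat("  planted arms: motif ", length(tr$motif_arm), ", miRNA ",
    length(tr$mirna_arm), ", overlap ", length(tr$overlap), "\n", sep = "")
cat("  calibrated scan cutoff (MSS): ", round(tr$mss_cutoff, 4), "\n",
    sep = "")
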