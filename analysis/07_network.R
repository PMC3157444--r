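#!/usr/bin/env Rscript

# Stage 7 — two-arm network assembly.
#
# Joins the transcriptional arm (significant genes with at least one
# promoter motif hit) and the post-transcriptional arm (anti-correlated
# miRNA targets, moderate stringency) into the final regulatory network,
# exports it, and checks the reconstruction against the planted truth.

suppressPackageStartupMessages(library(mycnet))

de_genes <- read.delim("results/de_genes.tsv", stringsAsFactors = FALSE)
hits <- read.delim("results/motif_hits.tsv", stringsAsFactors = FALSE)
pair_rows <- read.delim("results/pairs_moderate.tsv",
                        stringsAsFactors = FALSE)
pair_set <- list(pairs = pair_rows, genes = sort(unique(pair_rows$gene)))

net <- assemble_network(de_genes, hits, pair_set)
export_network(net, "results/network")
print(net)
cat("overlap fraction of motif arm: ",
    round(net$summary$overlap_fraction_of_motif_arm * 100, 1), "%\n",
    sep = "")

truth <- jsonlite::read_json("results/study/truth.json",
                             simplifyVector = TRUE)
cat("matches planted truth: motif arm ",
    identical(net$motif_arm, truth$motif_arm),
    ", miRNA arm ", identical(net$mirna_arm, truth$mirna_arm),
    ", overlap ", identical(sort(net$overlap), truth$overlap), "\n",
    sep = "")
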