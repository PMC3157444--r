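#!/usr/bin/env Rscript

# Stage 4 — miRNA target mapping.
#
# Predicts seed-match sites of the significant miRNAs in the significant
# genes' 3'UTRs at both stringencies (stringent = exact 8mer/7mer seed
# pairing, moderate = additionally one G:U wobble) and intersects the
# predictions with anti-correlated expression: upregulated miRNAs paired
# with downregulated targets and vice versa. The two stringencies mirror
# the TargetScan-vs-miRanda sensitivity contrast.

suppressPackageStartupMessages(library(mycnet))

mirnas <- read_seqs_fasta("results/study/mirnas.fa", alphabet = "rna")
utrs <- read_seqs_fasta("results/study/utrs.fa", alphabet = "dna")
de_genes <- read.delim("results/de_genes.tsv", stringsAsFactors = FALSE)
de_mirnas <- read.delim("results/de_mirnas.tsv", stringsAsFactors = FALSE)
sig_mi <- de_mirnas[de_mirnas$passes, ]

mi_up <- sig_mi$feature[sig_mi$direction == "up"]
mi_down <- sig_mi$feature[sig_mi$direction == "down"]
g_up <- de_genes$gene[de_genes$direction == "up"]
g_down <- de_genes$gene[de_genes$direction == "down"]

for (mode in c("stringent", "moderate")) {
  preds <- predict_targets(mirnas[sig_mi$feature],
                           utrs[intersect(names(utrs), de_genes$gene)],
                           mode = mode)
  pairs <- anticorrelated_pairs(mi_up, mi_down, g_up, g_down, preds)
  write.table(preds, sprintf("results/predictions_%s.tsv", mode),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pairs$pairs, sprintf("results/pairs_%s.tsv", mode),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(mode, ": ", nrow(pairs$pairs), " anti-correlated pairs involving ",
      length(pairs$genes), " unique genes\n", sep = "")
}
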