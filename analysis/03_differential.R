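#!/usr/bin/env Rscript

# Stage 3 — two-group differential filtering.
#
# mRNA probes: background elimination, per-probe ANOVA + geometric fold
# change, |FC| > 2 and p < 0.05 cut-offs, then collapsing of significant
# probes to unique genes (discordant-direction genes excluded). miRNAs:
# the same test on the detected dCT matrix with the inverted sign
# convention (greater dCT = lower expression).

suppressPackageStartupMessages(library(mycnet))

design <- read_design_tsv("results/study/design.tsv")

## mRNA branch
expr <- read_matrix_tsv("results/study/mrna_matrix.tsv")
expr <- background_filter(expr)
mrna_de <- differential_test(expr, design[colnames(expr)],
                             reference = "wt", kind = "mrna")
mrna_sets <- apply_thresholds(mrna_de, fc_cutoff = 2, p_cutoff = 0.05)
probe2gene <- read.delim("results/study/probe2gene.tsv",
                         stringsAsFactors = FALSE)
collapsed <- collapse_probes_to_genes(mrna_sets$significant, probe2gene)

write.table(mrna_sets$table, "results/de_mrna_probes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(collapsed$genes, "results/de_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## miRNA branch
dct <- read_matrix_tsv("results/mirna_dct_detected.tsv")
mirna_de <- differential_test(dct, design[colnames(dct)],
                              reference = "wt", kind = "mirna")
mirna_sets <- apply_thresholds(mirna_de, fc_cutoff = 2, p_cutoff = 0.05)
write.table(mirna_sets$table, "results/de_mirnas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(nrow(mrna_sets$significant), "significant probes ->",
    nrow(collapsed$genes), "unique genes (",
    sum(collapsed$genes$direction == "up"), "up,",
    sum(collapsed$genes$direction == "down"), "down )\n")
if (length(collapsed$discordant)) {
  cat("excluded discordant gene(s):",
      paste(collapsed$discordant, collapse = ", "), "\n")
}
cat(length(mirna_sets$up) + length(mirna_sets$down),
    "significant miRNAs (", length(mirna_sets$up), "up,",
    length(mirna_sets$down), "down )\n")
top <- mirna_sets$significant[order(-mirna_sets$significant$fold_change), ]
if (nrow(top)) {
  cat("largest miRNA fold change:", top$feature[1],
      sprintf("(%.1f-fold %s)\n", top$fold_change[1], top$direction[1]))
}
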