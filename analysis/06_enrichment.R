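#!/usr/bin/env Rscript

# Stage 6 — gene-set over-representation.
#
# Hypergeometric enrichment of the up- and down-regulated gene lists (and
# the combined list) against the full gene universe, reported with the
# p < 0.05 / fold > 2 filter, ranked by count.

suppressPackageStartupMessages(library(mycnet))

genesets <- read_gmt("results/study/genesets.gmt")
probe2gene <- read.delim("results/study/probe2gene.tsv",
                         stringsAsFactors = FALSE)
universe <- unique(probe2gene$gene)
de_genes <- read.delim("results/de_genes.tsv", stringsAsFactors = FALSE)

report <- function(lst, label) {
  if (!length(lst)) return(invisible(NULL))
  ranked <- filter_and_rank(fisher_enrichment(lst, universe, genesets))
  write.table(ranked, sprintf("results/enrichment_%s.tsv", label),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(label, ": ", nrow(ranked), " term(s) pass p<0.05 & fold>2",
      if (nrow(ranked)) sprintf("; top: %s (count %d, fold %.2f, p %.2g)",
                                ranked$term[1], ranked$count[1],
                                ranked$fold_enrichment[1],
                                ranked$p_value[1]),
      "\n", sep = "")
  ranked
}

report(de_genes$gene[de_genes$direction == "up"], "up")
report(de_genes$gene[de_genes$direction == "down"], "down")
report(de_genes$gene, "all")
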