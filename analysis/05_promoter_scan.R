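#!/usr/bin/env Rscript

# Stage 5 — promoter motif scan.
#
# Builds the PWM from the study's TRANSFAC count matrix, calibrates the
# matrix-similarity cutoff so the per-window false-positive rate on i.i.d.
# background is 0.01 (exact enumeration for this matrix width), and scans
# the promoters (2 kb upstream of the TSS through the first exon, both
# strands) of every significant gene.

suppressPackageStartupMessages(library(mycnet))

mat <- read_transfac("results/study/pwm.transfac")[[1]]
pwm <- build_pwm(mat$counts, id = mat$id)
de_genes <- read.delim("results/de_genes.tsv", stringsAsFactors = FALSE)
proms <- read_promoters_fasta("results/study/promoters.fa")
regions <- proms[proms$gene %in% de_genes$gene, ]

mss_cutoff <- calibrate_threshold(pwm, alpha = 0.01)
scan <- scan_promoters(pwm, regions, mss_cutoff, css_cutoff = 0.75)

write.table(scan$hits, "results/motif_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_hits_bed(scan$hits, "results/motif_hits.bed")

cat("PWM '", pwm$id, "' (consensus ", pwm_consensus(pwm),
    "), MSS cutoff ", round(mss_cutoff, 4), " at alpha 0.01\n", sep = "")
cat(scan$summary$n_sites, " binding sites found in ",
    scan$summary$n_genes, " of ", nrow(regions),
    " significant gene promoters\n", sep = "")
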