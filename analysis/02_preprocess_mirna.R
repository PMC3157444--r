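#!/usr/bin/env Rscript

# Stage 2 — TaqMan array preprocessing.
#
# Censors undetected wells and CT > 35 to 35 cycles, normalizes each miRNA
# against the U6 control (dCT), applies the min-dCT < 10 detection filter,
# and estimates per-cell copy numbers from the censored raw CT.

suppressPackageStartupMessages(library(mycnet))

ct_raw <- read_ct_tsv("results/study/mirna_ct.tsv")
ct <- censor_ct(ct_raw)
dct <- normalize_delta_ct(ct, control_id = "U6")
detected <- detection_filter(dct, cutoff = 10)

write_matrix_tsv(detected, "results/mirna_dct_detected.tsv", id_col = "mirna")

# copy-per-cell estimates from the mean censored raw CT of detected miRNAs
mean_ct <- rowMeans(ct[rownames(detected), , drop = FALSE])
copies <- data.frame(mirna = names(mean_ct),
                     mean_ct = round(mean_ct, 3),
                     copies_per_cell = round(copy_number(mean_ct), 1))
copies <- copies[order(-copies$copies_per_cell), ]
write.table(copies, "results/mirna_copy_number.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("detected ", attr(detected, "n_detected"), " of ",
    nrow(ct_raw) - 1L, " miRNAs (min dCT < 10)\n", sep = "")
cat("most abundant: ", copies$mirna[1], " (",
    format(copies$copies_per_cell[1], big.mark = ","),
    " copies/cell)\n", sep = "")
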