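test_that("configuration invariants are validated", {
  expect_s3_class(small_config(), "simulation_config")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(frac_de_genes_up = 0.7,
                                 frac_de_genes_down = 0.6))
  expect_error(simulation_config(n_overlap = 10, n_motif_arm = 4,
                                 n_mirna_arm = 12))
  # more arm genes than planted DE genes
  expect_error(simulation_config(n_genes = 50, frac_de_genes_up = 0.05,
                                 frac_de_genes_down = 0.05,
                                 n_motif_arm = 12, n_mirna_arm = 9,
                                 n_overlap = 4), "DE genes")
  # a miRNA arm with no DE miRNAs is impossible
  expect_error(simulation_config(frac_de_mirnas_up = 0,
                                 frac_de_mirnas_down = 0), "DE miRNAs")
})

test_that("a fixed seed reproduces the study bit for bit", {
  a <- generate_study(small_config(seed = 5))
  b <- generate_study(small_config(seed = 5))
  expect_identical(a, b)
  c <- generate_study(small_config(seed = 6))
  expect_false(identical(a$mrna_matrix, c$mrna_matrix))
})

test_that("nothing is planted when the DE fractions are zero", {
  cfg <- simulation_config(
    n_genes = 40, n_mirnas = 10,
    frac_de_genes_up = 0, frac_de_genes_down = 0,
    frac_de_mirnas_up = 0.2, frac_de_mirnas_down = 0.1,
    n_motif_arm = 0, n_mirna_arm = 0, n_overlap = 0,
    promoter_len_upstream = 200, first_exon_len = 80, utr_len = 150,
    seed = 2)
  st <- generate_study(cfg)
  expect_length(st$truth$de_genes_up, 0)
  expect_length(st$truth$de_genes_down, 0)
  expect_length(st$truth$motif_arm, 0)
  expect_null(st$truth$motif_sites)
})

test_that("planted structure matches the study invariants", {
  st <- generate_study(small_config(seed = 7))
  tr <- st$truth
  # planted identifiers exist in the matrices
  all_genes <- unique(st$probe2gene$gene)
  expect_true(all(c(tr$de_genes_up, tr$de_genes_down) %in% all_genes))
  expect_true(all(c(tr$de_mirnas_up, tr$de_mirnas_down) %in%
                    rownames(st$mirna_ct)))
  expect_true("U6" %in% rownames(st$mirna_ct))
  # censored CT never exceeds 35
  expect_true(all(st$mirna_ct <= 35))
  # every planted motif lies inside its promoter scan span
  L <- ncol(st$pwm_counts)
  for (i in seq_len(nrow(tr$motif_sites))) {
    s <- tr$motif_sites[i, ]
    reg <- st$promoters[st$promoters$gene == s$gene, ]
    expect_gte(s$start + reg$tss_offset, 0)
    expect_lte(s$start + reg$tss_offset + L, reg$exon_end)
  }
  # every planted seed site lies inside its UTR
  for (i in seq_len(nrow(tr$mirna_sites))) {
    s <- tr$mirna_sites[i, ]
    expect_gte(s$start, 0)
    expect_lte(s$start + 8, nchar(st$utrs[[s$gene]]))
  }
  # arm sets agree with the configured sizes and overlap relation
  expect_length(tr$motif_arm, 3)
  expect_length(tr$mirna_arm, 3)
  expect_identical(sort(intersect(tr$motif_arm, tr$mirna_arm)), tr$overlap)
})

test_that("planted mRNA effects have the configured mean log2 difference", {
  cfg <- small_config(seed = 8)
  st <- generate_study(cfg)
  wt <- st$design == "wt"
  up_probes <- st$probe2gene$probe[st$probe2gene$gene %in%
                                     st$truth$de_genes_up]
  d <- rowMeans(st$mrna_matrix[up_probes, !wt, drop = FALSE]) -
       rowMeans(st$mrna_matrix[up_probes, wt, drop = FALSE])
  n <- sum(!wt)
  expect_lt(abs(mean(d) - cfg$mrna_effect_log2),
            3 * cfg$mrna_noise_sd / sqrt(n))
  # planted 8mer words are present at the recorded positions
  for (i in seq_len(nrow(st$truth$mirna_sites))) {
    s <- st$truth$mirna_sites[i, ]
    word <- seed_words(st$mirna_seqs[[s$mirna]])$eightmer
    expect_equal(substr(st$utrs[[s$gene]], s$start + 1, s$start + 8), word)
  }
})

test_that("the planted enriched term leads the combined DE list by count", {
  first <- logical(5)
  for (i in 1:5) {
    st <- generate_study(small_config(seed = 100 + i))
    de <- c(st$truth$de_genes_up, st$truth$de_genes_down)
    res <- fisher_enrichment(de, unique(st$probe2gene$gene), st$genesets)
    ranked <- filter_and_rank(res)
    first[i] <- nrow(ranked) > 0 &&
      ranked$term[1] == st$truth$enriched_term &&
      ranked$p_value[1] < 0.05
  }
  expect_true(all(first))
})

test_that("a written study round-trips through the readers", {
  st <- generate_study(small_config(seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  back <- read_study(dir)
  expect_equal(back$mrna_matrix, st$mrna_matrix, tolerance = 1e-8)
  expect_equal(back$mirna_ct_raw, st$mirna_ct_raw, tolerance = 1e-8)
  expect_identical(back$design, st$design)
  expect_identical(back$utrs, st$utrs)
  expect_identical(back$mirna_seqs, st$mirna_seqs)
  expect_identical(back$promoters$seq, st$promoters$seq)
  expect_identical(back$promoters$tss_offset, st$promoters$tss_offset)
  expect_identical(unclass(back$genesets)[seq_along(st$genesets)],
                   unname(as.list(st$genesets)), ignore_attr = TRUE)
  expect_equal(back$pwm_counts, st$pwm_counts, ignore_attr = TRUE)
  expect_equal(back$truth$motif_arm, st$truth$motif_arm)
  # format contracts
  headers <- grep("^>", readLines(file.path(dir, "promoters.fa")),
                  value = TRUE)
  expect_true(all(grepl("^>g[0-9]+\\|[0-9]+\\|[0-9]+$", headers)))
  expect_equal(length(readLines(file.path(dir, "genesets.gmt"))),
               length(st$genesets))
})
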