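# let-7a: seed (positions 2-8) is GAGGUAG, so the canonical site words are
# CTACCTCA (8mer), CTACCTC (7mer-m8), TACCTCA (7mer-A1)
LET7 <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("canonical site words and their classification are correct", {
  w <- seed_words(LET7)
  expect_equal(w$eightmer, "CTACCTCA")
  expect_equal(w$m8, "CTACCTC")
  expect_equal(w$a1, "TACCTCA")
  utr <- paste0("GGGG", "CTACCTCA", "GGGG")
  hits <- predict_targets_stringent("let-7a", LET7, "g1", utr)
  expect_equal(nrow(hits), 1)               # one 8mer, subsumed 7mers absent
  expect_equal(hits$site_type, "8mer")
  expect_equal(hits$start, 4)
  expect_equal(hits$end, 12)
  # one 7mer-m8 (next base not A) and one 7mer-A1 in the same UTR
  utr2 <- paste0("GG", "CTACCTCG", "GGGG", "TACCTCA", "GG")
  hits2 <- predict_targets_stringent("let-7a", LET7, "g1", utr2)
  expect_setequal(hits2$site_type, c("7mer-m8", "7mer-A1"))
  # no seed complement -> empty
  expect_equal(nrow(predict_targets_stringent("let-7a", LET7, "g1",
                                              strrep("G", 50))), 0)
})

test_that("moderate mode adds single-wobble sites and nothing else", {
  # CTACCTT pairs seed position 8 (G) against T: one G:U wobble
  utr <- paste0("AAAA", "CTACCTT", "AAAA")
  s <- predict_targets_stringent("let-7a", LET7, "g1", utr)
  m <- predict_targets_moderate("let-7a", LET7, "g1", utr)
  # stringent sees only the chance 7mer-A1 made by the trailing As, if any;
  # the wobble word itself is invisible to it
  expect_false("wobble-7mer" %in% s$site_type)
  expect_true("wobble-7mer" %in% m$site_type)
  expect_equal(m$start[m$site_type == "wobble-7mer"], 4)
  # a non-wobble mismatch (A->C pairing impossible) is absent in both
  utr_bad <- paste0("AAAA", "CAACCTC", "AAAA")
  expect_false(4 %in% predict_targets_stringent("x", LET7, "g", utr_bad)$start)
  expect_false(4 %in% predict_targets_moderate("x", LET7, "g", utr_bad)$start)
  # N never matches
  expect_equal(nrow(predict_targets_moderate("x", LET7, "g",
                                             "AANACTACCTNAAA")), 0)
  expect_error(predict_targets_stringent("x", LET7, "g", "ACGTX"), "ACGTN")
  expect_error(predict_targets_stringent("x", "UGAGGXAGUA", "g", "ACGT"),
               "invalid miRNA")
})

test_that("predictions equal a brute-force pairing oracle on random pairs", {
  set.seed(51)
  for (rep in 1:25) {
    mature <- random_rna(22)
    utr <- random_dna(300)
    for (mode in c("stringent", "moderate")) {
      got <- if (mode == "stringent") {
        predict_targets_stringent("m", mature, "g", utr)
      } else {
        predict_targets_moderate("m", mature, "g", utr)
      }
      want <- brute_seed_sites(mature, utr, wobble_allowed = mode == "moderate")
      expect_equal(got[, c("start", "site_type")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("stringent predictions are a subset of moderate predictions", {
  set.seed(52)
  for (rep in 1:100) {
    mature <- random_rna(21)
    utr <- random_dna(150)
    s <- predict_targets_stringent("m", mature, "g", utr)
    m <- predict_targets_moderate("m", mature, "g", utr)
    key_s <- paste(s$start, s$site_type)
    key_m <- paste(m$start, m$site_type)
    expect_true(all(key_s %in% key_m))
  }
})

test_that("anti-correlated pairing keeps only opposite-direction pairs", {
  preds <- data.frame(
    mirna = c("m1", "m1", "m1", "m2", "m3"),
    gene = c("g1", "g1", "g2", "g3", "g1"),
    start = c(5, 40, 7, 9, 11), end = c(13, 48, 14, 17, 18),
    site_type = c("8mer", "7mer-m8", "8mer", "8mer", "8mer"),
    mode = "stringent")
  out <- anticorrelated_pairs(
    mirna_up = c("m1"), mirna_down = c("m2"),
    gene_up = c("g2", "g3"), gene_down = c("g1"),
    predictions = preds)
  # m1(up)-g1(down): kept with 2 supporting sites; m1-g2 same direction:
  # dropped; m2(down)-g3(up): kept; m3 not significant: dropped
  expect_equal(nrow(out$pairs), 2)
  expect_equal(out$pairs$n_sites[out$pairs$mirna == "m1"], 2)
  expect_equal(out$genes, c("g1", "g3"))
  expect_equal(out$mirna_counts, c(m1 = 1L, m2 = 1L))
})

test_that("pair set equals the brute-force double loop and ignores ordering", {
  set.seed(53)
  mirnas <- paste0("m", 1:10)
  genes <- paste0("g", 1:10)
  preds <- data.frame(
    mirna = sample(mirnas, 40, replace = TRUE),
    gene = sample(genes, 40, replace = TRUE),
    start = sample(0:90, 40, replace = TRUE))
  preds$end <- preds$start + 8
  preds$site_type <- "8mer"
  preds$mode <- "stringent"
  mi_up <- c("m1", "m2", "m3"); mi_down <- c("m4", "m5")
  g_up <- c("g1", "g2"); g_down <- c("g3", "g4", "g5")
  out <- anticorrelated_pairs(mi_up, mi_down, g_up, g_down, preds)
  brute <- character(0)
  for (m in mirnas) for (g in genes) {
    targeted <- any(preds$mirna == m & preds$gene == g)
    if (targeted && ((m %in% mi_up && g %in% g_down) ||
                     (m %in% mi_down && g %in% g_up))) {
      brute <- c(brute, paste(m, g))
    }
  }
  expect_setequal(paste(out$pairs$mirna, out$pairs$gene), brute)
  expect_true(length(out$genes) <= nrow(out$pairs))
  # shuffling the prediction rows changes nothing
  out2 <- anticorrelated_pairs(mi_up, mi_down, g_up, g_down,
                               preds[sample(nrow(preds)), ])
  expect_equal(out2$pairs, out$pairs)
})
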