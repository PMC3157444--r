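# non-palindromic 7-position test matrix
TEST_CONS <- "TTGACAC"

test_that("information vector and core follow the closed forms", {
  counts <- matrix(c(5, 5, 5, 5), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  p <- build_pwm(counts, pseudocount = 0)
  expect_equal(p$info, 0)                       # uniform column
  counts2 <- matrix(c(12, 0, 0, 0), 4, 1,
                    dimnames = list(c("A", "C", "G", "T")))
  p2 <- build_pwm(counts2, pseudocount = 0)
  expect_equal(p2$info, log(4))                 # single-base column
  expect_error(build_pwm(matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"))),
                         pseudocount = 0), "all-zero")
  # core of a 10-position matrix equals the brute-force best window
  set.seed(61)
  counts3 <- matrix(rpois(40, 12), 4, 10,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  p3 <- build_pwm(counts3)
  expect_equal(p3$core, brute_core(brute_freq(counts3)))
  expect_length(p3$core, 5)
  expect_equal(unname(colSums(p3$freq)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(p3$info >= 0))
})

test_that("matrix and core similarity match direct formula evaluation", {
  counts <- counts_from_consensus(TEST_CONS)
  p <- build_pwm(counts)
  expect_equal(matrix_similarity(p, TEST_CONS), 1)
  expect_equal(core_similarity(p, TEST_CONS), 1)
  # anti-consensus scores zero: per-position least frequent base; with a
  # single dominant base, any non-consensus base attains the minimum
  anti <- chartr("ACGT", "CATG", TEST_CONS)
  expect_equal(matrix_similarity(p, anti), 0)
  # hand-built 3-position matrix against an independent evaluation
  counts3 <- matrix(c(8, 2, 1, 1,
                      1, 9, 1, 1,
                      3, 3, 5, 1), 4, 3,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  p3 <- build_pwm(counts3)
  expect_equal(matrix_similarity(p3, "ACG"),
               brute_similarity(counts3, "ACG"), tolerance = 1e-12)
  expect_equal(matrix_similarity(p3, "TTT"),
               brute_similarity(counts3, "TTT"), tolerance = 1e-12)
  # random words, full and core-restricted, against the oracle
  set.seed(62)
  for (i in 1:20) {
    w <- random_dna(7)
    expect_equal(matrix_similarity(p, w), brute_similarity(counts, w),
                 tolerance = 1e-12)
    expect_equal(core_similarity(p, w),
                 brute_similarity(counts, w, positions = p$core),
                 tolerance = 1e-12)
    expect_true(matrix_similarity(p, w) >= 0 && matrix_similarity(p, w) <= 1)
  }
  # a word correct only on the core: core = 1, matrix < 1
  ch <- strsplit(TEST_CONS, "")[[1]]
  off_core <- setdiff(1:7, p$core)
  for (i in off_core) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  w_core <- paste(ch, collapse = "")
  expect_equal(core_similarity(p, w_core), 1)
  expect_lt(matrix_similarity(p, w_core), 1)
  expect_error(matrix_similarity(p, "ACGT"), "length")
})

test_that("threshold calibration matches exact enumeration and is monotone", {
  counts <- matrix(c(10, 2, 2, 2,
                     2, 12, 1, 1,
                     1, 1, 9, 3,
                     5, 5, 5, 1), 4, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- build_pwm(counts)
  expect_equal(calibrate_threshold(p, alpha = 1), 0)
  exact <- calibrate_threshold(p, alpha = 0.05, method = "exact")
  # exact cutoff has exceedance <= alpha, next level down exceeds it
  enum <- expand.grid(rep(list(c("A", "C", "G", "T")), 4))
  scores <- apply(enum, 1, function(r) {
    brute_similarity(counts, paste(r, collapse = ""))
  })
  expect_lte(mean(scores >= exact), 0.05)
  levels_ <- sort(unique(round(scores, 12)))
  below <- levels_[levels_ < exact - 1e-9]
  if (length(below)) expect_gt(mean(scores >= max(below) - 1e-9), 0.05)
  # Monte-Carlo lands within one grid step of the exact cutoff
  mc <- calibrate_threshold(p, alpha = 0.05, method = "mc",
                            n_samples = 50000, seed = 7)
  i_exact <- which.min(abs(levels_ - exact))
  neighbors <- levels_[max(1, i_exact - 1):min(length(levels_), i_exact + 1)]
  expect_true(any(abs(neighbors - mc) < 1e-9))
  # monotone nonincreasing in alpha
  alphas <- c(0.001, 0.01, 0.05, 0.2, 0.8)
  cuts <- vapply(alphas, function(a) {
    # small alphas may be unattainable for this weak matrix: cutoff 1
    suppressWarnings(calibrate_threshold(p, alpha = a, method = "exact"))
  }, numeric(1))
  expect_true(all(diff(cuts) <= 0))
  expect_error(calibrate_threshold(p, alpha = 1e-4, method = "mc",
                                   n_samples = 1000), "n_samples")
})

test_that("scanning finds planted instances with strand-mirrored coordinates", {
  set.seed(63)
  counts <- counts_from_consensus(TEST_CONS)
  p <- build_pwm(counts)
  bg <- random_dna(600)
  # plant the consensus on the sense strand 150 bases upstream of the TSS
  seq1 <- bg
  substr(seq1, 500 - 150 + 1, 500 - 150 + 7) <- TEST_CONS
  reg1 <- promoter_region("gA", seq1, tss_offset = 500)
  hits1 <- scan_region(p, reg1, mss_cutoff = 0.95, css_cutoff = 0.9)
  expect_equal(nrow(hits1), 1)
  expect_equal(hits1$start, -150)
  expect_equal(hits1$strand, "+")
  expect_equal(hits1$matrix_score, 1)
  # the reverse complement planted at the same sense span: minus-strand hit
  seq2 <- bg
  substr(seq2, 500 - 150 + 1, 500 - 150 + 7) <- revcomp(TEST_CONS)
  hits2 <- scan_region(p, promoter_region("gA", seq2, 500),
                       mss_cutoff = 0.95, css_cutoff = 0.9)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$start, -150)
  expect_equal(hits2$strand, "-")
  # region shorter than the matrix: empty, not an error
  expect_equal(nrow(scan_region(p, promoter_region("gB", "ACGT", 0, 4),
                                0.5, 0.5)), 0)
})

test_that("hit lists equal the brute-force all-window both-strand oracle", {
  set.seed(64)
  counts <- counts_from_consensus(TEST_CONS, major = 40)  # permissive matrix
  p <- build_pwm(counts)
  n_hits <- 0
  for (rep in 1:5) {
    seq <- random_dna(500)
    reg <- promoter_region(paste0("g", rep), seq, tss_offset = 0)
    got <- scan_region(p, reg, mss_cutoff = 0.75, css_cutoff = 0.7)
    want <- brute_scan(counts, seq, 0.75, 0.7)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$matrix_score, want$matrix_score, tolerance = 1e-12)
    expect_equal(got$core_score, want$core_score, tolerance = 1e-12)
    n_hits <- n_hits + nrow(got)
  }
  expect_gt(n_hits, 0)
})

test_that("scanning a sequence and its reverse complement mirror each other", {
  set.seed(65)
  p <- build_pwm(counts_from_consensus(TEST_CONS, major = 40))
  seq <- random_dna(400)
  substr(seq, 101, 107) <- TEST_CONS
  n <- nchar(seq)
  a <- scan_region(p, promoter_region("g", seq, 0), 0.75, 0.7)
  b <- scan_region(p, promoter_region("g", revcomp(seq), 0), 0.75, 0.7)
  expect_gt(nrow(a), 0)
  expect_equal(nrow(a), nrow(b))
  key_a <- paste(a$start, a$strand, round(a$matrix_score, 10))
  key_b <- paste(n - b$start - p$width, chartr("+-", "-+", b$strand),
                 round(b$matrix_score, 10))
  expect_setequal(key_a, key_b)
})

test_that("promoter-set scanning counts sites and genes separately", {
  set.seed(66)
  p <- build_pwm(counts_from_consensus(TEST_CONS))
  mk <- function(g, n_planted) {
    s <- random_dna(300)
    starts <- c(40, 160)[seq_len(n_planted)]
    for (st in starts) substr(s, st + 1, st + 7) <- TEST_CONS
    promoter_region(g, s, tss_offset = 200)
  }
  regions <- rbind(mk("g1", 1), mk("g2", 2), mk("g3", 0))
  out <- scan_promoters(p, regions, mss_cutoff = 0.95, css_cutoff = 0.9)
  expect_equal(out$summary$n_sites, 3)        # g2 counted twice in sites
  expect_equal(out$summary$n_genes, 2)        # but once in the gene tally
  expect_setequal(out$summary$genes, c("g1", "g2"))
  # summary equals a recount from the emitted hit table
  expect_equal(out$summary$n_sites, nrow(out$hits))
  expect_equal(out$summary$n_genes, length(unique(out$hits$gene)))
  expect_error(scan_promoters(p, rbind(regions, mk("g1", 0)), 0.9, 0.9),
               "duplicate")
})

test_that("promoter region bounds are validated", {
  expect_error(promoter_region("g", "ACGTACGT", 8), "tss_offset")
  expect_error(promoter_region("g", "ACGTACGT", 2, 12), "tss_offset")
  expect_error(promoter_region("g", strrep("A", 2500), 2200), "2000")
})
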