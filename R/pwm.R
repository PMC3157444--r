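#' MATCH-style position weight matrix scanning
#'
#' Promoter motif search follows the MATCH scheme: a position frequency
#' matrix is weighted by its per-position information content
#' `I(i) = sum_b f(i,b) * ln(4 f(i,b))` (natural log), and a candidate word
#' is scored by the normalized similarity
#' `MSS = (Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) f(i, word_i)` and Min/Max use the least/most
#' frequent base per position. The core similarity score (CSS) applies the
#' same formula restricted to the five consecutive positions of highest
#' summed information. Both scores live in `[0, 1]`; the consensus word
#' scores exactly 1. Thresholds are calibrated empirically against an
#' i.i.d. background so that the per-window false-positive rate is a chosen
#' alpha.
#'
#' @name pwm_scan
NULL

.BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Converts a count matrix into a pseudocount-adjusted frequency matrix with
#' its information vector, core positions, and per-position extreme
#' contributions.
#'
#' @param counts Nonnegative base x position count matrix: either 4 x L with
#'   rownames A/C/G/T or L x 4 with colnames A/C/G/T.
#' @param id Matrix identifier.
#' @param pseudocount Added to every cell before normalization (default
#'   0.25 per base). With `pseudocount = 0`, an all-zero column is an error.
#' @return Object of class `"pwm"`: list with `id`, `width`, `freq` (4 x L,
#'   columns sum to 1), `info` (length L), `core` (indices of the
#'   `min(5, L)` consecutive positions maximizing summed information),
#'   `contrib` (`info * freq`), `min_w`, `max_w`.
#' @export
build_pwm <- function(counts, id = "pwm", pseudocount = 0.25) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (ncol(counts) == 4 && !is.null(colnames(counts)) &&
      all(.BASES %in% colnames(counts)) && nrow(counts) != 4) {
    counts <- t(counts[, .BASES, drop = FALSE])
  }
  if (nrow(counts) != 4) stop("counts must have 4 base rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- .BASES
  counts <- counts[.BASES, , drop = FALSE]
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (pseudocount == 0 && any(colSums(counts) == 0)) {
    stop("all-zero column with pseudocount = 0")
  }
  adj <- counts + pseudocount
  freq <- sweep(adj, 2, colSums(adj), "/")
  L <- ncol(freq)
  # information vector, 0 * ln(0) treated as 0
  terms <- freq * log(4 * freq)
  terms[freq == 0] <- 0
  info <- colSums(terms)
  w <- min(5L, L)
  win_sums <- vapply(seq_len(L - w + 1L),
                     function(s) sum(info[s:(s + w - 1L)]), numeric(1))
  s0 <- which.max(win_sums)
  core <- s0:(s0 + w - 1L)
  contrib <- sweep(freq, 2, info, "*")
  structure(list(
    id = id, width = L, freq = freq, info = info, core = core,
    contrib = contrib,
    min_w = apply(contrib, 2, min),
    max_w = apply(contrib, 2, max)
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$id, "': ", x$width, " positions, consensus ",
      pwm_consensus(x), ", core ", x$core[1], "-", x$core[length(x$core)],
      "\n", sep = "")
  invisible(x)
}

#' Consensus word of a PWM
#'
#' The per-position most frequent base (ties broken in A<C<G<T order).
#' @param pwm A `"pwm"` object.
#' @return Character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(.BASES[apply(pwm$freq, 2, which.max)], collapse = "")
}

.encode_dna <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], c(.BASES, "N"))
  if (anyNA(idx)) stop("sequence contains characters outside ACGTN")
  idx
}

.revcomp_chr <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(seq)), "")[[1]]),
        collapse = "")
}

# per-position contribution lookups including N (scored as the minimum)
.contrib5 <- function(pwm) {
  rbind(pwm$contrib, N = pwm$min_w)
}

# word score (Current) over given positions for an encoded word
.word_current <- function(c5, enc, positions) {
  sum(c5[cbind(enc[positions], positions)])
}

.similarity <- function(cur, min_s, max_s) {
  rng <- max_s - min_s
  if (rng <= 0) return(1)   # uninformative matrix: every word attains max
  (cur - min_s) / rng
}

#' Matrix similarity score of a word
#'
#' @param pwm A `"pwm"` object.
#' @param word Character string of length `pwm$width` over A/C/G/T/N
#'   (`N` scores as the per-position minimum).
#' @return MSS in `[0, 1]`.
#' @export
matrix_similarity <- function(pwm, word) {
  enc <- .encode_dna(word)
  if (length(enc) != pwm$width) stop("word length must equal PWM width")
  c5 <- .contrib5(pwm)
  pos <- seq_len(pwm$width)
  .similarity(.word_current(c5, enc, pos), sum(pwm$min_w), sum(pwm$max_w))
}

#' Core similarity score of a word
#'
#' Same formula as [matrix_similarity()] restricted to the core positions.
#' @inheritParams matrix_similarity
#' @return CSS in `[0, 1]`.
#' @export
core_similarity <- function(pwm, word) {
  enc <- .encode_dna(word)
  if (length(enc) != pwm$width) stop("word length must equal PWM width")
  c5 <- .contrib5(pwm)
  .similarity(.word_current(c5, enc, pwm$core),
              sum(pwm$min_w[pwm$core]), sum(pwm$max_w[pwm$core]))
}

# vectorized MSS/CSS for every window of an encoded sequence
.window_scores <- function(pwm, enc) {
  L <- pwm$width
  nw <- length(enc) - L + 1L
  if (nw < 1L) return(list(mss = numeric(0), css = numeric(0)))
  c5 <- .contrib5(pwm)
  cur <- numeric(nw)
  cur_core <- numeric(nw)
  core <- pwm$core
  for (k in seq_len(L)) {
    v <- c5[, k][enc[k:(k + nw - 1L)]]
    cur <- cur + v
    if (k %in% core) cur_core <- cur_core + v
  }
  rng <- sum(pwm$max_w) - sum(pwm$min_w)
  rng_c <- sum(pwm$max_w[core]) - sum(pwm$min_w[core])
  list(
    mss = if (rng > 0) (cur - sum(pwm$min_w)) / rng else rep(1, nw),
    css = if (rng_c > 0) (cur_core - sum(pwm$min_w[core])) / rng_c
          else rep(1, nw)
  )
}

#' Calibrate an MSS cutoff for a target per-window false-positive rate
#'
#' Finds the smallest MSS cutoff whose exceedance probability under i.i.d.
#' background words is at most `alpha`. For matrices of width <= 8 all
#' `4^L` words are enumerated exactly (deterministic); wider matrices use
#' seeded Monte-Carlo sampling.
#'
#' @param pwm A `"pwm"` object.
#' @param background Named base probabilities (A/C/G/T), summing to 1.
#' @param alpha Target per-window exceedance probability in `(0, 1]`.
#' @param n_samples Monte-Carlo sample size (ignored for exact enumeration).
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @param method `"auto"` (exact when `width <= 8`), `"exact"`, or `"mc"`.
#' @return MSS cutoff in `[0, 1]`.
#' @export
calibrate_threshold <- function(pwm,
                                background = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                                alpha = 0.01, n_samples = 100000L,
                                seed = NULL,
                                method = c("auto", "exact", "mc")) {
  method <- match.arg(method)
  stopifnot(alpha > 0)
  if (alpha >= 1) return(0)
  background <- background[.BASES]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-6) {
    stop("background must give probabilities for A, C, G, T summing to 1")
  }
  L <- pwm$width
  if (method == "auto") method <- if (L <= 8) "exact" else "mc"
  if (method == "exact") {
    if (L > 10) stop("exact enumeration not feasible for width > 10")
    digits <- as.matrix(expand.grid(rep(list(1:4), L)))
    cur <- numeric(nrow(digits))
    logp <- numeric(nrow(digits))
    lb <- log(as.numeric(background))
    for (k in seq_len(L)) {
      cur <- cur + pwm$contrib[, k][digits[, k]]
      logp <- logp + lb[digits[, k]]
    }
    rng <- sum(pwm$max_w) - sum(pwm$min_w)
    mss <- if (rng > 0) (cur - sum(pwm$min_w)) / rng else rep(1, nrow(digits))
    agg <- rowsum(exp(logp), group = round(mss, 12))
    sc <- as.numeric(rownames(agg))
    o <- order(sc, decreasing = TRUE)
    sc <- sc[o]
    exceed <- cumsum(agg[o, 1])
  } else {
    if (n_samples * alpha < 10) {
      stop("n_samples too small for alpha = ", alpha,
           "; need at least ", ceiling(10 / alpha), " samples")
    }
    if (!is.null(seed)) set.seed(seed)
    draws <- matrix(sample.int(4, n_samples * L, replace = TRUE,
                               prob = as.numeric(background)),
                    nrow = n_samples)
    cur <- numeric(n_samples)
    for (k in seq_len(L)) cur <- cur + pwm$contrib[, k][draws[, k]]
    rng <- sum(pwm$max_w) - sum(pwm$min_w)
    mss <- if (rng > 0) (cur - sum(pwm$min_w)) / rng else rep(1, n_samples)
    tab <- table(round(mss, 12))
    sc <- as.numeric(names(tab))
    o <- order(sc, decreasing = TRUE)
    sc <- sc[o]
    exceed <- cumsum(as.numeric(tab[o])) / n_samples
  }
  ok <- exceed <= alpha
  if (!any(ok)) {
    warning("no cutoff achieves alpha = ", alpha, "; returning 1")
    return(1)
  }
  sc[max(which(ok))]
}

#' Define a promoter region
#'
#' A promoter region is the sense-strand sequence spanning up to 2 kb
#' upstream of the TSS through the end of the first exon. Coordinates in
#' scan output are 0-based half-open and TSS-relative (negative = upstream).
#'
#' @param gene Gene identifier.
#' @param seq Sense-strand sequence, 5'->3'.
#' @param tss_offset 0-based index of the TSS within `seq`.
#' @param exon_end Index one past the first exon (defaults to the sequence
#'   end).
#' @return One-row `data.frame` with columns `gene`, `seq`, `tss_offset`,
#'   `exon_end`.
#' @export
promoter_region <- function(gene, seq, tss_offset, exon_end = nchar(seq)) {
  if (!(tss_offset >= 0 && tss_offset < exon_end &&
        exon_end <= nchar(seq))) {
    stop("need 0 <= tss_offset < exon_end <= sequence length")
  }
  if (tss_offset > 2000) stop("upstream span exceeds 2000 bases")
  data.frame(gene = gene, seq = seq, tss_offset = as.integer(tss_offset),
             exon_end = as.integer(exon_end), stringsAsFactors = FALSE)
}

#' Scan one promoter region on both strands
#'
#' Slides the PWM over every window lying within `[0, exon_end)` on both
#' strands and reports windows passing both score cutoffs. Minus-strand hits
#' are reported at the mirrored sense-strand coordinate. All overlapping
#' hits are reported; no merging.
#'
#' @param pwm A `"pwm"` object.
#' @param region One-row data frame from [promoter_region()].
#' @param mss_cutoff,css_cutoff Minimum matrix / core similarity (hits
#'   require `>=` both). `css_cutoff` defaults to 0.75.
#' @return `data.frame` with columns `gene`, `pwm`, `start`, `end`
#'   (TSS-relative, 0-based half-open on the sense strand), `strand`,
#'   `core_score`, `matrix_score`. Regions shorter than the PWM give an
#'   empty result.
#' @export
scan_region <- function(pwm, region, mss_cutoff, css_cutoff = 0.75) {
  stopifnot(mss_cutoff >= 0, mss_cutoff <= 1,
            css_cutoff >= 0, css_cutoff <= 1)
  L <- pwm$width
  sub <- substr(region$seq, 1, region$exon_end)
  empty <- data.frame(gene = character(), pwm = character(),
                      start = integer(), end = integer(),
                      strand = character(), core_score = numeric(),
                      matrix_score = numeric(), stringsAsFactors = FALSE)
  if (nchar(sub) < L) return(empty)

  fwd <- .window_scores(pwm, .encode_dna(sub))
  rev_ <- .window_scores(pwm, .encode_dna(.revcomp_chr(sub)))
  n <- nchar(sub)

  take <- function(sc, strand) {
    hit <- which(sc$css >= css_cutoff & sc$mss >= mss_cutoff)
    if (!length(hit)) return(empty)
    start_abs <- if (strand == "+") hit - 1L else n - (hit - 1L) - L
    data.frame(gene = region$gene, pwm = pwm$id,
               start = start_abs - region$tss_offset,
               end = start_abs - region$tss_offset + L,
               strand = strand,
               core_score = sc$css[hit], matrix_score = sc$mss[hit],
               stringsAsFactors = FALSE)
  }
  out <- rbind(take(fwd, "+"), take(rev_, "-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a set of promoters and summarize
#'
#' @param pwm A `"pwm"` object.
#' @param regions Data frame of promoter regions (one row per gene; see
#'   [promoter_region()]). Duplicate gene ids are an error.
#' @inheritParams scan_region
#' @return List with `hits` (concatenated [scan_region()] tables) and
#'   `summary`: `n_sites` (all hits), `n_genes` (genes with >= 1 hit),
#'   `genes` (their ids).
#' @export
scan_promoters <- function(pwm, regions, mss_cutoff, css_cutoff = 0.75) {
  stopifnot(nrow(regions) >= 1)
  if (anyDuplicated(regions$gene)) stop("duplicate gene ids in regions")
  hits <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    scan_region(pwm, regions[i, , drop = FALSE], mss_cutoff, css_cutoff)
  }))
  rownames(hits) <- NULL
  genes <- sort(unique(hits$gene))
  list(hits = hits,
       summary = list(n_sites = nrow(hits), n_genes = length(genes),
                      genes = genes))
}

#' Synthetic E-box (Myc/Max) position count matrix
#'
#' An 8-position synthetic count matrix centered on the palindromic CACGTG
#' E-box with non-palindromic flanks (consensus `ACACGTGG`), built for
#' testing and simulation. It is NOT a curated Myc/Max matrix; real
#' TRANSFAC/JASPAR matrices must be supplied by the user for real analyses.
#'
#' @param core_count Count given to the consensus base at core positions
#'   (of 100 observations).
#' @param flank_count Count given to the consensus base at flank positions.
#' @return 4 x 8 count matrix (rows A/C/G/T).
#' @export
ebox_counts <- function(core_count = 97, flank_count = 70) {
  consensus <- c("A", "C", "A", "C", "G", "T", "G", "G")
  is_core <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  counts <- matrix(0, 4, 8, dimnames = list(.BASES, NULL))
  for (i in 1:8) {
    major <- if (is_core[i]) core_count else flank_count
    minor <- (100 - major) / 3
    counts[, i] <- minor
    counts[consensus[i], i] <- major
  }
  counts
}
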