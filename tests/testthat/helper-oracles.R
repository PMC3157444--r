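# Independent oracles and small fixtures, implemented with plain loops so
# they share no code path with the package internals.

# count matrix with a given consensus: `major` counts at the consensus base,
# 4 at each other base
counts_from_consensus <- function(consensus, major = 88) {
  b <- strsplit(consensus, "")[[1]]
  counts <- matrix(4, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(b)) counts[b[i], i] <- major
  counts
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# MATCH-style scores recomputed from the raw counts with explicit loops
brute_freq <- function(counts, pseudocount = 0.25) {
  adj <- counts + pseudocount
  apply(adj, 2, function(col) col / sum(col))
}

brute_info <- function(f) {
  vapply(seq_len(ncol(f)), function(i) {
    s <- 0
    for (b in 1:4) if (f[b, i] > 0) s <- s + f[b, i] * log(4 * f[b, i])
    s
  }, numeric(1))
}

brute_core <- function(f) {
  info <- brute_info(f)
  L <- length(info)
  w <- min(5, L)
  best <- -Inf; best_s <- 1
  for (s in 1:(L - w + 1)) {
    v <- sum(info[s:(s + w - 1)])
    if (v > best) { best <- v; best_s <- s }
  }
  best_s:(best_s + w - 1)
}

brute_similarity <- function(counts, word, positions = NULL,
                             pseudocount = 0.25) {
  f <- brute_freq(counts, pseudocount)
  info <- brute_info(f)
  if (is.null(positions)) positions <- seq_len(ncol(f))
  b <- strsplit(word, "")[[1]]
  cur <- mn <- mx <- 0
  for (i in positions) {
    cur <- cur + info[i] * (if (b[i] == "N") min(f[, i]) else f[b[i], i])
    mn <- mn + info[i] * min(f[, i])
    mx <- mx + info[i] * max(f[, i])
  }
  unname((cur - mn) / (mx - mn))
}

# every-window, both-strand scan by explicit enumeration
brute_scan <- function(counts, seq, mss_cut, css_cut, pseudocount = 0.25) {
  f <- brute_freq(counts, pseudocount)
  core <- brute_core(f)
  L <- ncol(f)
  n <- nchar(seq)
  hits <- list()
  for (s in 0:(n - L)) {
    for (strand in c("+", "-")) {
      w <- substr(seq, s + 1, s + L)
      if (strand == "-") w <- revcomp(w)
      mss <- brute_similarity(counts, w, NULL, pseudocount)
      css <- brute_similarity(counts, w, core, pseudocount)
      if (mss >= mss_cut && css >= css_cut) {
        hits[[length(hits) + 1]] <- data.frame(
          start = s, strand = strand, core_score = css, matrix_score = mss,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), strand = character(),
                      core_score = numeric(), matrix_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# seed-site enumeration by explicit per-window base pairing
brute_seed_sites <- function(mature, utr, wobble_allowed) {
  pairs_exact <- c(A = "U", C = "G", G = "C", T = "A")  # utr base -> miRNA base
  is_wobble <- function(utr_b, mi_b) {
    (utr_b == "T" && mi_b == "G") || (utr_b == "G" && mi_b == "U")
  }
  mi <- strsplit(mature, "")[[1]]
  u <- strsplit(utr, "")[[1]]
  n <- length(u)
  # pair utr window positions (5'->3') against miRNA seed positions reversed
  window_match <- function(s0, mi_pos) {
    k <- length(mi_pos)
    wob <- 0
    for (j in seq_len(k)) {
      ub <- u[s0 + j]                      # 1-based utr index
      mb <- mi[mi_pos[k - j + 1]]          # antiparallel pairing
      if (ub == "N") return(NA)
      if (pairs_exact[[ub]] == mb) next
      if (wobble_allowed && is_wobble(ub, mb)) { wob <- wob + 1; next }
      return(NA)
    }
    wob
  }
  eightmer_at <- function(s) {
    if (s < 0 || s + 8 > n) return(FALSE)
    w <- window_match(s, 2:8)
    !is.na(w) && w == 0 && u[s + 8] == "A"
  }
  hits <- list()
  for (s in 0:(n - 7)) {
    is8 <- eightmer_at(s)
    if (is8) {
      hits[[length(hits) + 1]] <- data.frame(start = s, site_type = "8mer")
    }
    w <- window_match(s, 2:8)
    if (!is.na(w) && w == 0 && !is8) {
      hits[[length(hits) + 1]] <- data.frame(start = s, site_type = "7mer-m8")
    } else if (!is.na(w) && wobble_allowed && w == 1) {
      hits[[length(hits) + 1]] <- data.frame(start = s,
                                             site_type = "wobble-7mer")
    }
    # 7mer-A1: positions 2-7 exact + A, unless it is the tail of an 8mer
    if (s + 7 <= n) {
      w7 <- window_match(s, 2:7)
      if (!is.na(w7) && w7 == 0 && u[s + 7] == "A" && !eightmer_at(s - 1)) {
        hits[[length(hits) + 1]] <- data.frame(start = s,
                                               site_type = "7mer-A1")
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out$start, out$site_type), , drop = FALSE]
}

# exact rational hypergeometric upper tail via binomial coefficients
brute_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  num <- 0
  for (i in k:min(K, n)) {
    if (n - i <= N - K) num <- num + choose(K, i) * choose(N - K, n - i)
  }
  num / choose(N, n)
}

# small, fast study for structural tests
small_config <- function(seed = 1, ...) {
  simulation_config(
    n_genes = 60, n_mirnas = 12, n_replicates_per_group = 3,
    frac_de_genes_up = 0.15, frac_de_genes_down = 0.15,
    frac_de_mirnas_up = 0.25, frac_de_mirnas_down = 0.10,
    promoter_len_upstream = 300, first_exon_len = 100, utr_len = 200,
    n_motif_arm = 3, n_mirna_arm = 3, n_overlap = 1,
    n_terms = 6, seed = seed, ...)
}
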