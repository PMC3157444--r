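#' miRNA seed-match target prediction
#'
#' Canonical miRNA target sites are short 3'UTR elements complementary to the
#' miRNA seed (nucleotides 2-8 of the mature sequence). Two stringencies are
#' provided: `stringent` reports only exact Watson-Crick seed matches (8mer,
#' 7mer-m8, 7mer-A1), emulating TargetScan-style seed pairing; `moderate`
#' additionally tolerates exactly one G:U wobble pair within the 7-nt match
#' (miRNA G opposite target T, or miRNA U opposite target G), emulating
#' miRanda/miRBase-style moderately stringent pairing. Stringent predictions
#' are always a subset of moderate ones.
#'
#' Coordinates are 0-based half-open in UTR space, 5'->3' on the mRNA.
#'
#' @name seed_targets
NULL

.rna_complement_dna <- c(A = "T", C = "G", G = "C", U = "A")

# reverse complement of an RNA word, written in the DNA alphabet
.seed_rc_dna <- function(rna_word) {
  b <- strsplit(rna_word, "")[[1]]
  bad <- !b %in% names(.rna_complement_dna)
  if (any(bad)) stop("invalid miRNA base(s): ", paste(unique(b[bad]), collapse = ""))
  paste(rev(unname(.rna_complement_dna[b])), collapse = "")
}

.check_utr <- function(utr) {
  if (grepl("[^ACGTN]", utr)) stop("UTR sequence contains non-ACGTN characters")
  invisible(utr)
}

#' Seed-match words for a mature miRNA
#'
#' Returns the UTR words (DNA alphabet, 5'->3') that constitute each site
#' type for a mature miRNA: `8mer` = reverse complement of seed positions 2-8
#' followed by A; `7mer-m8` = reverse complement of positions 2-8;
#' `7mer-A1` = reverse complement of positions 2-7 followed by A;
#' `wobble-7mer` = all variants of the 7mer-m8 word with exactly one G:U
#' wobble substitution (target C->T opposite a seed G, target A->G opposite
#' a seed U).
#'
#' @param mature Mature miRNA sequence, 5'->3', RNA alphabet (A/C/G/U),
#'   length >= 8.
#' @return Named list of character vectors: `eightmer`, `m8`, `a1`, `wobble`.
#' @export
seed_words <- function(mature) {
  if (nchar(mature) < 8) stop("mature miRNA must be >= 8 nt")
  s28 <- substr(mature, 2, 8)
  s27 <- substr(mature, 2, 7)
  m8 <- .seed_rc_dna(s28)           # 7 nt
  a1 <- paste0(.seed_rc_dna(s27), "A")
  eightmer <- paste0(m8, "A")
  # wobble variants of the 7mer-m8 word: word position k pairs seed
  # position (8 - k) of s28 (1-based within the 7-mer)
  seed_b <- strsplit(s28, "")[[1]]
  word_b <- strsplit(m8, "")[[1]]
  wobble <- character(0)
  for (j in seq_len(7)) {
    k <- 8 - j
    if (seed_b[j] == "G") {         # exact target C -> wobble T
      v <- word_b; v[k] <- "T"
      wobble <- c(wobble, paste(v, collapse = ""))
    } else if (seed_b[j] == "U") {  # exact target A -> wobble G
      v <- word_b; v[k] <- "G"
      wobble <- c(wobble, paste(v, collapse = ""))
    }
  }
  list(eightmer = eightmer, m8 = m8, a1 = a1, wobble = unique(wobble))
}

# 0-based start positions of fixed word occurrences in a string
.find_word <- function(word, seq) {
  hits <- gregexpr(word, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

.predict_one <- function(mirna_id, mature, gene_id, utr, mode) {
  .check_utr(utr)
  w <- seed_words(mature)
  p8 <- .find_word(w$eightmer, utr)
  pm8 <- setdiff(.find_word(w$m8, utr), p8)        # prefix of an 8mer
  pa1 <- setdiff(.find_word(w$a1, utr), p8 + 1L)   # suffix of an 8mer
  starts <- c(p8, pm8, pa1)
  res <- data.frame(
    mirna = rep(mirna_id, length(starts)),
    gene = rep(gene_id, length(starts)),
    start = starts,
    end = c(p8 + 8L, pm8 + 7L, pa1 + 7L),
    site_type = rep(c("8mer", "7mer-m8", "7mer-A1"),
                    c(length(p8), length(pm8), length(pa1))),
    stringsAsFactors = FALSE
  )
  if (mode == "moderate" && length(w$wobble)) {
    pw <- unlist(lapply(w$wobble, .find_word, seq = utr))
    if (length(pw)) {
      res <- rbind(res, data.frame(
        mirna = rep(mirna_id, length(pw)),
        gene = rep(gene_id, length(pw)),
        start = pw, end = pw + 7L, site_type = "wobble-7mer",
        stringsAsFactors = FALSE
      ))
    }
  }
  res$mode <- rep(mode, nrow(res))
  res[order(res$start, res$site_type), , drop = FALSE]
}

#' Predict seed-match sites for one miRNA/UTR pair
#'
#' @param mirna_id,mature miRNA identifier and mature sequence (RNA
#'   alphabet, 5'->3').
#' @param gene_id,utr Gene identifier and 3'UTR sequence (DNA alphabet; `N`
#'   never matches).
#' @return `data.frame` with columns `mirna`, `gene`, `start`, `end`
#'   (0-based half-open UTR coordinates), `site_type`, `mode`. Overlapping
#'   matches are reported once at the most specific type (an 8mer subsumes
#'   the 7mer-m8 and 7mer-A1 at the same locus).
#' @export
predict_targets_stringent <- function(mirna_id, mature, gene_id, utr) {
  .predict_one(mirna_id, mature, gene_id, utr, "stringent")
}

#' @rdname predict_targets_stringent
#' @details `predict_targets_moderate()` reports every stringent site plus
#'   7-nt matches carrying exactly one G:U wobble (`wobble-7mer`).
#' @export
predict_targets_moderate <- function(mirna_id, mature, gene_id, utr) {
  .predict_one(mirna_id, mature, gene_id, utr, "moderate")
}

#' Predict seed sites for all miRNA/UTR combinations
#'
#' @param mirnas Named character vector of mature sequences (names are
#'   miRNA ids), or a data frame with columns `mirna`, `mature`.
#' @param utrs Named character vector of 3'UTR sequences (names are gene
#'   ids), or a data frame with columns `gene`, `utr`.
#' @param mode `"stringent"` or `"moderate"`.
#' @return Combined prediction table (see [predict_targets_stringent()]).
#' @export
predict_targets <- function(mirnas, utrs, mode = c("stringent", "moderate")) {
  mode <- match.arg(mode)
  if (is.data.frame(mirnas)) mirnas <- stats::setNames(mirnas$mature, mirnas$mirna)
  if (is.data.frame(utrs)) utrs <- stats::setNames(utrs$utr, utrs$gene)
  out <- vector("list", length(mirnas) * length(utrs))
  k <- 0L
  for (m in names(mirnas)) {
    for (g in names(utrs)) {
      k <- k + 1L
      out[[k]] <- .predict_one(m, mirnas[[m]], g, utrs[[g]], mode)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Anti-correlated miRNA-target pairs
#'
#' Intersects seed-site predictions with direction-labeled significant sets:
#' an upregulated miRNA is paired with its predicted targets among the
#' downregulated genes, and vice versa. One pair is counted per
#' (miRNA, gene) regardless of site multiplicity; sites are retained as
#' evidence.
#'
#' @param mirna_up,mirna_down Significant miRNA ids by direction.
#' @param gene_up,gene_down Significant gene ids by direction.
#' @param predictions Prediction table from [predict_targets()].
#' @return List with `pairs` (data frame `mirna`, `gene`, `mirna_direction`,
#'   `gene_direction`, `n_sites`, `sites` as a semicolon-joined evidence
#'   string), `genes` (sorted unique target genes), `mirna_counts` (targets
#'   per miRNA, named integer vector).
#' @export
anticorrelated_pairs <- function(mirna_up, mirna_down, gene_up, gene_down,
                                 predictions) {
  p <- predictions
  keep <- (p$mirna %in% mirna_up & p$gene %in% gene_down) |
          (p$mirna %in% mirna_down & p$gene %in% gene_up)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0) {
    pairs <- data.frame(mirna = character(), gene = character(),
                        mirna_direction = character(),
                        gene_direction = character(),
                        n_sites = integer(), sites = character(),
                        stringsAsFactors = FALSE)
    return(list(pairs = pairs, genes = character(),
                mirna_counts = integer(0)))
  }
  key <- paste(p$mirna, p$gene, sep = "\r")
  by_pair <- split(p, key)
  pairs <- do.call(rbind, lapply(by_pair, function(d) {
    data.frame(
      mirna = d$mirna[1], gene = d$gene[1],
      mirna_direction = if (d$mirna[1] %in% mirna_up) "up" else "down",
      gene_direction = if (d$gene[1] %in% gene_up) "up" else "down",
      n_sites = nrow(d),
      sites = paste(sprintf("%d:%s", d$start, d$site_type), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  pairs <- pairs[order(pairs$mirna, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  counts <- table(pairs$mirna)
  list(
    pairs = pairs,
    genes = sort(unique(pairs$gene)),
    mirna_counts = stats::setNames(as.integer(counts), names(counts))
  )
}
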