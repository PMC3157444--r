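#' File formats
#'
#' Plain-text interchange: TSV matrices (header row, feature ids in the
#' first column), FASTA sequences (promoter headers carry
#' `gene|tss_offset|exon_end`), GMT gene sets, TRANSFAC and JASPAR count
#' matrices, and a JSON truth manifest. All coordinates in files are
#' 0-based half-open.
#'
#' @name io
NULL

#' Read / write a numeric TSV matrix
#'
#' First column holds feature ids; remaining columns are samples.
#'
#' @param path File path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param mat Matrix to write.
#' @param id_col Header for the feature-id column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a CT matrix with undetected markers
#'
#' Undetected wells (empty cells, `NA`, `Undetermined`, `Undetected`) are
#' read as `NA`, to be handled by [censor_ct()].
#'
#' @param path TSV path (first column miRNA ids).
#' @param undetected Strings treated as undetected.
#' @return Numeric matrix with `NA` for undetected wells.
#' @export
read_ct_tsv <- function(path,
                        undetected = c("", "NA", "Undetermined",
                                       "Undetected")) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = undetected,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(mode(m) <- "numeric")
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_ct_tsv
#' @param mat CT matrix (`NA` = undetected).
#' @param marker String written for undetected wells.
#' @export
write_ct_tsv <- function(mat, path, marker = "Undetermined") {
  ch <- matrix(sprintf("%.10g", mat), nrow(mat), ncol(mat),
               dimnames = dimnames(mat))
  ch[is.na(mat)] <- marker
  df <- data.frame(mirna = rownames(mat), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a two-column sample design
#'
#' @param path TSV with columns `sample`, `group`.
#' @return Named character vector sample -> group.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$group, df$sample)
}

#' @rdname read_design_tsv
#' @param design Named character vector sample -> group.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(
    data.frame(sample = names(design), group = unname(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write promoter FASTA
#'
#' Headers are `gene|tss_offset|exon_end` (0-based half-open).
#'
#' @param path FASTA path.
#' @return Promoter region data frame (see [promoter_region()]).
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop("promoter FASTA headers must be gene|tss_offset|exon_end")
  do.call(rbind, lapply(seq_along(ss), function(i) {
    promoter_region(parts[[i]][1], as.character(ss[[i]]),
                    as.integer(parts[[i]][2]), as.integer(parts[[i]][3]))
  }))
}

#' @rdname read_promoters_fasta
#' @param regions Promoter region data frame.
#' @export
write_promoters_fasta <- function(regions, path) {
  ss <- Biostrings::DNAStringSet(regions$seq)
  names(ss) <- sprintf("%s|%d|%d", regions$gene, regions$tss_offset,
                       regions$exon_end)
  Biostrings::writeXStringSet(ss, path)
}

#' Read / write plain sequence FASTA as a named vector
#'
#' @param path FASTA path.
#' @param alphabet `"dna"` (e.g. UTRs) or `"rna"` (mature miRNAs).
#' @return Named character vector of sequences.
#' @export
read_seqs_fasta <- function(path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  ss <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
        else Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_seqs_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_seqs_fasta <- function(seqs, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  ss <- if (alphabet == "dna") Biostrings::DNAStringSet(unname(seqs))
        else Biostrings::RNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
}

#' Read / write GMT gene sets
#'
#' One term per line: term id, description, then member genes,
#' tab-separated.
#'
#' @param path GMT path.
#' @return Named list term -> character vector of genes; descriptions kept
#'   as attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, character(1), 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list term -> genes.
#' @param descriptions Optional named descriptions (defaults to term ids).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(term) {
    paste(c(term, descriptions[[term]], sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read TRANSFAC flat-format count matrices
#'
#' Parses the classic flat format: optional `ID`/`NA` fields, a
#' `P0  A  C  G  T` header, numbered count rows, `//` separators. Counts
#' are parsed bit-exactly as written.
#'
#' @param path File path (may contain several matrices).
#' @return List of elements `list(id, counts)` with `counts` a 4 x L matrix
#'   (rows A/C/G/T).
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  out <- list()
  id <- NULL
  rows <- list()
  flush <- function() {
    if (length(rows)) {
      counts <- t(do.call(rbind, rows))
      rownames(counts) <- c("A", "C", "G", "T")
      out[[length(out) + 1L]] <<- list(
        id = if (is.null(id)) paste0("matrix", length(out) + 1L) else id,
        counts = counts)
    }
    id <<- NULL
    rows <<- list()
  }
  for (ln in lines) {
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^ID\\s", ln)) { id <- sub("^ID\\s+", "", ln); next }
    if (grepl("^NA\\s", ln) && is.null(id)) {
      id <- sub("^NA\\s+", "", ln); next
    }
    if (grepl("^P0", ln) || grepl("^PO", ln)) next
    if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(f[2:5])
    }
  }
  flush()
  out
}

#' Write a count matrix in TRANSFAC flat format
#'
#' @param counts 4 x L count matrix (rows A/C/G/T).
#' @param path Output path.
#' @param id Matrix identifier.
#' @export
write_transfac <- function(counts, path, id = "MATRIX") {
  cons <- c("A", "C", "G", "T")[apply(counts, 2, which.max)]
  lines <- c(paste("ID", id), "P0      A      C      G      T")
  for (i in seq_len(ncol(counts))) {
    lines <- c(lines, sprintf("%02d %6g %6g %6g %6g %s", i,
                              counts["A", i], counts["C", i],
                              counts["G", i], counts["T", i], cons[i]))
  }
  writeLines(c(lines, "//"), path)
}

#' Read JASPAR text-format count matrices
#'
#' Parses the `>ID name` header followed by four `A [ ... ]` style rows
#' (brackets optional).
#'
#' @param path File path (may contain several matrices).
#' @return List of elements `list(id, counts)` (counts 4 x L, rows A/C/G/T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) stop("expected '>' header in JASPAR file")
    id <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]][1]
    rows <- list()
    for (j in 1:4) {
      ln <- lines[i + j]
      base <- sub("^\\s*([ACGTacgt]).*$", "\\1", ln)
      nums <- regmatches(ln, gregexpr("[0-9.]+", ln))[[1]]
      rows[[toupper(base)]] <- as.numeric(nums)
    }
    counts <- do.call(rbind, rows[c("A", "C", "G", "T")])
    rownames(counts) <- c("A", "C", "G", "T")
    out[[length(out) + 1L]] <- list(id = id, counts = counts)
    i <- i + 5
  }
  out
}

#' Write motif hits as BED
#'
#' Chromosome column carries the gene id; scores are the matrix similarity
#' scaled to 0-1000. Coordinates are TSS-relative as produced by
#' [scan_region()], shifted by `offset` if absolute coordinates are wanted.
#'
#' @param hits Hit table from [scan_promoters()].
#' @param path Output path.
#' @param offset Added to start/end (e.g., a promoter's TSS offset).
#' @export
write_hits_bed <- function(hits, path, offset = 0L) {
  bed <- data.frame(
    chrom = hits$gene,
    start = hits$start + offset,
    end = hits$end + offset,
    name = hits$pwm,
    score = as.integer(round(hits$matrix_score * 1000)),
    strand = hits$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
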