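#' Two-group differential filtering
#'
#' Differential expression is assessed per feature with a one-way two-group
#' ANOVA (identical to the pooled-variance two-sample t-test; F = t^2) and a
#' geometric fold change computed from log2 group means. mRNA matrices are on
#' the log2 scale; miRNA matrices are on the dCT scale, where a LOWER value
#' means HIGHER expression, so the fold-change sign is inverted for miRNAs.
#'
#' @name diffexpr
NULL

#' Remove features at or below background
#'
#' Retains features whose maximum value across samples strictly exceeds
#' `threshold`. The default threshold is the 20th percentile of all values in
#' the matrix.
#'
#' @param mat Feature x sample numeric matrix (log2 scale).
#' @param threshold Background level; features with `max <= threshold` are
#'   dropped. Default `NULL` uses the 20th percentile of `mat`.
#' @return Filtered matrix.
#' @export
background_filter <- function(mat, threshold = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(threshold)) {
    threshold <- stats::quantile(mat, 0.20, names = FALSE)
  }
  mat[apply(mat, 1, max) > threshold, , drop = FALSE]
}

#' Per-feature two-group ANOVA with fold change
#'
#' For each feature, p comes from the one-way ANOVA F statistic on the two
#' groups (equal-variance; `F = t^2`, df = (1, n1 + n2 - 2)). The log2 fold
#' change of the test group over the reference is the difference of group
#' means for mRNA, and its negative for miRNA dCT data (greater dCT = lower
#' expression). Features with zero pooled variance get p = 1 when the group
#' means are equal and p = 0 otherwise.
#'
#' @param mat Feature x sample matrix: log2 expression (`kind = "mrna"`) or
#'   dCT (`kind = "mirna"`).
#' @param groups Character/factor of group labels, one per column.
#' @param reference Label of the reference group (default: first level).
#' @param kind `"mrna"` or `"mirna"`; controls the fold-change sign
#'   convention as described above.
#' @return `data.frame` with columns `feature`, `log2fc` (signed, test vs
#'   reference on the expression scale), `fold_change` (linear magnitude,
#'   >= 1), `direction` (`"up"`, `"down"`, `"none"`), `p_value`.
#' @export
differential_test <- function(mat, groups, reference = NULL,
                              kind = c("mrna", "mirna")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(mat), length(groups) == ncol(mat))
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("reference group '", reference, "' not found")
  test <- setdiff(lev, reference)
  i_ref <- groups == reference
  i_tst <- groups == test
  n1 <- sum(i_ref); n2 <- sum(i_tst)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")

  m_ref <- rowMeans(mat[, i_ref, drop = FALSE])
  m_tst <- rowMeans(mat[, i_tst, drop = FALSE])
  ss1 <- rowSums((mat[, i_ref, drop = FALSE] - m_ref)^2)
  ss2 <- rowSums((mat[, i_tst, drop = FALSE] - m_tst)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df                       # pooled variance
  se2 <- s2 * (1 / n1 + 1 / n2)
  diff <- m_tst - m_ref
  f <- diff^2 / se2
  p <- stats::pf(f, 1, df, lower.tail = FALSE)
  # degenerate rows: no residual variance
  zero_var <- se2 == 0
  p[zero_var & diff == 0] <- 1
  p[zero_var & diff != 0] <- 0

  log2fc <- if (kind == "mrna") diff else -diff
  data.frame(
    feature = rownames(mat),
    log2fc = log2fc,
    fold_change = 2^abs(log2fc),
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none")),
    p_value = p,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Apply fold-change and p-value cut-offs
#'
#' Keeps features with fold-change magnitude strictly greater than
#' `fc_cutoff` AND p strictly below `p_cutoff`, and partitions them by
#' direction.
#'
#' @param results Output of [differential_test()].
#' @param fc_cutoff Linear fold-change magnitude cutoff (default 2,
#'   strict `>`).
#' @param p_cutoff p-value cutoff (default 0.05, strict `<`).
#' @return List with `table` (the input plus a logical `passes` column),
#'   `significant` (passing rows), `up` and `down` (feature id vectors).
#' @export
apply_thresholds <- function(results, fc_cutoff = 2, p_cutoff = 0.05) {
  passes <- results$fold_change > fc_cutoff & results$p_value < p_cutoff
  results$passes <- passes
  sig <- results[passes, , drop = FALSE]
  list(
    table = results,
    significant = sig,
    up = sig$feature[sig$direction == "up"],
    down = sig$feature[sig$direction == "down"]
  )
}

#' Collapse significant probes to unique genes
#'
#' Maps significant probes to genes and assigns each gene the common
#' direction of its significant probes. Genes whose probes disagree in
#' direction are flagged discordant and excluded (direction is load-bearing
#' for the downstream anti-correlation mapping). Probes absent from the
#' mapping are reported, not fatal.
#'
#' @param sig Data frame of significant probe results (columns `feature`,
#'   `direction`), e.g. `apply_thresholds(...)$significant`.
#' @param probe2gene Data frame with columns `probe`, `gene`.
#' @return List with `genes` (data frame `gene`, `direction`, `n_probes`),
#'   `discordant` (gene ids excluded), `unmapped` (probe ids with no gene).
#' @export
collapse_probes_to_genes <- function(sig, probe2gene) {
  stopifnot(all(c("probe", "gene") %in% names(probe2gene)))
  idx <- match(sig$feature, probe2gene$probe)
  unmapped <- sig$feature[is.na(idx)]
  if (length(unmapped)) {
    warning(length(unmapped), " significant probe(s) had no gene mapping")
  }
  mapped <- sig[!is.na(idx), , drop = FALSE]
  mapped$gene <- probe2gene$gene[idx[!is.na(idx)]]
  if (nrow(mapped) == 0) {
    return(list(
      genes = data.frame(gene = character(), direction = character(),
                         n_probes = integer(), stringsAsFactors = FALSE),
      discordant = character(), unmapped = unmapped
    ))
  }
  by_gene <- split(mapped$direction, mapped$gene)
  dirs <- vapply(by_gene, function(d) {
    u <- unique(d)
    if (length(u) == 1) u else "discordant"
  }, character(1))
  n_probes <- lengths(by_gene)
  discordant <- names(dirs)[dirs == "discordant"]
  keep <- dirs != "discordant"
  list(
    genes = data.frame(gene = names(dirs)[keep], direction = unname(dirs[keep]),
                       n_probes = unname(n_probes[keep]),
                       stringsAsFactors = FALSE),
    discordant = discordant,
    unmapped = unmapped
  )
}
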