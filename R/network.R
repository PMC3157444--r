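#' Two-arm regulatory network assembly
#'
#' The reconstructed network has two arms rooted at the transcription
#' factor: a transcriptional arm (significant genes whose promoters carry at
#' least one factor binding site) and a post-transcriptional arm
#' (significant genes targeted by anti-correlated, factor-regulated miRNAs).
#' Genes in both arms form the overlap set, candidates for coherent
#' fine-tuning by both mechanisms.
#'
#' @name network
NULL

#' Assemble the two-arm regulatory network
#'
#' @param sig_genes Data frame of significant genes with columns `gene`,
#'   `direction` (from [collapse_probes_to_genes()]).
#' @param motif_hits Hit table from [scan_promoters()] (`$hits`).
#' @param pair_set Anti-correlated pair set from [anticorrelated_pairs()].
#' @return Object of class `"regulatory_network"`: list with `motif_arm`
#'   (gene ids), `motif_sites` (per-gene hit rows), `mirna_arm` (gene ids),
#'   `mirna_pairs` (supporting pair rows), `overlap`, `de_context`
#'   (direction per member gene and miRNA), and `summary` (arm sizes,
#'   overlap size, overlap fraction of the motif arm; `NA` when the motif
#'   arm is empty).
#' @export
assemble_network <- function(sig_genes, motif_hits, pair_set) {
  sg <- sig_genes$gene
  hit_genes <- unique(motif_hits$gene)
  pair_genes <- unique(pair_set$pairs$gene)
  mentioned <- unique(c(hit_genes, pair_genes))
  if (length(mentioned) > 0 && length(intersect(mentioned, sg)) == 0) {
    stop("gene identifiers of motif hits / pairs share nothing with the ",
         "significant gene set; inputs look mismatched")
  }
  motif_arm <- sort(intersect(sg, hit_genes))
  mirna_arm <- sort(intersect(sg, pair_genes))
  overlap <- intersect(motif_arm, mirna_arm)
  frac <- if (length(motif_arm) > 0) length(overlap) / length(motif_arm) else NA_real_

  mirna_dirs <- unique(pair_set$pairs[, c("mirna", "mirna_direction")])
  structure(list(
    motif_arm = motif_arm,
    motif_sites = motif_hits[motif_hits$gene %in% motif_arm, , drop = FALSE],
    mirna_arm = mirna_arm,
    mirna_pairs = pair_set$pairs[pair_set$pairs$gene %in% mirna_arm, ,
                                 drop = FALSE],
    overlap = overlap,
    de_context = list(
      genes = sig_genes[sig_genes$gene %in% union(motif_arm, mirna_arm), ,
                        drop = FALSE],
      mirnas = mirna_dirs
    ),
    summary = list(
      n_motif_arm = length(motif_arm),
      n_mirna_arm = length(mirna_arm),
      n_overlap = length(overlap),
      overlap_fraction_of_motif_arm = frac
    )
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- x$summary
  cat("Regulatory network: ", s$n_motif_arm, " motif-arm gene(s), ",
      s$n_mirna_arm, " miRNA-arm gene(s), ", s$n_overlap,
      " overlapping\n", sep = "")
  invisible(x)
}

#' Export a network as an edge list and JSON summary
#'
#' Writes `edges.tsv` (columns `regulator`, `type`, `target`, `evidence`)
#' and `network.json` (summary block plus arm membership). Motif edges have
#' regulator `"TF"` (the scanned factor), type `myc_motif`, and
#' `start:strand` site evidence; miRNA edges have the miRNA as regulator,
#' type `mirna`, and seed-site evidence.
#'
#' @param network A `"regulatory_network"` object.
#' @param dir Output directory (created if needed).
#' @param tf_label Regulator label for motif edges (default `"c-Myc"`).
#' @return Invisibly, the edge `data.frame`.
#' @export
export_network <- function(network, dir, tf_label = "c-Myc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hs <- network$motif_sites
  motif_edges <- if (nrow(hs)) {
    ev <- vapply(split(hs, hs$gene), function(d) {
      paste(sprintf("%d:%s", d$start, d$strand), collapse = ";")
    }, character(1))
    data.frame(regulator = tf_label, type = "myc_motif",
               target = names(ev), evidence = unname(ev),
               stringsAsFactors = FALSE)
  } else {
    data.frame(regulator = character(), type = character(),
               target = character(), evidence = character(),
               stringsAsFactors = FALSE)
  }
  mp <- network$mirna_pairs
  mirna_edges <- if (nrow(mp)) {
    data.frame(regulator = mp$mirna, type = "mirna", target = mp$gene,
               evidence = mp$sites, stringsAsFactors = FALSE)
  } else {
    motif_edges[0, ]
  }
  edges <- rbind(motif_edges, mirna_edges)
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    summary = network$summary,
    motif_arm = network$motif_arm,
    mirna_arm = network$mirna_arm,
    overlap = network$overlap
  ), file.path(dir, "network.json"), auto_unbox = TRUE, digits = NA,
     pretty = TRUE)
  invisible(edges)
}
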