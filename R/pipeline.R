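#' Run the full network-reconstruction pipeline on a study
#'
#' Chains every stage on a synthetic (or equivalently structured) study:
#' CT censoring, U6 dCT normalization and detection filtering; two-group
#' differential filtering of miRNAs (dCT scale) and mRNA probes (log2
#' scale) with probe-to-gene collapsing; seed-site prediction for the
#' significant miRNAs against the significant genes' 3'UTRs intersected
#' with anti-correlated directions; PWM threshold calibration and promoter
#' scanning of the significant genes; per-direction gene-set enrichment;
#' and two-arm network assembly.
#'
#' @param study A `"synthetic_study"` (or a list with the same fields).
#' @param reference Reference group label (default `"wt"`).
#' @param fc_cutoff,p_cutoff Differential cut-offs (fold change strictly
#'   `>`, p strictly `<`).
#' @param dct_cutoff Detection cutoff on minimum dCT (default 10).
#' @param background_threshold Passed to [background_filter()] (default:
#'   20th percentile).
#' @param target_mode Seed-match stringency, `"moderate"` or `"stringent"`.
#' @param alpha Per-window false-positive rate for the PWM scan cutoff.
#' @param css_cutoff Core-similarity cutoff (default: the study's).
#' @return List with elements `dct`, `detected`, `mirna_de`, `mirna_sets`,
#'   `mrna_de`, `mrna_sets`, `sig_genes`, `predictions`, `pairs`, `pwm`,
#'   `mss_cutoff`, `scan`, `enrichment_up`, `enrichment_down`,
#'   `enrichment_all` (combined significant gene list), `network`.
#' @export
run_pipeline <- function(study, reference = "wt",
                         fc_cutoff = 2, p_cutoff = 0.05,
                         dct_cutoff = 10, background_threshold = NULL,
                         target_mode = c("moderate", "stringent"),
                         alpha = study$config$scan_alpha,
                         css_cutoff = study$config$css_cutoff) {
  target_mode <- match.arg(target_mode)
  design <- study$design

  ## miRNA branch: censor -> dCT -> detection -> differential
  ct <- censor_ct(study$mirna_ct_raw)
  dct <- normalize_delta_ct(ct, control_id = "U6")
  detected <- detection_filter(dct, cutoff = dct_cutoff)
  mirna_de <- differential_test(detected, design[colnames(detected)],
                                reference = reference, kind = "mirna")
  mirna_sets <- apply_thresholds(mirna_de, fc_cutoff, p_cutoff)

  ## mRNA branch: background -> differential -> probes to genes
  expr <- background_filter(study$mrna_matrix, background_threshold)
  mrna_de <- differential_test(expr, design[colnames(expr)],
                               reference = reference, kind = "mrna")
  mrna_sets <- apply_thresholds(mrna_de, fc_cutoff, p_cutoff)
  collapsed <- collapse_probes_to_genes(mrna_sets$significant,
                                        study$probe2gene)
  sig_genes <- collapsed$genes
  gene_up <- sig_genes$gene[sig_genes$direction == "up"]
  gene_down <- sig_genes$gene[sig_genes$direction == "down"]

  ## post-transcriptional arm: seed sites of significant miRNAs in the
  ## significant genes' UTRs, anti-correlated directions only
  sig_mirnas <- c(mirna_sets$up, mirna_sets$down)
  predictions <- predict_targets(
    study$mirna_seqs[sig_mirnas],
    study$utrs[intersect(names(study$utrs), sig_genes$gene)],
    mode = target_mode)
  pairs <- anticorrelated_pairs(mirna_sets$up, mirna_sets$down,
                                gene_up, gene_down, predictions)

  ## transcriptional arm: calibrated PWM scan of significant promoters
  pwm <- build_pwm(study$pwm_counts, id = "EBOX_SYN")
  gc <- study$config$gc_background
  bg_comp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  mc_seed <- (study$config$seed * 131 + 7) %% .Machine$integer.max
  mss_cutoff <- calibrate_threshold(pwm, bg_comp, alpha = alpha,
                                    seed = mc_seed)
  regions <- study$promoters[study$promoters$gene %in% sig_genes$gene, ,
                             drop = FALSE]
  scan <- if (nrow(regions)) {
    scan_promoters(pwm, regions, mss_cutoff, css_cutoff)
  } else {
    list(hits = data.frame(gene = character(), pwm = character(),
                           start = integer(), end = integer(),
                           strand = character(), core_score = numeric(),
                           matrix_score = numeric()),
         summary = list(n_sites = 0L, n_genes = 0L, genes = character()))
  }

  ## enrichment of each direction against the full gene universe
  universe <- unique(study$probe2gene$gene)
  enr <- function(lst) {
    if (!length(lst)) return(NULL)
    filter_and_rank(fisher_enrichment(lst, universe, study$genesets))
  }

  ## two-arm network
  network <- assemble_network(sig_genes, scan$hits, pairs)

  list(dct = dct, detected = detected,
       mirna_de = mirna_de, mirna_sets = mirna_sets,
       mrna_de = mrna_de, mrna_sets = mrna_sets,
       sig_genes = sig_genes,
       predictions = predictions, pairs = pairs,
       pwm = pwm, mss_cutoff = mss_cutoff, scan = scan,
       enrichment_up = enr(gene_up), enrichment_down = enr(gene_down),
       enrichment_all = enr(sig_genes$gene),
       network = network)
}
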