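#' Synthetic study generation
#'
#' Generates a complete synthetic knockdown-vs-wild-type study with known
#' planted truth: a log2 mRNA probe matrix with planted effects, a TaqMan
#' CT matrix (U6 control row, censoring at 35 cycles, planted ddCT shifts),
#' promoter sequences with planted PWM instances on both strands, 3'UTRs
#' with planted 8mer seed sites, mature miRNA sequences, and gene sets with
#' one planted enriched term. Background sequence is i.i.d. at a configured
#' GC fraction, and is actively scrubbed of chance motif/seed matches so
#' that the planted truth is exact (see the methods vignette).
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the profiled study design: 2 replicates per group,
#' planted |log2FC| = 2 mRNA effects, ddCT shifts of 3 cycles (8-fold),
#' promoters spanning 2 kb upstream of the TSS through a first exon, and a
#' dominant fraction of upregulated miRNAs.
#'
#' @param n_genes,n_mirnas Feature counts.
#' @param n_replicates_per_group Samples per group (default 2).
#' @param frac_de_genes_up,frac_de_genes_down Fractions of genes planted
#'   up/down (sum <= 1).
#' @param mrna_effect_log2 Planted |log2 fold change| for DE genes.
#' @param mrna_noise_sd Log2-scale noise SD.
#' @param frac_de_mirnas_up,frac_de_mirnas_down Fractions of miRNAs planted
#'   up/down.
#' @param mirna_effect_dct Planted |ddCT| shift in cycles (a negative shift
#'   of CT in the test group = higher expression = "up").
#' @param ct_noise_sd Per-well CT noise SD in cycles.
#' @param frac_undetected_mirnas Fraction of miRNAs emitted undetected /
#'   above the 35-cycle limit.
#' @param frac_background_genes Fraction of genes planted at/below
#'   background expression.
#' @param promoter_len_upstream Bases upstream of the TSS (default 2000).
#' @param first_exon_len First-exon length in bases.
#' @param utr_len 3'UTR length in bases.
#' @param gc_background GC fraction of background sequence.
#' @param n_motif_arm,n_mirna_arm,n_overlap Planted arm sizes (arm genes are
#'   drawn from the planted DE genes; overlap genes belong to both arms).
#' @param motif_mutations 0 (plant exact consensus) or 1 (one random
#'   substitution per planted instance, for threshold tests).
#' @param scan_alpha Per-window false-positive rate used to calibrate the
#'   scan cutoff that background promoters are scrubbed against.
#' @param css_cutoff Core-similarity cutoff used for scrubbing/scanning.
#' @param n_terms Number of gene sets (including the planted term).
#' @param seed Integer RNG seed.
#' @return Validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 200, n_mirnas = 40,
                              n_replicates_per_group = 2,
                              frac_de_genes_up = 0.08,
                              frac_de_genes_down = 0.08,
                              mrna_effect_log2 = 2,
                              mrna_noise_sd = 0.25,
                              frac_de_mirnas_up = 0.15,
                              frac_de_mirnas_down = 0.05,
                              mirna_effect_dct = 3,
                              ct_noise_sd = 0.25,
                              frac_undetected_mirnas = 0.3,
                              frac_background_genes = 0.15,
                              promoter_len_upstream = 2000,
                              first_exon_len = 300,
                              utr_len = 500,
                              gc_background = 0.5,
                              n_motif_arm = 12, n_mirna_arm = 9,
                              n_overlap = 4,
                              motif_mutations = 0,
                              scan_alpha = 0.01, css_cutoff = 0.75,
                              n_terms = 10,
                              seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      n_genes >= 1, n_mirnas >= 1, n_replicates_per_group >= 1,
      frac_de_genes_up >= 0, frac_de_genes_up <= 1,
      frac_de_genes_down >= 0, frac_de_genes_down <= 1,
      frac_de_genes_up + frac_de_genes_down <= 1,
      frac_de_mirnas_up + frac_de_mirnas_down <= 1,
      mrna_effect_log2 >= 0, mrna_noise_sd > 0, ct_noise_sd > 0,
      frac_undetected_mirnas >= 0, frac_undetected_mirnas < 1,
      frac_background_genes >= 0, frac_background_genes < 1,
      promoter_len_upstream > 0, promoter_len_upstream <= 2000,
      first_exon_len > 0, utr_len > 0,
      gc_background > 0, gc_background < 1,
      n_motif_arm >= 0, n_mirna_arm >= 0,
      n_overlap >= 0, n_overlap <= min(n_motif_arm, n_mirna_arm),
      motif_mutations %in% c(0, 1), scan_alpha > 0, scan_alpha <= 1,
      n_terms >= 1
    )
  })
  n_up <- round(cfg$frac_de_genes_up * cfg$n_genes)
  n_down <- round(cfg$frac_de_genes_down * cfg$n_genes)
  n_arm <- cfg$n_motif_arm + cfg$n_mirna_arm - cfg$n_overlap
  if (n_arm > n_up + n_down) {
    stop("planted arms need ", n_arm, " DE genes but only ",
         n_up + n_down, " are planted; increase the DE fractions")
  }
  if (cfg$n_mirna_arm > 0 &&
      round(cfg$frac_de_mirnas_up * cfg$n_mirnas) +
      round(cfg$frac_de_mirnas_down * cfg$n_mirnas) == 0) {
    stop("a planted miRNA arm requires planted DE miRNAs")
  }
  structure(cfg, class = "simulation_config")
}

.rand_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

.rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# replace positions [start0, start0+len) (0-based) of a string, keeping any
# position inside `protect` (two-column matrix of 0-based half-open spans)
.resample_span <- function(seq, start0, len, gc, protect = NULL) {
  pos <- start0:(start0 + len - 1L)
  if (!is.null(protect) && nrow(protect)) {
    inside <- vapply(pos, function(p) {
      any(p >= protect[, 1] & p < protect[, 2])
    }, logical(1))
    pos <- pos[!inside]
  }
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ch[pos + 1L] <- sample(c("A", "C", "G", "T"), length(pos),
                         replace = TRUE, prob = p)
  paste(ch, collapse = "")
}

# all moderate-mode match words for a mature sequence
.all_seed_words <- function(mature) {
  w <- seed_words(mature)
  unique(c(w$eightmer, w$m8, w$a1, w$wobble))
}

#' Generate a synthetic study
#'
#' Deterministic for a fixed seed. Planted mRNA effects are additive log2
#' shifts on the test-group means of chosen genes; planted miRNA effects
#' are ddCT shifts; planted promoter motifs are consensus (or one-mutation)
#' instances of the PWM on either strand; planted UTR sites are exact 8mer
#' seed complements; one gene set is preferentially composed of planted DE
#' genes. Background promoter windows reaching the scan cutoffs and
#' background UTR occurrences of any DE-miRNA seed word are resampled away
#' so planted truth is exact.
#'
#' @param config A [simulation_config()].
#' @param pwm_counts Optional 4 x L count matrix for the planted motif
#'   (default [ebox_counts()]).
#' @return List of class `"synthetic_study"` with elements `mrna_matrix`,
#'   `mirna_ct` (censored, includes the U6 row), `mirna_ct_raw` (undetected
#'   wells as `NA`, values above 35 uncensored), `design`, `probe2gene`,
#'   `promoters`, `utrs`, `mirna_seqs`, `genesets`, `pwm_counts`, `config`,
#'   and `truth` (planted DE sets, arm memberships, site tables, enriched
#'   term, calibrated scan cutoffs).
#' @export
generate_study <- function(config, pwm_counts = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  n_rep <- cfg$n_replicates_per_group
  samples <- c(sprintf("wt_%d", seq_len(n_rep)),
               sprintf("kd_%d", seq_len(n_rep)))
  design <- stats::setNames(rep(c("wt", "kd"), each = n_rep), samples)

  ## ---- planted gene truth -------------------------------------------------
  n_up <- round(cfg$frac_de_genes_up * cfg$n_genes)
  n_down <- round(cfg$frac_de_genes_down * cfg$n_genes)
  de <- sample(genes, n_up + n_down)
  de_up <- de[seq_len(n_up)]
  de_down <- setdiff(de, de_up)
  n_bg <- round(cfg$frac_background_genes * cfg$n_genes)
  bg_genes <- sample(setdiff(genes, de), n_bg)

  n_arm <- cfg$n_motif_arm + cfg$n_mirna_arm - cfg$n_overlap
  arm_pool <- sample(de, n_arm)
  overlap_genes <- arm_pool[seq_len(cfg$n_overlap)]
  motif_only <- arm_pool[seq_len(cfg$n_motif_arm - cfg$n_overlap) +
                           cfg$n_overlap]
  mirna_only <- setdiff(arm_pool, c(overlap_genes, motif_only))
  motif_arm <- sort(c(overlap_genes, motif_only))
  mirna_arm <- sort(c(overlap_genes, mirna_only))

  ## ---- planted miRNA truth ------------------------------------------------
  n_mi_up <- round(cfg$frac_de_mirnas_up * cfg$n_mirnas)
  n_mi_down <- round(cfg$frac_de_mirnas_down * cfg$n_mirnas)
  de_mi <- sample(mirnas, n_mi_up + n_mi_down)
  mi_up <- de_mi[seq_len(n_mi_up)]
  mi_down <- setdiff(de_mi, mi_up)
  n_undet <- round(cfg$frac_undetected_mirnas * cfg$n_mirnas)
  undet <- sample(setdiff(mirnas, de_mi), min(n_undet,
                                              cfg$n_mirnas - length(de_mi)))

  ## mature sequences; DE miRNA seed-match words are kept pairwise distant
  ## (Hamming >= 2 across all 7-mer words) so planted sites of one miRNA can
  ## never chance-match another's seed
  mirna_seqs <- character(cfg$n_mirnas)
  names(mirna_seqs) <- mirnas
  accepted_words <- character(0)
  for (m in mirnas) {
    repeat {
      s <- .rand_rna(22)
      if (!m %in% de_mi) { mirna_seqs[m] <- s; break }
      w <- seed_words(s)
      cand <- c(w$m8, substr(w$a1, 1, 7))
      ok <- all(vapply(cand, function(a) {
        all(vapply(accepted_words, function(b) .hamming(a, b) >= 2,
                   logical(1)))
      }, logical(1)))
      if (ok) {
        mirna_seqs[m] <- s
        accepted_words <- c(accepted_words, cand)
        break
      }
    }
  }

  ## ---- mRNA matrix --------------------------------------------------------
  base_mean <- stats::setNames(stats::runif(cfg$n_genes, 6.5, 12), genes)
  planted_idx <- unique(c(de, arm_pool))
  base_mean[planted_idx] <- stats::runif(length(planted_idx), 8, 11)
  base_mean[bg_genes] <- stats::runif(n_bg, 2.5, 3.5)
  shift <- stats::setNames(numeric(cfg$n_genes), genes)
  shift[de_up] <- cfg$mrna_effect_log2
  shift[de_down] <- -cfg$mrna_effect_log2

  multi <- sample(genes, round(0.2 * cfg$n_genes))
  probe_gene <- c(genes, multi)
  o <- order(probe_gene)
  probe_gene <- probe_gene[o]
  probes <- sprintf("p%05d", seq_along(probe_gene))
  probe2gene <- data.frame(probe = probes, gene = probe_gene,
                           stringsAsFactors = FALSE)

  mrna <- matrix(0, length(probes), length(samples),
                 dimnames = list(probes, samples))
  for (i in seq_along(probes)) {
    g <- probe_gene[i]
    mu <- c(rep(base_mean[g], n_rep), rep(base_mean[g] + shift[g], n_rep))
    mrna[i, ] <- mu + stats::rnorm(length(samples), 0, cfg$mrna_noise_sd)
  }

  ## ---- miRNA CT matrix ----------------------------------------------------
  ct_base <- stats::setNames(stats::runif(cfg$n_mirnas, 22, 28), mirnas)
  ct_base[de_mi] <- stats::runif(length(de_mi), 23, 26.5)
  ct_shift <- stats::setNames(numeric(cfg$n_mirnas), mirnas)
  ct_shift[mi_up] <- -cfg$mirna_effect_dct   # lower CT = higher expression
  ct_shift[mi_down] <- cfg$mirna_effect_dct

  ct_raw <- matrix(0, cfg$n_mirnas + 1, length(samples),
                   dimnames = list(c(mirnas, "U6"), samples))
  for (m in mirnas) {
    if (m %in% undet) {
      v <- stats::runif(length(samples), 36, 39)
      v[sample(length(samples), ceiling(length(samples) / 2))] <- NA
      ct_raw[m, ] <- v
    } else {
      mu <- c(rep(ct_base[m], n_rep), rep(ct_base[m] + ct_shift[m], n_rep))
      ct_raw[m, ] <- mu + stats::rnorm(length(samples), 0, cfg$ct_noise_sd)
    }
  }
  ct_raw["U6", ] <- stats::rnorm(length(samples), 20, 0.1)
  ct <- censor_ct(ct_raw)

  ## ---- promoters with planted, scrubbed motifs ----------------------------
  if (is.null(pwm_counts)) pwm_counts <- ebox_counts()
  pwm <- build_pwm(pwm_counts, id = "EBOX_SYN")
  L <- pwm$width
  bg_comp <- c(A = (1 - cfg$gc_background) / 2, C = cfg$gc_background / 2,
               G = cfg$gc_background / 2, T = (1 - cfg$gc_background) / 2)
  mc_seed <- (cfg$seed * 131 + 7) %% .Machine$integer.max
  mss_cutoff <- calibrate_threshold(pwm, bg_comp, alpha = cfg$scan_alpha,
                                    seed = mc_seed)

  plen <- cfg$promoter_len_upstream + cfg$first_exon_len
  proms <- do.call(rbind, lapply(genes, function(g) {
    promoter_region(g, .rand_dna(plen, cfg$gc_background),
                    cfg$promoter_len_upstream, plen)
  }))

  # scrub chance hits from all background promoters
  for (iter in 1:50) {
    sc <- scan_promoters(pwm, proms, mss_cutoff, cfg$css_cutoff)
    if (nrow(sc$hits) == 0) break
    for (r in seq_len(nrow(sc$hits))) {
      h <- sc$hits[r, ]
      i <- match(h$gene, proms$gene)
      proms$seq[i] <- .resample_span(proms$seq[i],
                                     h$start + proms$tss_offset[i], L,
                                     cfg$gc_background)
    }
    if (iter == 50) stop("promoter scrubbing did not converge")
  }

  # plant consensus instances in motif-arm promoters
  consensus <- pwm_consensus(pwm)
  motif_sites <- NULL
  for (g in motif_arm) {
    i <- match(g, proms$gene)
    for (attempt in 1:30) {
      n_sites <- sample(1:3, 1)
      max_start <- proms$exon_end[i] - L
      starts <- sort(sample(seq(0, max_start, by = L), n_sites))
      strands <- sample(c("+", "-"), n_sites, replace = TRUE)
      seq_try <- proms$seq[i]
      for (k in seq_len(n_sites)) {
        word <- consensus
        if (cfg$motif_mutations == 1) {
          pos <- sample(L, 1)
          ch <- strsplit(word, "")[[1]]
          ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
          word <- paste(ch, collapse = "")
        }
        if (strands[k] == "-") word <- .revcomp_chr(word)
        substr(seq_try, starts[k] + 1L, starts[k] + L) <- word
      }
      planted <- cbind(starts, starts + L)
      hits <- scan_region(pwm, data.frame(gene = g, seq = seq_try,
                                          tss_offset = proms$tss_offset[i],
                                          exon_end = proms$exon_end[i],
                                          stringsAsFactors = FALSE),
                          mss_cutoff, cfg$css_cutoff)
      abs_start <- hits$start + proms$tss_offset[i]
      spurious <- !(abs_start %in% starts)
      if (!any(spurious)) {
        proms$seq[i] <- seq_try
        motif_sites <- rbind(motif_sites, data.frame(
          gene = g, start = starts - proms$tss_offset[i],
          strand = strands, stringsAsFactors = FALSE))
        break
      }
      # junction artifacts: resample outside planted spans and retry
      for (r in which(spurious)) {
        seq_try <- .resample_span(seq_try, abs_start[r], L,
                                  cfg$gc_background, protect = planted)
      }
      hits2 <- scan_region(pwm, data.frame(gene = g, seq = seq_try,
                                           tss_offset = proms$tss_offset[i],
                                           exon_end = proms$exon_end[i],
                                           stringsAsFactors = FALSE),
                           mss_cutoff, cfg$css_cutoff)
      if (all((hits2$start + proms$tss_offset[i]) %in% starts)) {
        proms$seq[i] <- seq_try
        motif_sites <- rbind(motif_sites, data.frame(
          gene = g, start = starts - proms$tss_offset[i],
          strand = strands, stringsAsFactors = FALSE))
        break
      }
      if (attempt == 30) stop("motif planting did not converge for ", g)
    }
  }

  ## ---- UTRs with planted, scrubbed seed sites -----------------------------
  utrs <- stats::setNames(
    vapply(genes, function(g) .rand_dna(cfg$utr_len, cfg$gc_background),
           character(1)), genes)
  de_words <- unique(unlist(lapply(de_mi, function(m) {
    .all_seed_words(mirna_seqs[[m]])
  })))
  scrub_utrs <- function(utrs, protect_by_gene) {
    for (iter in 1:50) {
      dirty <- FALSE
      for (g in names(utrs)) {
        protect <- protect_by_gene[[g]]
        for (w in de_words) {
          occ <- .find_word(w, utrs[[g]])
          for (p in occ) {
            # covered = every position lies inside the union of planted spans
            covered <- !is.null(protect) && nrow(protect) &&
              all(vapply(p:(p + nchar(w) - 1L), function(q) {
                any(q >= protect[, 1] & q < protect[, 2])
              }, logical(1)))
            if (!covered) {
              utrs[[g]] <- .resample_span(utrs[[g]], p, nchar(w),
                                          cfg$gc_background,
                                          protect = protect)
              dirty <- TRUE
            }
          }
        }
      }
      if (!dirty) return(utrs)
    }
    stop("UTR scrubbing did not converge")
  }
  utrs <- scrub_utrs(utrs, stats::setNames(vector("list", length(genes)),
                                           genes))

  # assign opposite-direction DE miRNAs to miRNA-arm genes and plant 8mers
  gene_dir <- stats::setNames(rep("up", length(de)), de)
  gene_dir[de_down] <- "down"
  mirna_sites <- NULL
  protect_by_gene <- stats::setNames(vector("list", length(genes)), genes)
  for (g in mirna_arm) {
    pool <- if (gene_dir[[g]] == "down") mi_up else mi_down
    if (!length(pool)) {
      stop("no DE miRNA of the direction opposite to arm gene ", g)
    }
    n_m <- min(sample(1:2, 1), length(pool))
    ms <- sample(pool, n_m)
    max_start <- cfg$utr_len - 8L
    starts <- sample(seq(0, max_start, by = 8L), n_m)
    for (k in seq_len(n_m)) {
      word <- seed_words(mirna_seqs[[ms[k]]])$eightmer
      u <- utrs[[g]]
      substr(u, starts[k] + 1L, starts[k] + 8L) <- word
      utrs[[g]] <- u
      protect_by_gene[[g]] <- rbind(protect_by_gene[[g]],
                                    c(starts[k], starts[k] + 8L))
      mirna_sites <- rbind(mirna_sites, data.frame(
        mirna = ms[k], gene = g, start = starts[k],
        stringsAsFactors = FALSE))
    }
  }
  utrs <- scrub_utrs(utrs, protect_by_gene)

  ## ---- gene sets ----------------------------------------------------------
  terms <- sprintf("GS%02d", seq_len(cfg$n_terms))
  planted_term <- terms[1]
  genesets <- vector("list", cfg$n_terms)
  names(genesets) <- terms
  n_members <- min(15, length(de) + 3)
  n_from_de <- min(round(0.8 * n_members), length(de))
  genesets[[planted_term]] <- sort(c(
    sample(de, n_from_de),
    sample(setdiff(genes, de), n_members - n_from_de)))
  for (t in terms[-1]) {
    genesets[[t]] <- sort(sample(genes, sample(10:30, 1)))
  }

  structure(list(
    mrna_matrix = mrna,
    mirna_ct = ct,
    mirna_ct_raw = ct_raw,
    design = design,
    probe2gene = probe2gene,
    promoters = proms,
    utrs = utrs,
    mirna_seqs = mirna_seqs,
    genesets = genesets,
    pwm_counts = pwm_counts,
    config = cfg,
    truth = list(
      de_genes_up = sort(de_up), de_genes_down = sort(de_down),
      background_genes = sort(bg_genes),
      de_mirnas_up = sort(mi_up), de_mirnas_down = sort(mi_down),
      undetected_mirnas = sort(undet),
      motif_arm = motif_arm, mirna_arm = mirna_arm,
      overlap = sort(overlap_genes),
      motif_sites = motif_sites,
      mirna_sites = mirna_sites,
      enriched_term = planted_term,
      mss_cutoff = mss_cutoff, css_cutoff = cfg$css_cutoff
    )
  ), class = "synthetic_study")
}

#' Write a synthetic study to a directory
#'
#' Emits TSV matrices (`mrna_matrix.tsv`, `mirna_ct.tsv` with undetected
#' wells as `Undetermined`, `design.tsv`, `probe2gene.tsv`), FASTA
#' sequences (`promoters.fa` with `gene|tss_offset|exon_end` headers,
#' `utrs.fa`, `mirnas.fa`), `genesets.gmt`, the planted count matrix in
#' TRANSFAC format (`pwm.transfac`), and a JSON truth manifest
#' (`truth.json`). Files round-trip through [read_study()].
#'
#' @param study A `"synthetic_study"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(
    "mrna_matrix.tsv", "mirna_ct.tsv", "design.tsv", "probe2gene.tsv",
    "promoters.fa", "utrs.fa", "mirnas.fa", "genesets.gmt",
    "pwm.transfac", "truth.json"))
  write_matrix_tsv(study$mrna_matrix, paths[1], id_col = "probe")
  write_ct_tsv(study$mirna_ct_raw, paths[2])
  write_design_tsv(study$design, paths[3])
  utils::write.table(study$probe2gene, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_promoters_fasta(study$promoters, paths[5])
  write_seqs_fasta(study$utrs, paths[6], alphabet = "dna")
  write_seqs_fasta(study$mirna_seqs, paths[7], alphabet = "rna")
  write_gmt(study$genesets, paths[8])
  write_transfac(study$pwm_counts, paths[9], id = "EBOX_SYN")
  jsonlite::write_json(study$truth, paths[10], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a written synthetic study back
#'
#' @param dir Directory written by [write_study()].
#' @return List with elements `mrna_matrix`, `mirna_ct_raw`, `design`,
#'   `probe2gene`, `promoters`, `utrs`, `mirna_seqs`, `genesets`,
#'   `pwm_counts`, `truth`.
#' @export
read_study <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(
    mrna_matrix = read_matrix_tsv(file.path(dir, "mrna_matrix.tsv")),
    mirna_ct_raw = read_ct_tsv(file.path(dir, "mirna_ct.tsv")),
    design = read_design_tsv(file.path(dir, "design.tsv")),
    probe2gene = utils::read.delim(file.path(dir, "probe2gene.tsv"),
                                   stringsAsFactors = FALSE),
    promoters = read_promoters_fasta(file.path(dir, "promoters.fa")),
    utrs = read_seqs_fasta(file.path(dir, "utrs.fa"), "dna"),
    mirna_seqs = read_seqs_fasta(file.path(dir, "mirnas.fa"), "rna"),
    genesets = read_gmt(file.path(dir, "genesets.gmt")),
    pwm_counts = read_transfac(file.path(dir, "pwm.transfac"))[[1]]$counts,
    truth = truth
  )
}
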