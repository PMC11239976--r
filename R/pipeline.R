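#' Default analysis parameters
#'
#' The bespoke statistics' defaults in one place: 250-bp ESA flanks,
#' 1-Mb accessibility windows, zygotic selection at fold > 2 and
#' P < 1e-10 with a total-count floor of 10, top-150 germline-biased
#' genes with 500-bp upstream promoters, germline inclusion floor 1 and
#' soma pseudocount 0.01, expression-ratio floor 0.01.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(flank = 250, esa_pseudocount = 1, window = 1e6,
       window_pseudo = 0.1, tss_span = 2000, tss_core = 50,
       tss_flank_norm = 100, fold_min = 2, p_max = 1e-10,
       min_total = 10, ratio_floor = 0.01, n_top = 150, upstream = 500,
       floor_g = 1, pseudo_s = 0.01, motif_threshold = 0.8,
       motif_halfwin = 50, normalize_to = "2L")
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# stage pairs (female cluster, male cluster) per post-activation stage
.stage_pairs <- function(cluster_meta) {
  meta <- cluster_meta[!is.na(cluster_meta$stage) &
                         cluster_meta$stage >= 1 &
                         !is.na(cluster_meta$sex), ]
  stages <- sort(unique(meta$stage))
  pairs <- do.call(rbind, lapply(stages, function(s) {
    f <- meta$cluster[meta$stage == s & meta$sex == "F"]
    m <- meta$cluster[meta$stage == s & meta$sex == "M"]
    if (length(f) == 1 && length(m) == 1) {
      data.frame(stage = as.character(s), female = f, male = m,
                 stringsAsFactors = FALSE)
    }
  }))
  pairs
}

#' Run the full synthetic analysis end to end
#'
#' Simulates a complete multiome input set from `config`, then runs every
#' analysis stage -- cut-site statistics (ESA, TSS enrichment, FRiP,
#' fragment sizes, windowed accessibility with female/male ratios,
#' chromosome tallies), expression analyses (NB differential expression,
#' zygotic gene selection, sex expression ratios, sex-biased ranking),
#' germline-to-soma bias with promoter extraction (plus motif-site
#' accessibility and PCA when a genome and PWMs are available), and
#' imaging normalization -- writing one TSV per table into `out_dir`
#' plus a machine-readable `summary.json` echoing all parameters.
#' Deterministic: identical configurations produce identical outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A `SimConfig`.
#' @param params Analysis parameters, see [default_params()]; partial
#'   lists are merged over the defaults.
#' @param pwms Optional list of `MotifPWM`s for the motif-accessibility
#'   stage (requires `config$make_genome`).
#' @param use_peaks Set `FALSE` to skip FRiP (logged, not an error).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         params = list(), pwms = NULL,
                         use_peaks = TRUE) {
  p <- utils::modifyList(default_params(), params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(parameters = p, seed = config$seed, stages = list())

  ann <- make_toy_annotation(config)
  sim <- simulate_fragments(config, ann)
  cuts <- build_cut_sites(sim$fragments, sim$clusters)
  .write_tsv(as.data.frame(ann$genes), out_dir, "genes")

  esa <- compute_esa(cuts, ann$genes, flank = p$flank,
                     pseudocount = p$esa_pseudocount)
  .write_tsv(as.data.frame(esa), out_dir, "esa")
  ok <- !esa$windows_overlap
  esa_median <- tapply(esa$esa[ok], esa$cluster[ok], median)
  summary$stages$esa <- as.list(esa_median)

  te <- tss_enrichment(cuts, ann$genes, span = p$tss_span,
                       core = p$tss_core, flank_norm = p$tss_flank_norm)
  .write_tsv(te$scores, out_dir, "tss_enrichment")
  summary$stages$tss_enrichment <- setNames(as.list(te$scores$score),
                                            te$scores$cluster)

  if (use_peaks) {
    fp <- frip(sim$fragments, ann$peaks, sim$clusters)
    .write_tsv(fp$per_cluster, out_dir, "frip")
    summary$stages$frip_median <- setNames(as.list(fp$per_cluster$median),
                                           fp$per_cluster$cluster)
  } else {
    gc_log("run_pipeline: no peaks supplied, skipping FRiP")
    summary$stages$frip_median <- NULL
  }

  fs <- fragment_size_distribution(sim$fragments, sim$clusters)
  .write_tsv(fs, out_dir, "fragment_sizes")

  wa <- windowed_accessibility(cuts, ann$chrom_sizes, window = p$window)
  .write_tsv(as.data.frame(wa), out_dir, "window_accessibility")
  pairs <- .stage_pairs(sim$clusters$clusters)
  acc_ratios <- list()
  for (i in seq_len(NROW(pairs))) {
    sr <- sex_ratio_windows(wa, pairs$female[i], pairs$male[i],
                            pseudo = p$window_pseudo)
    .write_tsv(sr$chromosomes, out_dir,
               paste0("accessibility_ratio_stage", pairs$stage[i]))
    acc_ratios[[pairs$stage[i]]] <-
      setNames(as.list(sr$chromosomes$mean_ratio), sr$chromosomes$chrom)
  }
  summary$stages$accessibility_fm_ratio <- acc_ratios

  tal <- chromosome_tallies(cuts, normalize_to = p$normalize_to)
  .write_tsv(tal, out_dir, "chromosome_tallies")

  cs <- simulate_counts(config, ann)
  norm <- normalize_counts(cs$matrix)
  meta <- cs$clusters$clusters
  pre <- meta$cluster[!is.na(meta$stage) & meta$stage == 0]
  post2 <- meta$cluster[!is.na(meta$stage) & meta$stage == 2]
  de <- nb_wald_de(cs$matrix, cs$clusters, group_A = post2,
                   group_B = pre, min_total = p$min_total)
  .write_tsv(as.data.frame(de), out_dir, "de_activation")
  zyg <- select_zygotic_genes(de, fold_min = p$fold_min, p_max = p$p_max)
  writeLines(zyg, file.path(out_dir, "zygotic_genes.txt"))
  summary$stages$n_zygotic <- length(zyg)

  if (length(zyg) && NROW(pairs)) {
    dr <- sex_expression_ratios(norm$matrix, cs$clusters, zyg,
                                pairs, ann$genes, floor = p$ratio_floor)
    .write_tsv(dr$per_chromosome, out_dir, "expression_ratio_chromosomes")
    summary$stages$expression_fm_ratio <- lapply(
      split(dr$per_chromosome, dr$per_chromosome$stage),
      function(d) setNames(as.list(d$mean_ratio), d$chrom))
  }
  for (i in seq_len(NROW(pairs))) {
    de_mf <- nb_wald_de(cs$matrix, cs$clusters,
                        group_A = pairs$male[i],
                        group_B = pairs$female[i],
                        min_total = p$min_total)
    .write_tsv(rank_sex_biased(de_mf), out_dir,
               paste0("male_biased_rank_stage", pairs$stage[i]))
  }

  post <- meta$cluster[!is.na(meta$stage) & meta$stage >= 1]
  bc <- cs$clusters$barcodes
  nuclear <- do.call(rbind, lapply(post, function(cl) {
    cells <- bc$barcode[bc$cluster == cl]
    data.frame(cluster = cl, gene_id = rownames(norm$matrix),
               value = as.numeric(Matrix::rowMeans(
                 norm$matrix[, cells, drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  bias <- germline_soma_ratio(nuclear, cs$soma_signal,
                              floor_g = p$floor_g, pseudo_s = p$pseudo_s)
  .write_tsv(as.data.frame(bias), out_dir, "germline_soma_bias")
  tops <- lapply(post, function(cl) top_n_genes(bias, cl, n = p$n_top))
  names(tops) <- post
  for (cl in post) {
    .write_tsv(tops[[cl]], out_dir, paste0("top_genes_", cl))
  }
  proms <- promoter_regions(ann$genes, tops[[post[1]]]$gene_id,
                            upstream = p$upstream)
  .write_tsv(as.data.frame(proms), out_dir, "promoters")
  if (!is.null(ann$genome)) {
    write_fasta(proms, ann$genome,
                file.path(out_dir, "promoters.fasta"))
    if (!is.null(pwms)) {
      scan_seqs <- region_sequences(ann$peaks, ann$genome,
                                    strand_aware = FALSE)
      hits <- scan_motifs(pwms, scan_seqs, regions = ann$peaks,
                          threshold_frac = p$motif_threshold)
      tam <- motif_accessibility_index(cuts, hits, ann$peaks,
                                       halfwin = p$motif_halfwin)
      .write_tsv(data.frame(cluster = rownames(tam), tam,
                            check.names = FALSE), out_dir,
                 "motif_accessibility")
      if (all(is.finite(tam)) && ncol(tam) >= 2) {
        pca <- tf_pca(tam, n_components = min(2, nrow(tam) - 1))
        .write_tsv(data.frame(cluster = rownames(pca$scores),
                              pca$scores), out_dir, "tf_pca_scores")
        summary$stages$tf_pca_var_frac <- pca$var_frac
      }
    }
  } else {
    gc_log("run_pipeline: no genome in config, skipping motif stages")
  }

  nuc <- simulate_nuclei(config)
  h3 <- normalize_h3(nuc$records)
  cmp <- compare_h3_groups(h3)
  .write_tsv(cmp$tests, out_dir, "h3_tests")
  .write_tsv(cmp$summary, out_dir, "h3_summary")
  summary$stages$h3_p <- setNames(as.list(cmp$tests$p), cmp$tests$stage)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
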