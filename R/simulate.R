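#' Configuration for the synthetic multiome generator
#'
#' Collects every parameter of the synthetic genome, fragment, count and
#' imaging generators into one list, with defaults that emulate the
#' embryonic germline study design: five chromosome arms with a short X,
#' germline clusters before and after zygotic activation for both sexes,
#' TSS-concentrated accessibility in female clusters with a decondensed
#' first male stage, partial X dosage compensation (male per-copy boost
#' 1.6 on both the chromatin and expression side), a bimodal
#' subnucleosomal/mononucleosomal fragment-length mixture, and
#' gonad-grouped nucleus intensities. One master seed deterministically
#' derives independent sub-seeds for the annotation, fragment, count and
#' imaging streams so each can be regenerated on its own.
#'
#' @param seed Master seed (integer).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_genes Named gene counts per chromosome.
#' @param clusters data.frame with columns `cluster`, `sex` (`F`/`M`/NA),
#'   `stage` (0 = pre-activation), `lineage`, `n_cells`,
#'   `frags_per_cell`, `theta_tss` (fraction of cut placements drawn from
#'   a TSS-centered normal), `x_boost` (male per-copy X weight).
#' @param tss_sd SD (bp) of the TSS-centered placement component.
#' @param frag_len Fragment-length mixture: `w_sub` subnucleosomal weight,
#'   normal components `(mu_sub, sd_sub)` and `(mu_mono, sd_mono)`,
#'   clamped to `[min, max]`.
#' @param counts Count-model parameters: lognormal baseline NB means
#'   (`baseline_meanlog`, `baseline_sdlog`), NB `dispersion`, the planted
#'   activation design (`n_activated`, `activation_fold`), the male X
#'   per-copy expression factor `x_factor`, and the male-biased gene
#'   design (`n_sex_biased`, `sex_fold_range`).
#' @param imaging Imaging-model parameters: stages, planted germ/SGP H3
#'   ratios per sex and stage, gonads and nuclei per group, per-gonad
#'   lognormal gain SD and intensity noise SD.
#' @param make_genome Generate an i.i.d. uniform-base genome FASTA in
#'   [make_toy_annotation()] (memory-heavy for multi-Mb configurations;
#'   intended for the compact sequence-analysis presets).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(
    seed = 1L,
    chrom_lengths = c(`2L` = 8e6, `2R` = 8e6, `3L` = 8e6, `3R` = 8e6,
                      X = 1.6e6),
    n_genes = c(`2L` = 120, `2R` = 120, `3L` = 120, `3R` = 120, X = 25),
    clusters = data.frame(
      cluster = c("GC", "FGC1", "MGC1", "FGC2", "MGC2"),
      sex = c(NA, "F", "M", "F", "M"),
      stage = c(0L, 1L, 1L, 2L, 2L),
      lineage = "germline",
      n_cells = 200L,
      frags_per_cell = 500,
      theta_tss = c(0.3, 0.6, 0.1, 0.6, 0.3),
      x_boost = c(1, 1, 1.6, 1, 1.6),
      stringsAsFactors = FALSE),
    tss_sd = 75,
    frag_len = list(w_sub = 0.55, mu_sub = 75, sd_sub = 25,
                    mu_mono = 200, sd_mono = 30, min = 20, max = 600),
    counts = list(baseline_meanlog = log(2), baseline_sdlog = 1,
                  dispersion = 0.3, n_activated = 50,
                  activation_fold = 4, x_factor = 1.6,
                  n_sex_biased = 20, sex_fold_range = c(1.5, 8)),
    imaging = list(stages = c("s9-10", "s17", "L3"),
                   germ_ratio = list(
                     F = c(`s9-10` = 1.0, s17 = 0.8, L3 = 0.8),
                     M = c(`s9-10` = 0.7, s17 = 1.0, L3 = 1.0)),
                   n_gonads = 10, n_germ = 10, n_sgp = 8,
                   gain_sdlog = 0.3, noise_sdlog = 0.2),
    make_genome = FALSE) {
  stopifnot(identical(sort(names(chrom_lengths)), sort(names(n_genes))),
            all(clusters$theta_tss >= 0), all(clusters$theta_tss <= 1),
            all(clusters$x_boost > 0), all(clusters$frags_per_cell > 0))
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_genes = n_genes, clusters = clusters, tss_sd = tss_sd,
                 frag_len = frag_len, counts = counts, imaging = imaging,
                 make_genome = make_genome),
            class = "SimConfig")
}

#' Compact configuration for sequence- and ESA-scale analyses
#'
#' A small-genome variant of [sim_config()] (1.8 Mb total, 180 genes) at
#' which a few hundred thousand cut sites give tens of cuts per 500-bp
#' window, the regime where per-gene ESA ratios are stable; also the
#' preset used for genome-sequence work (promoters, motif scanning).
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `SimConfig`.
#' @export
sim_config_compact <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    chrom_lengths = c(`2L` = 4e5, `2R` = 4e5, `3L` = 4e5, `3R` = 4e5,
                      X = 2e5),
    n_genes = c(`2L` = 40, `2R` = 40, `3L` = 40, `3R` = 40, X = 20),
    make_genome = TRUE, ...)
}

# deterministic sub-seed per stream, kept well below 2^31
.sub_seed <- function(seed, k) {
  (abs(seed) %% 100000L) * 10007L + k
}

#' Generate a toy annotation: gene models, chromosome sizes, peaks, genome
#'
#' Genes are laid out in equal slots along each chromosome with seeded
#' jitter, lengths drawn uniformly from 2-6 kb, strands alternating; each
#' gene's peak is the TSS +/- 250 bp interval. With `cfg$make_genome`, an
#' i.i.d. uniform-base genome is generated. Deterministic given the
#' configuration seed.
#'
#' @param cfg A `SimConfig`.
#' @return List with `genes` (`GeneModelSet`), `chrom_sizes`, `peaks`
#'   (`IntervalSet`), and `genome` (`DNAStringSet` or `NULL`).
#' @export
make_toy_annotation <- function(cfg) {
  set.seed(.sub_seed(cfg$seed, 1L))
  gene_rows <- list()
  for (ch in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[ch]]
    n <- cfg$n_genes[[ch]]
    slot <- floor(len / n)
    if (slot < 8000) {
      stop("chromosome ", ch, " too small for ", n,
           " genes (needs >= 8 kb per gene)")
    }
    glen <- sample(2000:6000, n, replace = TRUE)
    jitter_max <- slot - glen - 2000L
    offset <- 1000L + floor(runif(n) * pmax(jitter_max - 1000L, 1L))
    a <- (seq_len(n) - 1L) * slot + offset + 1L   # 1-based gene start
    strand <- rep(c("+", "-"), length.out = n)
    gene_rows[[ch]] <- data.frame(
      gene_id = sprintf("g%s_%03d", ch, seq_len(n)),
      name = sprintf("g%s_%03d", ch, seq_len(n)),
      chrom = ch, strand = strand,
      tss = ifelse(strand == "+", a, a + glen - 1L),
      end3 = ifelse(strand == "+", a + glen - 1L, a),
      stringsAsFactors = FALSE)
  }
  genes <- as_gene_model_set(do.call(rbind, gene_rows),
                             cfg$chrom_lengths)
  t0 <- genes$tss - 1L
  peaks <- as_interval_set(data.frame(
    chrom = genes$chrom,
    start = pmax(t0 - 250L, 0L),
    end = pmin(t0 + 251L, unname(cfg$chrom_lengths[genes$chrom])),
    name = genes$gene_id, stringsAsFactors = FALSE))
  genome <- NULL
  if (isTRUE(cfg$make_genome)) {
    genome <- Biostrings::DNAStringSet(vapply(
      names(cfg$chrom_lengths), function(ch) {
        paste(sample(c("A", "C", "G", "T"), cfg$chrom_lengths[[ch]],
                     replace = TRUE), collapse = "")
      }, ""))
    names(genome) <- names(cfg$chrom_lengths)
  }
  list(genes = genes, chrom_sizes = cfg$chrom_lengths, peaks = peaks,
       genome = genome)
}

# diploid copy weights: autosomes carry 2 copies in both sexes; the X
# carries 2 in females and a single x_boost-weighted copy in males (1.5
# for unsexed, mixed clusters)
.x_weight <- function(sex, x_boost) {
  if (is.na(sex)) 1.5 else if (sex == "F") 2 else x_boost
}

#' Simulate scATAC fragments with a known placement model
#'
#' Per cell, a Poisson number of fragments; each fragment picks a
#' chromosome with probability proportional to length times the diploid
#' copy weight (autosomes 2 in both sexes; X: 2 in females, `x_boost`
#' in males, 1.5 unsexed), then a center either from a normal around a
#' random gene TSS on
#' that chromosome (with probability `theta_tss`, SD `tss_sd`) or
#' uniformly, and a length from the bimodal mixture. Coordinates are
#' emitted already in fragment-file convention (0-based half-open), no
#' further Tn5 shifting is applied.
#'
#' @param cfg A `SimConfig`.
#' @param annotation Output of [make_toy_annotation()].
#' @return List with `fragments` (`FragmentSet`) and `clusters`
#'   (`ClusterAssignment`).
#' @export
simulate_fragments <- function(cfg, annotation) {
  set.seed(.sub_seed(cfg$seed, 2L))
  sizes <- annotation$chrom_sizes
  genes <- annotation$genes
  chroms <- names(sizes)
  tss_by_chrom <- split(genes$tss - 1L, genes$chrom)
  frag_rows <- list()
  bc_rows <- list()
  for (i in seq_len(nrow(cfg$clusters))) {
    cl <- cfg$clusters[i, ]
    wts <- unname(sizes[chroms]) *
      ifelse(chroms == "X", .x_weight(cl$sex, cl$x_boost), 2)
    n_per_cell <- rpois(cl$n_cells, cl$frags_per_cell)
    barcodes <- sprintf("%s_%04d", cl$cluster, seq_len(cl$n_cells))
    total <- sum(n_per_cell)
    if (total == 0) next
    chrom <- sample(chroms, total, replace = TRUE, prob = wts)
    center <- numeric(total)
    at_tss <- runif(total) < cl$theta_tss
    for (ch in chroms) {
      sel <- chrom == ch
      n_sel <- sum(sel)
      if (!n_sel) next
      cen <- floor(runif(n_sel) * sizes[[ch]])
      tss_sel <- sel & at_tss
      n_tss <- sum(tss_sel)
      tss_vec <- tss_by_chrom[[ch]]
      if (n_tss && length(tss_vec)) {
        anchors <- tss_vec[sample.int(length(tss_vec), n_tss,
                                      replace = TRUE)]
        cen[at_tss[sel]] <- round(rnorm(n_tss, anchors, cfg$tss_sd))
      }
      center[sel] <- cen
    }
    fl <- cfg$frag_len
    sub <- runif(total) < fl$w_sub
    len <- round(ifelse(sub, rnorm(total, fl$mu_sub, fl$sd_sub),
                        rnorm(total, fl$mu_mono, fl$sd_mono)))
    len <- pmin(pmax(len, fl$min), fl$max)
    start <- round(center - len / 2)
    end <- start + len
    start <- pmax(start, 0)
    end <- pmin(end, unname(sizes[chrom]))
    ok <- start < end
    frag_rows[[cl$cluster]] <- data.frame(
      chrom = chrom[ok], start = as.integer(start[ok]),
      end = as.integer(end[ok]),
      barcode = rep(barcodes, n_per_cell)[ok],
      count = 1L, stringsAsFactors = FALSE)
    bc_rows[[cl$cluster]] <- data.frame(
      barcode = barcodes, cluster = cl$cluster, stringsAsFactors = FALSE)
  }
  fragments <- as_fragment_set(do.call(rbind, frag_rows), sizes)
  clusters <- cluster_assignment(
    do.call(rbind, bc_rows),
    cfg$clusters[, c("cluster", "sex", "stage", "lineage")])
  list(fragments = fragments, clusters = clusters)
}

#' Simulate a gene-by-cell count matrix with planted structure
#'
#' Counts are negative binomial with per-gene lognormal per-copy
#' baseline means. Diploid copy multipliers encode the planted truth:
#' autosomal genes get factor 2 in all cells while X-linked genes get 2
#' in female cells and `x_factor` in male cells (1.5 unsexed); a random
#' activated set is multiplied by `activation_fold` in all post-activation
#' clusters (stage >= 1); a random male-biased set (disjoint from the
#' activated set) gets log-spaced folds up to `sex_fold_range[2]` in male
#' cells. A somatic run-on reference signal is also drawn, with activated
#' genes strongly depleted in soma so germline bias ranking has planted
#' truth.
#'
#' @param cfg A `SimConfig`.
#' @param annotation Output of [make_toy_annotation()].
#' @return List with `matrix` (sparse counts, genes x cells), `clusters`
#'   (`ClusterAssignment`), `soma_signal` (data.frame `gene_id`,
#'   `value`), and `truth` (baseline means, activated and sex-biased
#'   tables, `x_factor`).
#' @export
simulate_counts <- function(cfg, annotation) {
  set.seed(.sub_seed(cfg$seed, 3L))
  genes <- annotation$genes
  ng <- nrow(genes)
  cp <- cfg$counts
  mu <- rlnorm(ng, cp$baseline_meanlog, cp$baseline_sdlog)
  activated <- sort(sample(genes$gene_id, cp$n_activated))
  pool <- setdiff(genes$gene_id, activated)
  sex_biased <- sort(sample(pool, cp$n_sex_biased))
  sex_folds <- exp(seq(log(cp$sex_fold_range[1]),
                       log(cp$sex_fold_range[2]),
                       length.out = cp$n_sex_biased))
  is_x <- genes$chrom == "X"
  cols <- list()
  bc_rows <- list()
  for (i in seq_len(nrow(cfg$clusters))) {
    cl <- cfg$clusters[i, ]
    mult <- rep(2, ng)            # per-copy baseline means, diploid
    mult[is_x] <- .x_weight(cl$sex, cp$x_factor)
    if (!is.na(cl$stage) && cl$stage >= 1) {
      mult[match(activated, genes$gene_id)] <-
        mult[match(activated, genes$gene_id)] * cp$activation_fold
    }
    if (!is.na(cl$sex) && cl$sex == "M") {
      mult[match(sex_biased, genes$gene_id)] <-
        mult[match(sex_biased, genes$gene_id)] * sex_folds
    }
    m <- matrix(rnbinom(ng * cl$n_cells, mu = mu * mult,
                        size = 1 / cp$dispersion),
                nrow = ng, ncol = cl$n_cells)
    barcodes <- sprintf("%s_%04d", cl$cluster, seq_len(cl$n_cells))
    colnames(m) <- barcodes
    cols[[cl$cluster]] <- m
    bc_rows[[cl$cluster]] <- data.frame(
      barcode = barcodes, cluster = cl$cluster, stringsAsFactors = FALSE)
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- genes$gene_id
  soma <- rlnorm(ng, meanlog = 0, sdlog = 1)
  soma[match(activated, genes$gene_id)] <-
    soma[match(activated, genes$gene_id)] * 0.01
  clusters <- cluster_assignment(
    do.call(rbind, bc_rows),
    cfg$clusters[, c("cluster", "sex", "stage", "lineage")])
  list(matrix = methods::as(Matrix::Matrix(mat, sparse = TRUE),
                            "CsparseMatrix"),
       clusters = clusters,
       soma_signal = data.frame(gene_id = genes$gene_id, value = soma,
                                stringsAsFactors = FALSE),
       truth = list(
         baseline = data.frame(gene_id = genes$gene_id, mu = mu,
                               chrom = genes$chrom,
                               stringsAsFactors = FALSE),
         activated = data.frame(gene_id = activated,
                                fold = rep(cp$activation_fold,
                                           length(activated)),
                                stringsAsFactors = FALSE),
         sex_biased = data.frame(gene_id = sex_biased, fold = sex_folds,
                                 stringsAsFactors = FALSE),
         x_factor = cp$x_factor))
}

#' Simulate per-nucleus staining intensities grouped by gonad
#'
#' Each gonad draws a lognormal staining gain applied to every intensity
#' in it; SGP nuclei carry the reference H3/DAPI ratio and germ nuclei a
#' planted germ/SGP ratio per sex and stage, all with lognormal noise.
#'
#' @param cfg A `SimConfig`.
#' @return List with `records` (one row per nucleus, the
#'   [normalize_h3()] input format) and `truth` (planted germ/SGP ratio
#'   per sex and stage).
#' @export
simulate_nuclei <- function(cfg) {
  set.seed(.sub_seed(cfg$seed, 4L))
  im <- cfg$imaging
  rows <- list()
  truth <- list()
  for (sex in c("F", "M")) {
    for (st in im$stages) {
      ratio <- im$germ_ratio[[sex]][[st]]
      truth[[length(truth) + 1L]] <- data.frame(
        sex = sex, stage = st, germ_sgp_ratio = ratio,
        stringsAsFactors = FALSE)
      for (g in seq_len(im$n_gonads)) {
        gid <- sprintf("%s_%s_g%02d", sex, st, g)
        gain <- rlnorm(1, 0, im$gain_sdlog)
        n <- im$n_germ + im$n_sgp
        ct <- c(rep("germ", im$n_germ), rep("SGP", im$n_sgp))
        dapi <- rlnorm(n, log(100), 0.1)
        eff <- ifelse(ct == "germ", ratio, 1)
        h3 <- gain * dapi * eff * rlnorm(n, 0, im$noise_sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          gonad_id = gid, cell_type = ct, sex = sex, stage = st,
          h3_mean = h3, dapi_mean = dapi, stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, rows), truth = do.call(rbind, truth))
}
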