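#' Derive Tn5 cut sites from fragments
#'
#' Each fragment contributes two cut sites -- its start and `end - 1`
#' (0-based) -- replicated by the fragment count, so the total cut-site mass
#' is exactly twice the total fragment mass. Fragments whose barcode is not
#' present in the cluster assignment are dropped (count logged).
#'
#' @param fragments A `FragmentSet`.
#' @param clusters A `ClusterAssignment`.
#' @return A `CutSiteIndex`: data.frame with columns `chrom`, `pos`
#'   (0-based), `cluster`, `w` (multiplicity), sorted by
#'   (cluster, chrom, pos); attributes `cluster_totals` and `chrom_sizes`.
#' @export
build_cut_sites <- function(fragments, clusters) {
  cl <- clusters$barcodes$cluster[match(fragments$barcode,
                                        clusters$barcodes$barcode)]
  keep <- !is.na(cl)
  if (!any(keep)) stop("no fragment barcode matches the cluster assignment")
  if (any(!keep)) {
    gc_log("build_cut_sites: dropped ", sum(!keep),
           " fragments with unassigned barcodes")
  }
  fr <- fragments[keep, ]
  cl <- cl[keep]
  cuts <- data.frame(
    chrom = rep(fr$chrom, 2L),
    pos = c(fr$start, fr$end - 1L),
    cluster = rep(cl, 2L),
    w = rep(fr$count, 2L),
    stringsAsFactors = FALSE)
  cuts <- cuts[order(cuts$cluster, cuts$chrom, cuts$pos), ]
  rownames(cuts) <- NULL
  totals <- tapply(cuts$w, cuts$cluster, sum)
  structure(cuts,
            cluster_totals = setNames(as.numeric(totals), names(totals)),
            chrom_sizes = attr(fragments, "chrom_sizes"),
            class = c("CutSiteIndex", "data.frame"))
}

#' @exportS3Method base::print
print.CutSiteIndex <- function(x, ...) {
  cat("CutSiteIndex:", sum(x$w), "cut sites,",
      length(attr(x, "cluster_totals")), "clusters\n")
  invisible(x)
}

# sum cut weights per (cluster, window) for windows given as GRanges; cuts
# overlapping several windows are counted in each
.count_in_windows <- function(cuts, windows) {
  cut_gr <- GenomicRanges::GRanges(
    cuts$chrom, IRanges::IRanges(start = cuts$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(cut_gr, windows)
  data.frame(cut = S4Vectors::queryHits(hits),
             window = S4Vectors::subjectHits(hits))
}

# full (cluster x window) weighted count table, zeros included
.cluster_window_counts <- function(cuts, windows, n_windows) {
  ov <- .count_in_windows(cuts, windows)
  clusters <- sort(unique(cuts$cluster))
  out <- matrix(0, nrow = n_windows, ncol = length(clusters),
                dimnames = list(NULL, clusters))
  if (nrow(ov)) {
    key <- paste(ov$window, cuts$cluster[ov$cut], sep = "\r")
    sums <- rowsum(cuts$w[ov$cut], key)
    parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
    wi <- as.integer(vapply(parts, `[[`, "", 1L))
    ci <- vapply(parts, `[[`, "", 2L)
    out[cbind(wi, match(ci, clusters))] <- sums[, 1L]
  }
  out
}

#' End-to-start accessibility (ESA) per cluster and gene
#'
#' For every gene, counts cut sites within `flank` bp of the transcript
#' 3' end and of the TSS (windows are `[pos - flank, pos + flank]`,
#' inclusive, clipped at chromosome bounds) and forms
#' `esa = (end_count + pseudocount) / (tss_count + pseudocount)`.
#' An ESA near 1 indicates dispersed accessibility over the gene; values
#' well below 1 indicate TSS-focused accessibility. Genes whose two windows
#' overlap (TSS-to-end distance < 2 * flank) are flagged `windows_overlap`
#' and should be excluded from summaries. Any cluster-size normalization
#' cancels in this within-cluster ratio and is therefore not applied here.
#'
#' @param cuts A `CutSiteIndex`.
#' @param genes A `GeneModelSet`.
#' @param flank Half-width of each window in bp.
#' @param pseudocount Added to numerator and denominator.
#' @return An `EsaTable`: data.frame with one row per (cluster, gene) and
#'   columns `cluster`, `gene_id`, `chrom`, `tss`, `tss_count`, `end_count`,
#'   `esa`, `windows_overlap`.
#' @export
compute_esa <- function(cuts, genes, flank = 250, pseudocount = 1) {
  stopifnot(flank > 0)
  sizes <- attr(cuts, "chrom_sizes")
  win_of <- function(pos1) {          # pos1: 1-based anchor position
    p0 <- pos1 - 1L
    lo <- pmax(p0 - flank, 0L)
    hi <- p0 + flank
    if (!is.null(sizes)) hi <- pmin(hi, unname(sizes[genes$chrom]) - 1L)
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(start = lo + 1L, end = hi + 1L))
  }
  n <- nrow(genes)
  tss_counts <- .cluster_window_counts(cuts, win_of(genes$tss), n)
  end_counts <- .cluster_window_counts(cuts, win_of(genes$end3), n)
  clusters <- colnames(tss_counts)
  out <- data.frame(
    cluster = rep(clusters, each = n),
    gene_id = rep(genes$gene_id, length(clusters)),
    chrom = rep(genes$chrom, length(clusters)),
    tss = rep(genes$tss, length(clusters)),
    tss_count = as.vector(tss_counts),
    end_count = as.vector(end_counts),
    stringsAsFactors = FALSE)
  out$esa <- (out$end_count + pseudocount) / (out$tss_count + pseudocount)
  out$windows_overlap <- rep(abs(genes$tss - genes$end3) < 2 * flank,
                             length(clusters))
  structure(out, flank = flank, pseudocount = pseudocount,
            class = c("EsaTable", "data.frame"))
}

#' Per-gene ESA ratio between two clusters
#'
#' Divides one cluster's per-gene ESA values by another's, producing a track
#' ordered along the genome; used to compare read-distribution breadth
#' between clusters while cancelling locus-specific effects.
#'
#' @param esa An `EsaTable`.
#' @param numerator_cluster,denominator_cluster Cluster labels.
#' @return data.frame with `gene_id`, `chrom`, `tss`, `esa_num`, `esa_den`,
#'   `ratio`, `windows_overlap`, sorted by (chrom, tss).
#' @export
esa_cluster_ratio <- function(esa, numerator_cluster, denominator_cluster) {
  for (cl in c(numerator_cluster, denominator_cluster)) {
    if (!cl %in% esa$cluster) stop("unknown cluster: ", cl)
  }
  a <- esa[esa$cluster == numerator_cluster, ]
  b <- esa[esa$cluster == denominator_cluster, ]
  m <- merge(a[, c("gene_id", "chrom", "tss", "esa", "windows_overlap")],
             b[, c("gene_id", "esa")],
             by = "gene_id", suffixes = c("_num", "_den"))
  m$ratio <- m$esa_num / m$esa_den
  m <- m[order(m$chrom, m$tss), ]
  rownames(m) <- NULL
  names(m)[names(m) == "esa_num"] <- "esa_num"
  m[, c("gene_id", "chrom", "tss", "esa_num", "esa_den", "ratio",
        "windows_overlap")]
}

#' TSS enrichment profile and score per cluster
#'
#' Aggregates cut-site density in a strand-oriented window of `+/- span` bp
#' around every TSS, normalizes by the mean density in the two outermost
#' `flank_norm`-bp segments (plus a pseudocount of 0.1), and scores each
#' cluster as the mean normalized density within `+/- core` bp of the TSS.
#' Accessible chromatin concentrated at promoters yields scores well above
#' 1; a uniform read distribution yields a score near 1.
#'
#' @param cuts A `CutSiteIndex`.
#' @param genes A `GeneModelSet`.
#' @param span Profile half-width (bp).
#' @param core Scoring half-width around the TSS (bp).
#' @param flank_norm Width of each outermost normalization segment (bp).
#' @param pseudocount Added to the flank density before division.
#' @return List with `profile` (data.frame `cluster`, `rel`, `density`,
#'   `norm_density`) and `scores` (data.frame `cluster`, `score`; `NA` for
#'   clusters with no cut sites near any TSS).
#' @export
tss_enrichment <- function(cuts, genes, span = 2000, core = 50,
                           flank_norm = 100, pseudocount = 0.1) {
  stopifnot(span > core, span > flank_norm)
  t0 <- genes$tss - 1L
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(t0 - span, 0L) + 1L, end = t0 + span + 1L))
  ov <- .count_in_windows(cuts, win)
  rel <- cuts$pos[ov$cut] - t0[ov$window]
  neg <- genes$strand[ov$window] == "-"
  rel[neg] <- -rel[neg]
  keep <- abs(rel) <= span
  rel <- rel[keep]
  cl <- cuts$cluster[ov$cut][keep]
  w <- cuts$w[ov$cut][keep]
  clusters <- sort(unique(cuts$cluster))
  positions <- seq(-span, span)
  dens <- matrix(0, nrow = length(positions), ncol = length(clusters),
                 dimnames = list(NULL, clusters))
  if (length(rel)) {
    sums <- rowsum(w, paste(rel, cl, sep = "\r"))
    parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
    ri <- as.integer(vapply(parts, `[[`, "", 1L)) + span + 1L
    ci <- match(vapply(parts, `[[`, "", 2L), clusters)
    dens[cbind(ri, ci)] <- sums[, 1L]
  }
  edge <- abs(positions) > span - flank_norm
  core_idx <- abs(positions) <= core
  norm <- colMeans(dens[edge, , drop = FALSE]) + pseudocount
  norm_dens <- sweep(dens, 2, norm, "/")
  score <- colMeans(norm_dens[core_idx, , drop = FALSE])
  score[colSums(dens) == 0] <- NA_real_
  profile <- data.frame(
    cluster = rep(clusters, each = length(positions)),
    rel = rep(positions, length(clusters)),
    density = as.vector(dens),
    norm_density = as.vector(norm_dens),
    stringsAsFactors = FALSE)
  list(profile = profile,
       scores = data.frame(cluster = clusters, score = unname(score),
                           stringsAsFactors = FALSE))
}

#' Fraction of reads in peaks (FRiP) per cell and cluster
#'
#' A fragment is in peaks when it overlaps any peak by at least 1 bp
#' (whole-fragment overlap, weighted by the fragment count -- the standard
#' FRiP definition). Cells with zero fragments do not appear in the output.
#'
#' @param fragments A `FragmentSet`.
#' @param peaks An `IntervalSet` of peaks.
#' @param clusters A `ClusterAssignment`.
#' @return List with `per_cell` (data.frame `barcode`, `cluster`, `total`,
#'   `in_peaks`, `frip`) and `per_cluster` (quartile summary per cluster).
#' @export
frip <- function(fragments, peaks, clusters) {
  if (nrow(peaks) == 0) stop("peaks must be non-empty")
  cl <- clusters$barcodes$cluster[match(fragments$barcode,
                                        clusters$barcodes$barcode)]
  keep <- !is.na(cl)
  fr <- fragments[keep, ]
  cl <- cl[keep]
  frag_gr <- GenomicRanges::GRanges(
    fr$chrom, IRanges::IRanges(start = fr$start + 1L, end = fr$end))
  # disjoint seqlevels simply mean zero overlap, not a user error
  in_peak <- suppressWarnings(
    GenomicRanges::countOverlaps(frag_gr, .iv_granges(peaks))) > 0
  total <- rowsum(fr$count, fr$barcode)
  hit <- rowsum(fr$count * in_peak, fr$barcode)
  per_cell <- data.frame(
    barcode = rownames(total),
    cluster = cl[match(rownames(total), fr$barcode)],
    total = total[, 1L],
    in_peaks = hit[, 1L],
    stringsAsFactors = FALSE)
  per_cell$frip <- per_cell$in_peaks / per_cell$total
  rownames(per_cell) <- NULL
  qs <- do.call(rbind, lapply(split(per_cell$frip, per_cell$cluster),
    function(v) {
      data.frame(n_cells = length(v), q25 = quantile(v, 0.25, names = FALSE),
                 median = median(v), q75 = quantile(v, 0.75, names = FALSE),
                 mean = mean(v))
    }))
  per_cluster <- cbind(data.frame(cluster = rownames(qs),
                                  stringsAsFactors = FALSE), qs)
  rownames(per_cluster) <- NULL
  list(per_cell = per_cell, per_cluster = per_cluster)
}

#' Fragment-size distribution per cluster
#'
#' @param fragments A `FragmentSet`.
#' @param clusters A `ClusterAssignment`.
#' @return data.frame with `cluster`, `length` (end - start), `count`
#'   (weighted by fragment counts).
#' @export
fragment_size_distribution <- function(fragments, clusters) {
  cl <- clusters$barcodes$cluster[match(fragments$barcode,
                                        clusters$barcodes$barcode)]
  keep <- !is.na(cl)
  len <- fragments$end[keep] - fragments$start[keep]
  sums <- rowsum(fragments$count[keep], paste(cl[keep], len, sep = "\r"))
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(cluster = vapply(parts, `[[`, "", 1L),
                    length = as.integer(vapply(parts, `[[`, "", 2L)),
                    count = sums[, 1L], stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$length), ]
  rownames(out) <- NULL
  out
}

#' Windowed accessibility indices
#'
#' Tiles every chromosome with fixed-width windows starting at coordinate 0
#' (the final short window is retained and flagged `truncated`), counts cut
#' sites per (cluster, window), and scales to an accessibility index of
#' counts per million cluster cut sites.
#'
#' @param cuts A `CutSiteIndex`.
#' @param chrom_sizes Named chromosome lengths; defaults to the sizes
#'   carried by `cuts`.
#' @param window Window width in bp.
#' @return A `WindowAccessibility` data.frame with `cluster`, `chrom`,
#'   `start`, `end`, `count`, `index`, `truncated`.
#' @export
windowed_accessibility <- function(cuts, chrom_sizes = NULL,
                                   window = 1e6) {
  stopifnot(window > 0)
  if (is.null(chrom_sizes)) chrom_sizes <- attr(cuts, "chrom_sizes")
  stopifnot(!is.null(chrom_sizes))
  tiles <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - 1L, by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  totals <- attr(cuts, "cluster_totals")
  bin <- cuts$pos %/% as.integer(window)
  key <- paste(cuts$cluster, cuts$chrom, bin, sep = "\r")
  sums <- rowsum(cuts$w, key)
  clusters <- names(totals)
  grid <- data.frame(
    cluster = rep(clusters, each = nrow(tiles)),
    chrom = rep(tiles$chrom, length(clusters)),
    start = rep(tiles$start, length(clusters)),
    end = rep(tiles$end, length(clusters)),
    stringsAsFactors = FALSE)
  gkey <- paste(grid$cluster, grid$chrom, grid$start %/% as.integer(window),
                sep = "\r")
  grid$count <- sums[match(gkey, rownames(sums)), 1L]
  grid$count[is.na(grid$count)] <- 0
  grid$index <- grid$count / unname(totals[grid$cluster]) * 1e6
  grid$truncated <- (grid$end - grid$start) < window
  structure(grid, window = window, cluster_totals = totals,
            class = c("WindowAccessibility", "data.frame"))
}

#' Female-to-male ratios of windowed accessibility indices
#'
#' In the absence of dosage compensation at the chromatin level, the
#' female-to-male accessibility ratio on the X chromosome is expected to be
#' near 2 (two female X copies versus one male); full compensation drives
#' it toward 1. Autosomal ratios serve as the ~1 reference.
#'
#' @param wa A `WindowAccessibility` table.
#' @param female_cluster,male_cluster Cluster labels.
#' @param pseudo Pseudocount added to both indices.
#' @return List with `windows` (per-window ratio) and `chromosomes`
#'   (mean ratio per chromosome).
#' @export
sex_ratio_windows <- function(wa, female_cluster, male_cluster,
                              pseudo = 0.1) {
  for (cl in c(female_cluster, male_cluster)) {
    if (!cl %in% wa$cluster) stop("unknown cluster: ", cl)
  }
  f <- wa[wa$cluster == female_cluster, ]
  m <- wa[wa$cluster == male_cluster, ]
  key <- function(d) paste(d$chrom, d$start, sep = ":")
  m <- m[match(key(f), key(m)), ]
  windows <- data.frame(chrom = f$chrom, start = f$start, end = f$end,
                        index_f = f$index, index_m = m$index,
                        ratio = (f$index + pseudo) / (m$index + pseudo),
                        truncated = f$truncated, stringsAsFactors = FALSE)
  means <- tapply(windows$ratio, windows$chrom, mean)
  chromosomes <- data.frame(chrom = names(means),
                            mean_ratio = as.numeric(means),
                            n_windows = as.integer(table(windows$chrom)[
                              names(means)]),
                            stringsAsFactors = FALSE)
  rownames(chromosomes) <- NULL
  list(windows = windows, chromosomes = chromosomes)
}

#' Per-chromosome cut-site tallies relative to a reference chromosome
#'
#' @param cuts A `CutSiteIndex`.
#' @param normalize_to Reference chromosome (default `"2L"`).
#' @return data.frame with `cluster`, `chrom`, `count`, `relative`
#'   (count / reference count within the cluster).
#' @export
chromosome_tallies <- function(cuts, normalize_to = "2L") {
  sums <- rowsum(cuts$w, paste(cuts$cluster, cuts$chrom, sep = "\r"))
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(cluster = vapply(parts, `[[`, "", 1L),
                    chrom = vapply(parts, `[[`, "", 2L),
                    count = sums[, 1L], stringsAsFactors = FALSE)
  refs <- out$count[out$chrom == normalize_to]
  names(refs) <- out$cluster[out$chrom == normalize_to]
  missing <- setdiff(unique(out$cluster), names(refs))
  if (length(missing)) {
    stop("no cut sites on reference chromosome ", normalize_to,
         " in cluster(s): ", paste(missing, collapse = ", "))
  }
  out$relative <- out$count / unname(refs[out$cluster])
  out <- out[order(out$cluster, out$chrom), ]
  rownames(out) <- NULL
  out
}
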