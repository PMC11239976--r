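#' Germline-to-soma transcription bias table
#'
#' Compares nuclear expression in germline clusters against a somatic
#' nascent-transcription reference (e.g., GRO-seq). Genes whose germline
#' value falls below `floor_g` are marked failing and carry no ratio (an
#' inclusion floor, not value clamping); the soma signal receives a
#' `pseudo_s` pseudocount so the ratio is always defined, and genes absent
#' from the soma table are treated as soma signal 0.
#'
#' @param nuclear_expr data.frame with columns `cluster`, `gene_id`,
#'   `value` (mean normalized nuclear expression per cluster).
#' @param soma_signal data.frame with columns `gene_id`, `value`.
#' @param floor_g Germline inclusion floor.
#' @param pseudo_s Soma pseudocount.
#' @return A `BiasTable` data.frame: `cluster`, `gene_id`, `g`, `s`,
#'   `pass`, `ratio` (`NA` where `pass` is `FALSE`).
#' @export
germline_soma_ratio <- function(nuclear_expr, soma_signal, floor_g = 1,
                                pseudo_s = 0.01) {
  stopifnot(all(c("cluster", "gene_id", "value") %in% names(nuclear_expr)),
            all(c("gene_id", "value") %in% names(soma_signal)))
  if (!length(intersect(nuclear_expr$gene_id, soma_signal$gene_id))) {
    stop("no gene ids shared between nuclear and soma tables")
  }
  s <- soma_signal$value[match(nuclear_expr$gene_id, soma_signal$gene_id)]
  s[is.na(s)] <- 0
  out <- data.frame(cluster = nuclear_expr$cluster,
                    gene_id = nuclear_expr$gene_id,
                    g = nuclear_expr$value, s = s,
                    pass = nuclear_expr$value >= floor_g,
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$pass, out$g / (out$s + pseudo_s), NA_real_)
  structure(out, floor_g = floor_g, pseudo_s = pseudo_s,
            class = c("BiasTable", "data.frame"))
}

#' Top germline-biased genes for one cluster
#'
#' Orders passing genes by descending germline-to-soma ratio, breaking
#' ties by descending germline expression then lexicographic gene id, and
#' returns the first `n` (all passing genes, with a warning, when fewer
#' than `n` pass).
#'
#' @param bias A `BiasTable`.
#' @param cluster Cluster label.
#' @param n Number of genes to return.
#' @return data.frame `rank`, `gene_id`, `ratio`, `g`, `s`.
#' @export
top_n_genes <- function(bias, cluster, n = 150) {
  d <- bias[bias$cluster == cluster & bias$pass, ]
  if (nrow(d) == 0) stop("no passing genes for cluster ", cluster)
  if (nrow(d) < n) {
    warning("only ", nrow(d), " passing genes for cluster ", cluster,
            " (requested ", n, ")")
    n <- nrow(d)
  }
  ord <- order(-d$ratio, -d$g, d$gene_id)[seq_len(n)]
  out <- data.frame(rank = seq_len(n), gene_id = d$gene_id[ord],
                    ratio = d$ratio[ord], g = d$g[ord], s = d$s[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Strand-aware upstream promoter regions
#'
#' For a plus-strand gene with 1-based TSS `t`, the promoter is the
#' 0-based half-open interval `[t - 1 - upstream, t - 1)`; for a
#' minus-strand gene, `[t, t + upstream)`. Regions are clipped at
#' chromosome bounds and clipped regions are flagged `short`.
#'
#' @param genes A `GeneModelSet`.
#' @param gene_ids Genes to extract (default: all).
#' @param upstream Promoter length in bp.
#' @return An `IntervalSet` with columns `chrom`, `start`, `end`, `name`
#'   (gene id), `strand`, `short`.
#' @export
promoter_regions <- function(genes, gene_ids = genes$gene_id,
                             upstream = 500) {
  stopifnot(upstream > 0)
  missing <- setdiff(gene_ids, genes$gene_id)
  if (length(missing)) {
    stop("gene(s) absent from models: ", paste(missing, collapse = ", "))
  }
  g <- genes[match(gene_ids, genes$gene_id), ]
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - 1L - upstream, g$tss)
  end <- ifelse(plus, g$tss - 1L, g$tss + upstream)
  start <- pmax(start, 0L)
  sizes <- attr(genes, "chrom_sizes")
  if (!is.null(sizes)) end <- pmin(end, unname(sizes[g$chrom]))
  keep <- start < end
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " empty promoter region(s)")
  }
  iv <- data.frame(chrom = g$chrom[keep], start = start[keep],
                   end = end[keep], name = g$gene_id[keep],
                   strand = g$strand[keep],
                   short = (end - start)[keep] < upstream,
                   stringsAsFactors = FALSE)
  as_interval_set(iv)
}

# 5 x w log-odds matrix (A,C,G,T,N rows); N contributes 0
.pwm_logodds <- function(pwm) {
  lom <- log(pwm$mat / pwm$bg)
  rbind(lom, N = rep(0, ncol(lom)))
}

.scan_one_strand <- function(code, lom, w) {
  L <- length(code)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (j in seq_len(w)) {
    scores <- scores + lom[code[j:(j + n - 1L)], j]
  }
  scores
}

#' Scan sequences for PWM hits
#'
#' Both strands are scanned with log-odds scores against the PWM
#' background; a window is a hit when its score reaches `threshold_frac`
#' times the maximum attainable score for that PWM. `N` bases score as
#' background (contribution 0). Overlapping hits, including the same
#' window on both strands, are all kept. Sequences shorter than a motif
#' are skipped for that motif.
#'
#' @param pwms List of `MotifPWM` objects.
#' @param sequences A `DNAStringSet` (or named character vector) over
#'   `A/C/G/T/N`.
#' @param regions Optional `IntervalSet` aligned with `sequences` giving
#'   each sequence's genomic location (plus strand); hit coordinates are
#'   then genomic. Without it, coordinates are sequence-local and `chrom`
#'   is the sequence name.
#' @param threshold_frac Fraction of the maximum attainable score.
#' @return data.frame of `MotifHit`s: `motif`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `score`.
#' @export
scan_motifs <- function(pwms, sequences, regions = NULL,
                        threshold_frac = 0.8) {
  seq_chr <- if (is(sequences, "XStringSet")) {
    as.character(sequences)
  } else as.character(sequences)
  if (is.null(names(seq_chr))) names(seq_chr) <- seq_along(seq_chr)
  if (!is.null(regions)) stopifnot(nrow(regions) == length(seq_chr))
  base_levels <- c("A", "C", "G", "T", "N")
  hits <- list()
  for (si in seq_along(seq_chr)) {
    chars <- strsplit(toupper(seq_chr[[si]]), "")[[1]]
    code <- match(chars, base_levels)
    code[is.na(code)] <- 5L
    for (pwm in pwms) {
      lom <- .pwm_logodds(pwm)
      w <- ncol(pwm$mat)
      if (length(code) < w) next
      max_score <- sum(apply(lom[1:4, , drop = FALSE], 2, max))
      thr <- threshold_frac * max_score
      # minus strand == reverse-complemented PWM scanned on the plus text
      rc_lom <- rbind(lom[4:1, w:1, drop = FALSE], N = rep(0, w))
      for (strand in c("+", "-")) {
        scores <- .scan_one_strand(code,
                                   if (strand == "+") lom else rc_lom, w)
        at <- which(scores >= thr)
        if (!length(at)) next
        start0 <- at - 1L
        if (!is.null(regions)) {
          hits[[length(hits) + 1L]] <- data.frame(
            motif = pwm$id, chrom = regions$chrom[si],
            start = regions$start[si] + start0,
            end = regions$start[si] + start0 + w,
            strand = strand, score = scores[at],
            stringsAsFactors = FALSE)
        } else {
          hits[[length(hits) + 1L]] <- data.frame(
            motif = pwm$id, chrom = names(seq_chr)[si], start = start0,
            end = start0 + w, strand = strand, score = scores[at],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$motif, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Motif-site accessibility index per cluster
#'
#' A length-normalized enrichment index: for each (cluster, motif), the
#' fraction of the cluster's in-region cut sites that fall within
#' `halfwin` bp of motif hit centers, divided by the fraction of the
#' scanned length those hit windows occupy. Values near 1 indicate no
#' enrichment; above 1, cut sites concentrate at the motif's sites. Hit
#' windows are merged per motif and intersected with the scanned regions;
#' a pseudocount of 0.5 is applied to both cut-site counts.
#'
#' @param cuts A `CutSiteIndex`.
#' @param hits Motif hits from [scan_motifs()] (genomic coordinates).
#' @param scanned The `IntervalSet` that was scanned.
#' @param halfwin Half-width around each hit center in bp.
#' @return A clusters-by-motifs matrix of indices (`NA` for clusters with
#'   no in-region cut sites).
#' @export
motif_accessibility_index <- function(cuts, hits, scanned, halfwin = 50) {
  scanned_gr <- GenomicRanges::reduce(.iv_granges(scanned))
  scanned_len <- sum(IRanges::width(scanned_gr))
  ov <- .count_in_windows(cuts, scanned_gr)
  in_region <- rowsum(cuts$w[ov$cut], cuts$cluster[ov$cut])
  clusters <- sort(unique(cuts$cluster))
  region_counts <- setNames(rep(0, length(clusters)), clusters)
  region_counts[rownames(in_region)] <- in_region[, 1L]
  if (any(region_counts == 0)) {
    gc_log("motif_accessibility_index: no in-region cut sites for ",
           paste(names(region_counts)[region_counts == 0], collapse = ", "))
  }
  motifs <- sort(unique(hits$motif))
  out <- matrix(NA_real_, nrow = length(clusters), ncol = length(motifs),
                dimnames = list(clusters, motifs))
  for (mo in motifs) {
    h <- hits[hits$motif == mo, ]
    center <- (h$start + h$end) %/% 2L
    win <- GenomicRanges::GRanges(
      h$chrom,
      IRanges::IRanges(start = pmax(center - halfwin, 0L) + 1L,
                       end = center + halfwin))
    win <- GenomicRanges::intersect(GenomicRanges::reduce(win), scanned_gr)
    win_len <- sum(IRanges::width(win))
    if (win_len == 0) next
    ovm <- .count_in_windows(cuts, win)
    in_win <- rowsum(cuts$w[ovm$cut], cuts$cluster[ovm$cut])
    win_counts <- setNames(rep(0, length(clusters)), clusters)
    win_counts[rownames(in_win)] <- in_win[, 1L]
    idx <- ((win_counts + 0.5) / (region_counts + 0.5)) /
      (win_len / scanned_len)
    idx[region_counts == 0] <- NA_real_
    out[, mo] <- idx
  }
  out
}

#' PCA over the cluster-by-motif accessibility matrix
#'
#' Columns are centered and scaled to unit variance (zero-variance columns
#' dropped), then decomposed by singular values. The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param m Clusters-by-motifs numeric matrix.
#' @param n_components Number of components to return.
#' @return List with `scores` (clusters x components), `loadings`
#'   (motifs x components), `var_frac` (variance fractions), and
#'   `dropped` (zero-variance motifs).
#' @export
tf_pca <- function(m, n_components = 2) {
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  if (anyNA(m)) stop("accessibility matrix contains missing entries")
  sds <- apply(m, 2, sd)
  dropped <- colnames(m)[sds == 0]
  m2 <- m[, sds > 0, drop = FALSE]
  if (ncol(m2) < 2) stop("fewer than 2 motifs with nonzero variance")
  max_comp <- min(nrow(m2) - 1L, ncol(m2))
  if (n_components > max_comp) {
    stop("requested ", n_components, " components but at most ", max_comp,
         " are available for ", nrow(m2), " clusters")
  }
  pc <- prcomp(m2, center = TRUE, scale. = TRUE)
  keep <- seq_len(n_components)
  rot <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  flip <- vapply(keep, function(k) {
    sign(rot[which.max(abs(rot[, k])), k])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  var_frac <- (pc$sdev^2 / sum(pc$sdev^2))[keep]
  list(scores = scores, loadings = rot, var_frac = var_frac,
       dropped = dropped)
}
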