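#' Total-count normalization of a count matrix
#'
#' Size factors are each cell's total count divided by the median cell
#' total, so normalized column sums are equal across cells. All-zero cells
#' are dropped with a warning.
#'
#' @param m Gene-by-cell count matrix (dense or sparse) with dimnames.
#' @param method Normalization method; only `"total-count"`.
#' @return List with `matrix` (normalized, same class family as input) and
#'   `size_factors` (named numeric).
#' @export
normalize_counts <- function(m, method = c("total-count")) {
  method <- match.arg(method)
  totals <- Matrix::colSums(m)
  if (all(totals == 0)) stop("count matrix has no nonzero cell")
  if (any(totals == 0)) {
    warning("dropping ", sum(totals == 0), " all-zero cells")
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  sf <- totals / median(totals)
  norm <- m %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(norm) <- dimnames(m)
  list(matrix = norm, size_factors = setNames(as.numeric(sf), colnames(m)))
}

.row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m * m)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  list(mean = as.numeric(mu), var = as.numeric(v), n = n)
}

#' Negative-binomial Wald test between two cell groups
#'
#' A pseudobulk-free NB test: counts are total-count normalized within the
#' comparison; per-gene group means estimate the NB means; a single
#' per-gene dispersion is estimated by the method of moments (variance of
#' normalized counts minus the size-factor-scaled Poisson component, over
#' the squared mean), pooled across the two groups and floored at 1e-8.
#' The Wald statistic is the log2 fold change over its delta-method
#' standard error, with a two-sided normal p-value. A half-count continuity
#' term (0.5 added to each group's summed normalized count) keeps the fold
#' change finite for genes absent from one group. Genes whose total raw
#' count across both groups is below `min_total` are flagged `excluded`
#' and receive no p-value.
#'
#' @param m Gene-by-cell count matrix with dimnames.
#' @param clusters A `ClusterAssignment`.
#' @param group_A,group_B Character vectors of cluster labels; the fold
#'   change is A over B.
#' @param min_total Total raw count threshold below which a gene is
#'   excluded.
#' @return A `DEResult` data.frame: `gene_id`, `mean_A`, `mean_B`
#'   (normalized group means), `lfc`, `fold`, `se`, `stat`, `p`,
#'   `total_raw`, `excluded`.
#' @export
nb_wald_de <- function(m, clusters, group_A, group_B, min_total = 10) {
  bc <- clusters$barcodes
  cells_A <- intersect(colnames(m), bc$barcode[bc$cluster %in% group_A])
  cells_B <- intersect(colnames(m), bc$barcode[bc$cluster %in% group_B])
  if (length(cells_A) == 0 || length(cells_B) == 0) {
    stop("empty cell group (A: ", length(cells_A),
         " cells, B: ", length(cells_B), " cells)")
  }
  if (length(cells_A) < 2 || length(cells_B) < 2) {
    stop("both groups need at least 2 cells")
  }
  raw <- m[, c(cells_A, cells_B), drop = FALSE]
  norm <- normalize_counts(raw)
  y <- norm$matrix
  sf <- norm$size_factors
  cells_A <- intersect(cells_A, colnames(y))
  cells_B <- intersect(cells_B, colnames(y))
  a <- .row_stats(y[, cells_A, drop = FALSE])
  b <- .row_stats(y[, cells_B, drop = FALSE])
  inv_sf_A <- mean(1 / sf[cells_A])
  inv_sf_B <- mean(1 / sf[cells_B])
  # method-of-moments dispersion per group, pooled by residual df
  phi_A <- (a$var - a$mean * inv_sf_A) / a$mean^2
  phi_B <- (b$var - b$mean * inv_sf_B) / b$mean^2
  wA <- ifelse(is.finite(phi_A), a$n - 1, 0)
  wB <- ifelse(is.finite(phi_B), b$n - 1, 0)
  phi_A[!is.finite(phi_A)] <- 0
  phi_B[!is.finite(phi_B)] <- 0
  denom <- wA + wB
  phi <- ifelse(denom > 0, (phi_A * wA + phi_B * wB) / pmax(denom, 1),
                0)
  phi <- pmax(phi, 1e-8)
  # continuity-adjusted means keep the LFC finite at zero group counts
  mu_A <- (a$mean * a$n + 0.5) / a$n
  mu_B <- (b$mean * b$n + 0.5) / b$n
  lfc <- log2(mu_A / mu_B)
  var_A <- (mu_A * inv_sf_A + phi * mu_A^2) / a$n
  var_B <- (mu_B * inv_sf_B + phi * mu_B^2) / b$n
  se <- sqrt(var_A / mu_A^2 + var_B / mu_B^2) / log(2)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  total_raw <- as.numeric(Matrix::rowSums(raw))
  excluded <- total_raw < min_total
  p[excluded] <- NA_real_
  stat[excluded] <- NA_real_
  out <- data.frame(gene_id = rownames(m), mean_A = a$mean,
                    mean_B = b$mean, lfc = lfc, fold = 2^lfc, se = se,
                    stat = stat, p = p, total_raw = total_raw,
                    excluded = excluded, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, group_A = group_A, group_B = group_B,
            min_total = min_total, class = c("DEResult", "data.frame"))
}

#' Import an externally produced differential-expression table
#'
#' Accepts a TSV with header `gene lfc p` (for instance a DESeq2 export) so
#' downstream gene selection and ranking can run on an external engine's
#' results.
#'
#' @param path Input TSV.
#' @return A `DEResult`-compatible data.frame with `gene_id`, `lfc`,
#'   `fold`, `p`, `excluded` (`TRUE` where `p` is missing).
#' @export
read_de_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "lfc", "p") %in% names(df)))
  out <- data.frame(gene_id = df$gene, lfc = df$lfc, fold = 2^df$lfc,
                    p = df$p, excluded = is.na(df$p),
                    stringsAsFactors = FALSE)
  structure(out, class = c("DEResult", "data.frame"))
}

#' Select zygotically activated genes
#'
#' Keeps non-excluded genes with fold change strictly greater than
#' `fold_min` (up in group A) and p-value strictly below `p_max`; with the
#' defaults these are the fold > 2 and P < 1e-10 cutoffs applied to the
#' stage-2 germline versus pre-activation comparison.
#'
#' @param de A `DEResult`.
#' @param fold_min Strict lower bound on the A/B fold change.
#' @param p_max Strict upper bound on the p-value.
#' @return Character vector of selected gene ids (sorted).
#' @export
select_zygotic_genes <- function(de, fold_min = 2, p_max = 1e-10) {
  sel <- !de$excluded & !is.na(de$p) & de$fold > fold_min & de$p < p_max
  sort(de$gene_id[sel])
}

#' Female-to-male expression ratios by gene and chromosome
#'
#' For each (female cluster, male cluster) stage pair, computes per-gene
#' ratios of normalized group means, `(mean_F + floor)/(mean_M + floor)`,
#' over a gene set (typically the zygotically activated genes), and
#' averages ratios per chromosome. On the X, a mean ratio of 2 indicates no
#' dosage compensation and 1 full compensation; autosomes are expected
#' near 1.
#'
#' @param m Normalized gene-by-cell matrix.
#' @param clusters A `ClusterAssignment`.
#' @param gene_set Character vector of gene ids (must be matrix rows).
#' @param stage_pairs data.frame with columns `female`, `male` and
#'   optionally `stage`.
#' @param genes A `GeneModelSet` (or data.frame with `gene_id`, `chrom`)
#'   mapping genes to chromosomes.
#' @param floor Pseudocount added to both means.
#' @return A `DosageReport`: list with `per_gene` and `per_chromosome`
#'   data.frames.
#' @export
sex_expression_ratios <- function(m, clusters, gene_set, stage_pairs,
                                  genes, floor = 0.01) {
  if (length(gene_set) == 0) stop("empty gene set")
  missing <- setdiff(gene_set, rownames(m))
  if (length(missing)) {
    stop("gene set members absent from matrix: ",
         paste(head(missing, 5), collapse = ", "))
  }
  bc <- clusters$barcodes
  if (is.null(stage_pairs$stage)) {
    stage_pairs$stage <- paste0(stage_pairs$female, "/", stage_pairs$male)
  }
  per_gene <- do.call(rbind, lapply(seq_len(nrow(stage_pairs)), function(i) {
    fcl <- stage_pairs$female[i]
    mcl <- stage_pairs$male[i]
    for (cl in c(fcl, mcl)) {
      if (!cl %in% bc$cluster) stop("unknown cluster: ", cl)
    }
    fcells <- intersect(colnames(m), bc$barcode[bc$cluster == fcl])
    mcells <- intersect(colnames(m), bc$barcode[bc$cluster == mcl])
    mf <- Matrix::rowMeans(m[gene_set, fcells, drop = FALSE])
    mm <- Matrix::rowMeans(m[gene_set, mcells, drop = FALSE])
    data.frame(stage = stage_pairs$stage[i], gene_id = gene_set,
               chrom = genes$chrom[match(gene_set, genes$gene_id)],
               mean_f = as.numeric(mf), mean_m = as.numeric(mm),
               ratio = (as.numeric(mf) + floor) / (as.numeric(mm) + floor),
               pass = as.numeric(mf) + as.numeric(mm) > 0,
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  ok <- per_gene[per_gene$pass & !is.na(per_gene$chrom), ]
  agg <- aggregate(ratio ~ stage + chrom, data = ok, FUN = mean)
  n <- aggregate(gene_id ~ stage + chrom, data = ok, FUN = length)
  per_chromosome <- merge(agg, n, by = c("stage", "chrom"))
  names(per_chromosome) <- c("stage", "chrom", "mean_ratio", "n_genes")
  per_chromosome <- per_chromosome[order(per_chromosome$stage,
                                         per_chromosome$chrom), ]
  rownames(per_chromosome) <- NULL
  structure(list(per_gene = per_gene, per_chromosome = per_chromosome),
            floor = floor, class = "DosageReport")
}

#' Rank genes by sex-biased fold change
#'
#' Rank 1 is the largest A-over-B fold change among non-excluded genes
#' (for a male-versus-female comparison, the most male-biased gene). Ties
#' in fold break by ascending p-value, then lexicographic gene id.
#'
#' @param de A `DEResult` for the comparison of interest.
#' @return data.frame `rank`, `gene_id`, `fold`, `lfc`, `p` over
#'   non-excluded genes.
#' @export
rank_sex_biased <- function(de) {
  d <- de[!de$excluded, ]
  ord <- order(-d$fold, d$p, d$gene_id)
  out <- data.frame(rank = seq_along(ord), gene_id = d$gene_id[ord],
                    fold = d$fold[ord], lfc = d$lfc[ord], p = d$p[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
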