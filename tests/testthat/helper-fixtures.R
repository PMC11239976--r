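# small deterministic fixtures and independent brute-force oracles

tiny_sizes <- c(chrA = 10000L, chrB = 8000L)

tiny_genes <- function() {
  as_gene_model_set(data.frame(
    gene_id = c("g1", "g2", "g3"),
    name = c("g1", "g2", "g3"),
    chrom = c("chrA", "chrA", "chrB"),
    strand = c("+", "-", "+"),
    tss = c(2001L, 6000L, 1501L),
    end3 = c(4000L, 4001L, 3500L),
    stringsAsFactors = FALSE), tiny_sizes)
}

tiny_clusters <- function(barcodes, cluster) {
  cluster_assignment(data.frame(barcode = barcodes, cluster = cluster,
                                stringsAsFactors = FALSE))
}

random_fragments <- function(n, seed, sizes = tiny_sizes,
                             barcodes = c("b1", "b2", "b3"),
                             max_count = 3L) {
  set.seed(seed)
  chrom <- sample(names(sizes), n, replace = TRUE)
  start <- floor(runif(n) * (unname(sizes[chrom]) - 400L))
  len <- sample(50:300, n, replace = TRUE)
  as_fragment_set(data.frame(
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + len),
    barcode = sample(barcodes, n, replace = TRUE),
    count = sample(seq_len(max_count), n, replace = TRUE),
    stringsAsFactors = FALSE), sizes)
}

# oracle: weighted cut-site count in an inclusive 0-based window
brute_window_count <- function(cuts, cluster, chrom, lo, hi) {
  sel <- cuts$cluster == cluster & cuts$chrom == chrom &
    cuts$pos >= lo & cuts$pos <= hi
  sum(cuts$w[sel])
}

# oracle: per-cell FRiP by scanning every fragment against every peak
brute_frip <- function(fragments, peaks, clusters) {
  bc <- clusters$barcodes
  out <- numeric(0)
  for (b in unique(fragments$barcode)) {
    if (!b %in% bc$barcode) next
    fr <- fragments[fragments$barcode == b, ]
    hit <- vapply(seq_len(nrow(fr)), function(i) {
      any(peaks$chrom == fr$chrom[i] & peaks$start < fr$end[i] &
            peaks$end > fr$start[i])
    }, logical(1))
    out[b] <- sum(fr$count[hit]) / sum(fr$count)
  }
  out
}

# oracle: exhaustive PWM window scores on one sequence (plus strand)
brute_scan <- function(pwm, seq_chr) {
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  w <- ncol(pwm$mat)
  lom <- log(pwm$mat / pwm$bg)
  n <- length(chars) - w + 1L
  vapply(seq_len(n), function(s) {
    sum(vapply(seq_len(w), function(j) {
      b <- chars[s + j - 1L]
      if (b == "N") 0 else lom[b, j]
    }, numeric(1)))
  }, numeric(1))
}

# oracle: exact two-sided rank-sum permutation p-value (distinct values)
brute_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  rk <- rank(pooled)
  stats <- apply(combs, 2, function(idx) sum(rk[idx]))
  center <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - center) >= abs(r_obs - center) - 1e-9)
}

simple_pwm <- function(id = "m1",
                       consensus = c("A", "C", "G", "T", "A", "C")) {
  w <- length(consensus)
  mat <- matrix(0.04, nrow = 4, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(w)) mat[consensus[j], j] <- 0.88
  structure(list(id = id, name = id, mat = mat, bg = rep(0.25, 4)),
            class = "MotifPWM")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
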