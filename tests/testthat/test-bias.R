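test_that("germline-to-soma ratios apply floor and pseudocount rules", {
  nuc <- data.frame(cluster = "MGC1",
                    gene_id = c("a", "b", "c", "d"),
                    value = c(5, 0.5, 2, 3), stringsAsFactors = FALSE)
  soma <- data.frame(gene_id = c("a", "b", "c"),
                     value = c(0.99, 1, 0), stringsAsFactors = FALSE)
  bt <- germline_soma_ratio(nuc, soma)
  expect_equal(bt$ratio[bt$gene_id == "a"], 5)        # 5 / (0.99 + 0.01)
  expect_true(is.na(bt$ratio[bt$gene_id == "b"]))     # below floor 1
  expect_false(bt$pass[bt$gene_id == "b"])
  expect_equal(bt$ratio[bt$gene_id == "c"], 200)      # s = 0, pseudo only
  expect_equal(bt$ratio[bt$gene_id == "d"], 300)      # absent from soma
  expect_error(germline_soma_ratio(
    nuc, data.frame(gene_id = "zz", value = 1)), "no gene ids shared")
})

test_that("top-N selection ranks by ratio with documented tie-breaks", {
  bt <- germline_soma_ratio(
    data.frame(cluster = "c1", gene_id = c("gB", "gA", "gC", "gD", "gE"),
               value = c(5, 5, 9, 1, 0.2), stringsAsFactors = FALSE),
    data.frame(gene_id = c("gB", "gA", "gC", "gD"),
               value = c(0.99, 0.99, 0.99, 0.99),
               stringsAsFactors = FALSE))
  top2 <- top_n_genes(bt, "c1", n = 2)
  expect_equal(top2$gene_id, c("gC", "gA"))   # ratio 9; then tie -> lexic.
  expect_warning(all_of_them <- top_n_genes(bt, "c1", n = 150),
                 "only 4 passing")
  expect_equal(nrow(all_of_them), 4)

  # planted high-ratio set recovered exactly in a noiseless table
  ng <- 400
  ids <- sprintf("g%03d", seq_len(ng))
  val <- rep(2, ng)
  val[1:150] <- 50
  bt2 <- germline_soma_ratio(
    data.frame(cluster = "c1", gene_id = ids, value = val,
               stringsAsFactors = FALSE),
    data.frame(gene_id = ids, value = rep(1, ng),
               stringsAsFactors = FALSE))
  expect_setequal(top_n_genes(bt2, "c1", n = 150)$gene_id, ids[1:150])
})

test_that("promoter regions follow the strand-aware 500-bp convention", {
  gm <- as_gene_model_set(data.frame(
    gene_id = c("p1", "m1", "edge"), name = c("p1", "m1", "edge"),
    chrom = "chrA", strand = c("+", "-", "+"),
    tss = c(1000L, 1000L, 300L), end3 = c(3000L, 400L, 2300L),
    stringsAsFactors = FALSE), tiny_sizes)
  pr <- promoter_regions(gm, upstream = 500)
  expect_equal(pr$start[pr$name == "p1"], 499)
  expect_equal(pr$end[pr$name == "p1"], 999)
  expect_equal(pr$start[pr$name == "m1"], 1000)
  expect_equal(pr$end[pr$name == "m1"], 1500)
  expect_equal(pr$start[pr$name == "edge"], 0)   # clipped at chromosome 0
  expect_equal(pr$end[pr$name == "edge"], 299)
  expect_true(pr$short[pr$name == "edge"])
  expect_false(any(pr$short[pr$name != "edge"]))
  expect_error(promoter_regions(gm, "nope"), "absent from models")

  # minus-strand promoter sequence is the reverse complement of the slice
  set.seed(1)
  genome <- Biostrings::DNAStringSet(setNames(paste(
    sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
    collapse = ""), "chrA"))
  seqs <- region_sequences(pr[pr$name == "m1", ], genome)
  fwd <- as.character(Biostrings::subseq(genome[["chrA"]], 1001, 1500))
  expect_equal(as.character(seqs[[1]]), revcomp_chr(fwd))
  expect_equal(Biostrings::width(seqs), 500)
})

test_that("motif scanning matches exhaustive enumeration on both strands", {
  pwm <- simple_pwm()
  consensus <- "ACGTAC"
  set.seed(3)
  bases <- sample(c("A", "C", "G", "T"), 10000, replace = TRUE)
  seqs <- paste(bases, collapse = "")
  hits <- scan_motifs(list(pwm), setNames(seqs, "s1"),
                      threshold_frac = 0.8)
  # oracle: enumerate all windows on both strands
  fwd <- brute_scan(pwm, seqs)
  rev <- rev(brute_scan(pwm, revcomp_chr(seqs)))
  maxs <- sum(apply(log(pwm$mat / pwm$bg), 2, max))
  expect_equal(sum(fwd >= 0.8 * maxs) + sum(rev >= 0.8 * maxs),
               nrow(hits))
  plus <- hits[hits$strand == "+", ]
  expect_equal(sort(plus$start), sort(which(fwd >= 0.8 * maxs) - 1L))

  # the consensus scores maximally; its reverse complement hits on minus
  h1 <- scan_motifs(list(pwm), setNames(consensus, "c"))
  expect_equal(h1$score[h1$strand == "+"], maxs, tolerance = 1e-12)
  h2 <- scan_motifs(list(pwm), setNames(revcomp_chr(consensus), "rc"))
  expect_equal(h2$score[h2$strand == "-"], maxs, tolerance = 1e-12)
  # N bases score as background: all-N sequence yields no hits
  expect_equal(nrow(scan_motifs(list(pwm),
                                setNames(strrep("N", 50), "n"))), 0)
  # sequences shorter than the motif are skipped
  expect_equal(nrow(scan_motifs(list(pwm), setNames("ACG", "tiny"))), 0)
})

test_that("motif accessibility index is ~1 under uniformity and flags enrichment", {
  set.seed(3)
  scanned <- as_interval_set(data.frame(
    chrom = "chrA", start = 0L, end = 10000L, name = "r1",
    stringsAsFactors = FALSE))
  hits <- data.frame(motif = rep(c("mA", "mB"), each = 5),
                     chrom = "chrA",
                     start = c(seq(500, 8500, length.out = 5),
                               seq(900, 8900, length.out = 5)),
                     stringsAsFactors = FALSE)
  hits$start <- as.integer(hits$start)
  hits$end <- hits$start + 6L
  hits$strand <- "+"
  hits$score <- 1

  # uniform cuts across the region for two clusters
  n <- 20000
  st <- as.integer(floor(runif(n) * 9900))
  fr <- as_fragment_set(data.frame(
    chrom = "chrA", start = st, end = st + 50L,
    barcode = sample(c("b1", "b2"), n, replace = TRUE),
    count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  ca <- tiny_clusters(c("b1", "b2"), c("c1", "c2"))
  cuts <- build_cut_sites(fr, ca)
  tam <- motif_accessibility_index(cuts, hits, scanned, halfwin = 50)
  expect_true(all(abs(tam - 1) < 0.25))

  # plant extra cut mass at mA centers for cluster c2 only
  extra <- as_fragment_set(data.frame(
    chrom = "chrA",
    start = rep(as.integer(hits$start[1:5]) + 3L, each = 200) - 25L,
    end = rep(as.integer(hits$start[1:5]) + 3L, each = 200) + 25L,
    barcode = "b2", count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  cuts2 <- build_cut_sites(
    as_fragment_set(rbind(as.data.frame(fr), as.data.frame(extra)),
                    tiny_sizes), ca)
  tam2 <- motif_accessibility_index(cuts2, hits, scanned, halfwin = 50)
  expect_equal(which.max(tam2), which(rownames(tam2) == "c2") +
                 (which(colnames(tam2) == "mA") - 1) * nrow(tam2))
  expect_gt(tam2["c2", "mA"], tam2["c1", "mA"])
  expect_gt(tam2["c2", "mA"], tam2["c2", "mB"])
})

test_that("PCA of the cluster-by-motif matrix behaves like a PCA should", {
  set.seed(3)
  m <- matrix(rnorm(8 * 10, mean = 1, sd = 0.2), nrow = 8,
              dimnames = list(paste0("cl", 1:8), paste0("m", 1:10)))
  m["cl7", 1:5] <- m["cl7", 1:5] + 3     # one planted outlier cluster
  m <- rbind(m, cl7b = m["cl7", ])       # and its duplicate
  pca <- tf_pca(m, n_components = 2)
  expect_equal(pca$scores["cl7", ], pca$scores["cl7b", ])
  expect_lt(abs(sum(pca$scores[, 1] * pca$scores[, 2])), 1e-8)
  expect_true(all(pca$var_frac >= 0) && sum(pca$var_frac) <= 1)
  # the planted cluster separates on PC1
  others <- setdiff(rownames(m), c("cl7", "cl7b"))
  expect_gt(min(abs(pca$scores["cl7", 1] - pca$scores[others, 1])),
            max(dist(pca$scores[others, 1])))

  # full-rank reconstruction of the standardized matrix
  full <- tf_pca(m, n_components = nrow(m) - 1)
  std <- scale(m)
  rec <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(rec - std)), 1e-8)

  expect_error(tf_pca(m, n_components = nrow(m) + 2), "components")
  # permuting cluster labels of cut sites drives indices toward 1
  set.seed(33)
  scanned <- as_interval_set(data.frame(chrom = "chrA", start = 0L,
                                        end = 10000L))
  hits <- data.frame(motif = "mA", chrom = "chrA",
                     start = as.integer(seq(200, 9000, by = 450)),
                     stringsAsFactors = FALSE)
  hits$end <- hits$start + 8L
  hits$strand <- "+"
  hits$score <- 1
  n <- 50000
  st <- as.integer(floor(runif(n) * 9900))
  fr <- as_fragment_set(data.frame(
    chrom = "chrA", start = st, end = st + 60L,
    barcode = sample(paste0("b", 1:4), n, replace = TRUE),
    count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  ca <- tiny_clusters(paste0("b", 1:4), paste0("c", 1:4))
  tam <- motif_accessibility_index(build_cut_sites(fr, ca), hits,
                                   scanned)
  expect_lt(mean(abs(tam - 1)), 0.1)
})
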