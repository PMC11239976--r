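test_that("cut sites record both fragment endpoints and conserve mass", {
  fr <- as_fragment_set(data.frame(
    chrom = c("chrA", "chrA"), start = c(100L, 500L),
    end = c(250L, 700L), barcode = c("b1", "b2"), count = c(1L, 3L),
    stringsAsFactors = FALSE), tiny_sizes)
  ca <- tiny_clusters(c("b1", "b2"), c("c1", "c1"))
  cuts <- build_cut_sites(fr, ca)
  expect_setequal(cuts$pos[cuts$w == 1], c(100L, 249L))
  expect_setequal(cuts$pos[cuts$w == 3], c(500L, 699L))
  expect_equal(sum(cuts$w), 2 * sum(fr$count))

  big <- random_fragments(1000, seed = 3)
  cuts2 <- build_cut_sites(big, tiny_clusters(c("b1", "b2", "b3"), "c1"))
  expect_equal(sum(cuts2$w), 2 * sum(big$count))

  orphan <- tiny_clusters("zz", "c9")
  expect_error(build_cut_sites(fr, orphan), "no fragment barcode")
})

test_that("window and flank counts match a brute-force per-position scan", {
  fr <- random_fragments(2000, seed = 11,
                         barcodes = paste0("b", 1:6))
  ca <- tiny_clusters(paste0("b", 1:6), rep(c("c1", "c2"), 3))
  cuts <- build_cut_sites(fr, ca)
  genes <- tiny_genes()

  esa <- compute_esa(cuts, genes, flank = 250)
  for (i in seq_len(nrow(esa))) {
    g <- genes[genes$gene_id == esa$gene_id[i], ]
    t0 <- g$tss - 1L
    e0 <- g$end3 - 1L
    expect_equal(esa$tss_count[i],
                 brute_window_count(cuts, esa$cluster[i], g$chrom,
                                    t0 - 250, t0 + 250))
    expect_equal(esa$end_count[i],
                 brute_window_count(cuts, esa$cluster[i], g$chrom,
                                    e0 - 250, e0 + 250))
  }

  wa <- windowed_accessibility(cuts, tiny_sizes, window = 2000)
  for (i in seq_len(nrow(wa))) {
    expect_equal(wa$count[i],
                 brute_window_count(cuts, wa$cluster[i], wa$chrom[i],
                                    wa$start[i], wa$end[i] - 1))
  }

  fp <- frip(fr, as_interval_set(data.frame(
    chrom = "chrA", start = 1000L, end = 5000L)), ca)
  oracle <- brute_frip(fr, data.frame(chrom = "chrA", start = 1000L,
                                      end = 5000L), ca)
  expect_equal(fp$per_cell$frip[match(names(oracle),
                                      fp$per_cell$barcode)],
               unname(oracle))
})

test_that("ESA arithmetic, flags and cluster ratios follow the definitions", {
  # 40 cuts in the TSS window, 10 in the end window, pseudocount 0
  fr <- as_fragment_set(data.frame(
    chrom = "chrA",
    start = c(rep(2100L, 20), rep(3900L, 5)),
    end = c(rep(2150L, 20), rep(3950L, 5)),
    barcode = "b1", count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  ca <- tiny_clusters("b1", "c1")
  cuts <- build_cut_sites(fr, ca)
  genes <- tiny_genes()   # g1: tss 2001, end3 4000, span 2000
  esa0 <- compute_esa(cuts, genes, flank = 250, pseudocount = 0)
  row <- esa0[esa0$gene_id == "g1" & esa0$cluster == "c1", ]
  expect_equal(row$tss_count, 40)
  expect_equal(row$end_count, 10)
  expect_equal(row$esa, 0.25)
  expect_false(row$windows_overlap)

  # a short gene's windows overlap and are flagged
  short <- as_gene_model_set(data.frame(
    gene_id = "s1", name = "s1", chrom = "chrA", strand = "+",
    tss = 5000L, end3 = 5399L, stringsAsFactors = FALSE), tiny_sizes)
  expect_true(compute_esa(cuts, short)$windows_overlap[1])

  # identical clusters give unit ratios; ratio(A,B) * ratio(B,A) = 1
  fr2 <- random_fragments(3000, seed = 5, barcodes = c("b1", "b2"))
  ca2 <- tiny_clusters(c("b1", "b2"), c("cA", "cB"))
  esa2 <- compute_esa(build_cut_sites(fr2, ca2), genes)
  rab <- esa_cluster_ratio(esa2, "cA", "cB")
  rba <- esa_cluster_ratio(esa2, "cB", "cA")
  expect_equal(rab$ratio * rba$ratio[match(rab$gene_id, rba$gene_id)],
               rep(1, nrow(rab)))
  same <- esa_cluster_ratio(esa2, "cA", "cA")
  expect_equal(same$ratio, rep(1, nrow(same)))
  expect_false(is.unsorted(order(same$chrom, same$tss)))
  expect_error(esa_cluster_ratio(esa2, "cA", "nope"), "unknown cluster")
})

test_that("ESA ratios show no positional autocorrelation when placement is shared", {
  cfg <- sim_config(
    seed = 7,
    chrom_lengths = c(`2L` = 1e6, `2R` = 1e6, `3L` = 1e6, `3R` = 1e6,
                      X = 1e6),
    n_genes = c(`2L` = 100, `2R` = 100, `3L` = 100, `3R` = 100,
                X = 100),
    clusters = data.frame(
      cluster = c("cA", "cB"), sex = NA, stage = 1L,
      lineage = "germline", n_cells = 200L, frags_per_cell = 500,
      theta_tss = 0.3, x_boost = 1, stringsAsFactors = FALSE))
  ann <- make_toy_annotation(cfg)
  sim <- simulate_fragments(cfg, ann)
  cuts <- build_cut_sites(sim$fragments, sim$clusters)
  esa <- compute_esa(cuts, ann$genes)
  rat <- esa_cluster_ratio(esa, "cA", "cB")
  r <- rat$ratio[!rat$windows_overlap]
  rho <- cor(r[-1], r[-length(r)], method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("ESA is near 1 under uniform placement and decreases with theta", {
  cfg <- sim_config_compact(seed = 7)
  cfg$make_genome <- FALSE
  ann <- make_toy_annotation(cfg)
  medians <- sapply(c(0, 0.3, 0.6, 0.9), function(theta) {
    cfg$clusters <- data.frame(
      cluster = "c1", sex = NA, stage = 1L, lineage = "germline",
      n_cells = 200L, frags_per_cell = 500, theta_tss = theta,
      x_boost = 1, stringsAsFactors = FALSE)
    sim <- simulate_fragments(cfg, ann)
    cuts <- build_cut_sites(sim$fragments, sim$clusters)
    esa <- compute_esa(cuts, ann$genes)
    ok <- !esa$windows_overlap
    c(mean(esa$esa[ok]), median(esa$esa[ok]))
  })
  expect_gt(medians[1, 1], 0.9)   # uniform null: mean ESA in [0.9, 1.1]
  expect_lt(medians[1, 1], 1.1)
  expect_true(all(diff(medians[2, ]) < 0))  # strictly decreasing medians
})

test_that("TSS enrichment separates uniform from concentrated placement", {
  cfg <- sim_config_compact(seed = 7)
  cfg$make_genome <- FALSE
  cfg$clusters <- data.frame(
    cluster = c("flat", "peaked"), sex = NA, stage = 1L,
    lineage = "germline", n_cells = 100L, frags_per_cell = 500,
    theta_tss = c(0, 0.9), x_boost = 1, stringsAsFactors = FALSE)
  ann <- make_toy_annotation(cfg)
  sim <- simulate_fragments(cfg, ann)
  cuts <- build_cut_sites(sim$fragments, sim$clusters)
  te <- tss_enrichment(cuts, ann$genes)
  s <- setNames(te$scores$score, te$scores$cluster)
  expect_equal(unname(s["flat"]), 1, tolerance = 0.15)
  expect_gt(s["peaked"], 3)
  expect_gt(s["peaked"], s["flat"])

  # all cut sites exactly at one TSS: huge score, empty far flanks
  t1 <- tiny_genes()$tss[1]
  fr <- as_fragment_set(data.frame(
    chrom = "chrA", start = t1 - 1L, end = t1, barcode = "b1",
    count = 500L, stringsAsFactors = FALSE), tiny_sizes)
  te2 <- tss_enrichment(build_cut_sites(fr, tiny_clusters("b1", "c1")),
                        tiny_genes())
  expect_gt(te2$scores$score, 50)
})

test_that("FRiP respects its bounds and arithmetic", {
  peaks <- as_interval_set(data.frame(chrom = "chrA", start = 0L,
                                      end = 10000L))
  inside <- as_fragment_set(data.frame(
    chrom = "chrA", start = c(10L, 600L), end = c(200L, 900L),
    barcode = "b1", count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  ca <- tiny_clusters("b1", "c1")
  expect_equal(frip(inside, peaks, ca)$per_cell$frip, 1)

  outside <- as_fragment_set(data.frame(
    chrom = "chrB", start = 10L, end = 100L, barcode = "b1",
    count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  expect_equal(frip(outside, peaks, ca)$per_cell$frip, 0)

  half <- as_fragment_set(data.frame(
    chrom = c(rep("chrA", 3), rep("chrB", 3)),
    start = rep(c(100L, 300L, 500L), 2),
    end = rep(c(200L, 400L, 600L), 2),
    barcode = "b1", count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  expect_equal(frip(half, peaks, ca)$per_cell$frip, 0.5)
  expect_error(frip(inside, peaks[0, ], ca), "non-empty")
})

test_that("fragment sizes tally by length and recover the bimodal mixture", {
  fr <- as_fragment_set(data.frame(
    chrom = "chrA", start = c(100L, 100L), end = c(250L, 180L),
    barcode = c("b1", "b1"), count = c(1L, 4L),
    stringsAsFactors = FALSE), tiny_sizes)
  fs <- fragment_size_distribution(fr, tiny_clusters("b1", "c1"))
  expect_equal(fs$count[fs$length == 150], 1)
  expect_equal(fs$count[fs$length == 80], 4)
  expect_equal(sum(fs$count), sum(fr$count))

  cfg <- sim_config_compact(seed = 7)
  cfg$make_genome <- FALSE
  cfg$clusters <- data.frame(
    cluster = "c1", sex = NA, stage = 1L, lineage = "germline",
    n_cells = 200L, frags_per_cell = 500, theta_tss = 0, x_boost = 1,
    stringsAsFactors = FALSE)
  ann <- make_toy_annotation(cfg)
  sim <- simulate_fragments(cfg, ann)
  fs2 <- fragment_size_distribution(sim$fragments, sim$clusters)
  counts <- setNames(fs2$count, fs2$length)
  lens <- as.integer(names(counts))
  smooth <- stats::filter(counts, rep(1 / 11, 11), sides = 2)
  sub <- lens >= 20 & lens <= 140
  mono <- lens > 140 & lens <= 350
  mode1 <- lens[sub][which.max(smooth[sub])]
  mode2 <- lens[mono][which.max(smooth[mono])]
  expect_lt(abs(mode1 - 75), 15)
  expect_lt(abs(mode2 - 200), 15)
})

test_that("windowed indices conserve counts and normalize per million", {
  fr <- as_fragment_set(data.frame(
    chrom = "chrA", start = c(100L, 150L), end = c(300L, 400L),
    barcode = "b1", count = 1L, stringsAsFactors = FALSE), tiny_sizes)
  cuts <- build_cut_sites(fr, tiny_clusters("b1", "c1"))
  wa <- windowed_accessibility(cuts, tiny_sizes, window = 1000)
  expect_equal(sum(wa$count), sum(cuts$w))
  one <- wa[wa$chrom == "chrA" & wa$start == 0, ]
  expect_equal(one$index, 1e6)           # all cuts in a single window
  expect_equal(sum(wa$index), 1e6)

  big <- random_fragments(2000, seed = 9)
  cuts2 <- build_cut_sites(big, tiny_clusters(c("b1", "b2", "b3"), "c1"))
  wa2 <- windowed_accessibility(cuts2, tiny_sizes, window = 3000)
  expect_equal(sum(wa2$count), sum(cuts2$w))
  # chrA is 10 kb: its final 3-kb tile is short and flagged
  expect_true(wa2$truncated[wa2$chrom == "chrA" & wa2$start == 9000][1])
})

test_that("sex ratios of windows are positive, unit at identity", {
  fr <- random_fragments(2000, seed = 13, barcodes = c("b1", "b2"))
  ca <- tiny_clusters(c("b1", "b2"), c("F1", "M1"))
  wa <- windowed_accessibility(build_cut_sites(fr, ca), tiny_sizes,
                               window = 2000)
  sr <- sex_ratio_windows(wa, "F1", "F1")
  expect_equal(sr$windows$ratio, rep(1, nrow(sr$windows)))
  srr <- sex_ratio_windows(wa, "F1", "M1")
  expect_true(all(srr$windows$ratio > 0))
  expect_error(sex_ratio_windows(wa, "F1", "nope"), "unknown cluster")
})

test_that("chromosome tallies normalize to the reference", {
  fr <- as_fragment_set(data.frame(
    chrom = c(rep("2L", 50), rep("X", 25)),
    start = seq(0, by = 10, length.out = 75),
    end = seq(100, by = 10, length.out = 75),
    barcode = "b1", count = 1L, stringsAsFactors = FALSE),
    c(`2L` = 10000L, X = 10000L))
  tal <- chromosome_tallies(build_cut_sites(fr, tiny_clusters("b1", "c1")))
  expect_equal(tal$relative[tal$chrom == "2L"], 1)
  expect_equal(tal$relative[tal$chrom == "X"], 0.5)
  expect_error(chromosome_tallies(
    build_cut_sites(fr, tiny_clusters("b1", "c1")), "4"), "4")
})
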