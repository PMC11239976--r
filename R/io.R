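#' Read a scATAC fragments file
#'
#' Parses a tab-separated fragments file (`chrom start end barcode [count]`,
#' BED-style 0-based half-open coordinates, optionally gzip/bgzip compressed,
#' `#` comment lines allowed) and validates every record against the supplied
#' chromosome sizes. Fragments on chromosomes absent from `chrom_sizes` are
#' dropped (their number is recorded in the `n_dropped` attribute); a missing
#' count column defaults to 1.
#'
#' @param path Path to the fragments file.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @return A `FragmentSet`: a data.frame with columns `chrom`, `start`,
#'   `end`, `barcode`, `count`, plus attributes `chrom_sizes` and
#'   `n_dropped`.
#' @export
read_fragments <- function(path, chrom_sizes) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop("malformed fragment line ", lineno[which(nf < 4)[1]],
         ": fewer than 4 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  barcode <- vapply(parts, `[[`, "", 4L)
  count <- rep(1L, length(chrom))
  has5 <- nf >= 5
  if (any(has5)) {
    count[has5] <- suppressWarnings(
      as.integer(vapply(parts[has5], `[[`, "", 5L)))
  }
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad)) {
    stop("malformed fragment line ", lineno[bad[1]],
         ": non-integer coordinate or count")
  }
  bad <- which(start >= end | start < 0L | count < 1L)
  if (length(bad)) {
    stop("malformed fragment line ", lineno[bad[1]],
         ": requires 0 <= start < end and count >= 1")
  }
  known <- chrom %in% names(chrom_sizes)
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    gc_log("read_fragments: dropped ", n_dropped,
           " fragments on unknown chromosomes")
  }
  fr <- data.frame(chrom = chrom[known], start = start[known],
                   end = end[known], barcode = barcode[known],
                   count = count[known], stringsAsFactors = FALSE)
  over <- fr$end > unname(chrom_sizes[fr$chrom])
  if (any(over)) {
    stop("fragment beyond chromosome end on ", fr$chrom[which(over)[1]])
  }
  as_fragment_set(fr, chrom_sizes, n_dropped = n_dropped)
}

#' Construct a FragmentSet from an in-memory data.frame
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `barcode` and
#'   optionally `count` (defaults to 1).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_dropped Bookkeeping count of records dropped upstream.
#' @return A `FragmentSet`.
#' @export
as_fragment_set <- function(df, chrom_sizes, n_dropped = 0L) {
  if (is.null(df$count)) df$count <- 1L
  stopifnot(all(c("chrom", "start", "end", "barcode", "count") %in% names(df)),
            all(df$start < df$end), all(df$count >= 1))
  rownames(df) <- NULL
  structure(df[, c("chrom", "start", "end", "barcode", "count")],
            chrom_sizes = chrom_sizes, n_dropped = as.integer(n_dropped),
            class = c("FragmentSet", "data.frame"))
}

#' Write a fragments file
#'
#' @param fragments A `FragmentSet`.
#' @param path Output path; written gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(as.data.frame(fragments)[, c("chrom", "start", "end",
                                           "barcode", "count")],
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models and reduce to one transcript per gene
#'
#' Reads transcript structures and derives a single strand-aware
#' (TSS, 3' end) pair per gene. When a gene has several isoforms the longest
#' transcript is used; ties resolve to the first in file order. GTF input is
#' 1-based closed; BED is 0-based half-open and converted on read; the `tsv`
#' dialect accepts a pre-reduced table (columns `gene_id`, optional `name`,
#' `chrom`, `strand`, `tss`, `end3`, 1-based) and is the override path for
#' any other isoform convention.
#'
#' @param path Input file.
#' @param dialect One of `"gtf"`, `"bed12"`, `"tsv"`.
#' @param chrom_sizes Optional named vector; when given, models are validated
#'   against chromosome bounds and models on unknown chromosomes are dropped.
#' @return A `GeneModelSet`: data.frame with columns `gene_id`, `name`,
#'   `chrom`, `strand`, `tss`, `end3` (both 1-based).
#' @export
read_gene_models <- function(path, dialect = c("gtf", "bed12", "tsv"),
                             chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  tx <- switch(dialect,
    gtf = .read_tx_gtf(path),
    bed12 = .read_tx_bed(path),
    tsv = NULL)
  if (dialect == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (is.null(df$name)) df$name <- df$gene_id
    return(as_gene_model_set(df, chrom_sizes))
  }
  # tx: one row per transcript: gene_id, name, chrom, strand, start, end
  # (1-based closed)
  strands <- tapply(tx$strand, tx$gene_id, function(s) length(unique(s)))
  if (any(strands > 1)) {
    stop("gene(s) with transcripts on both strands: ",
         paste(names(strands)[strands > 1], collapse = ", "))
  }
  tx$len <- tx$end - tx$start + 1L
  ord <- order(tx$gene_id, -tx$len)
  tx <- tx[ord, ]
  tx <- tx[!duplicated(tx$gene_id), ]
  models <- data.frame(
    gene_id = tx$gene_id, name = tx$name, chrom = tx$chrom,
    strand = tx$strand,
    tss = ifelse(tx$strand == "+", tx$start, tx$end),
    end3 = ifelse(tx$strand == "+", tx$end, tx$start),
    stringsAsFactors = FALSE)
  as_gene_model_set(models[order(models$gene_id), ], chrom_sizes)
}

# parse GTF transcript lines; falls back to exon spans when no transcript
# features are present
.read_tx_gtf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9)) stop("malformed GTF: fewer than 9 fields")
  feat <- vapply(parts, `[[`, "", 3L)
  use <- feat %in% c("transcript", "mRNA")
  by_exon <- FALSE
  if (!any(use)) {
    use <- feat == "exon"
    by_exon <- TRUE
    if (!any(use)) stop("GTF contains no transcript or exon features")
  }
  parts <- parts[use]
  attr_of <- function(attrs, key) {
    pat <- paste0(key, ' "([^"]*)"')
    m <- regexpr(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    out[m != -1L] <- sub(pat, "\\1", regmatches(attrs, m))
    out
  }
  attrs <- vapply(parts, `[[`, "", 9L)
  tx <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 4L)),
    end = as.integer(vapply(parts, `[[`, "", 5L)),
    strand = vapply(parts, `[[`, "", 7L),
    gene_id = attr_of(attrs, "gene_id"),
    tx_id = attr_of(attrs, "transcript_id"),
    name = attr_of(attrs, "gene_name"),
    stringsAsFactors = FALSE)
  if (anyNA(tx$gene_id)) stop("GTF records without gene_id attribute")
  if (anyNA(tx$tx_id)) tx$tx_id <- tx$gene_id
  tx$name[is.na(tx$name)] <- tx$gene_id[is.na(tx$name)]
  if (by_exon) {
    key <- paste(tx$gene_id, tx$tx_id, sep = "\r")
    tx <- do.call(rbind, lapply(split(tx, key), function(d) {
      d2 <- d[1, ]
      d2$start <- min(d$start)
      d2$end <- max(d$end)
      d2
    }))
    rownames(tx) <- NULL
  }
  stopifnot(all(tx$strand %in% c("+", "-")), all(tx$start <= tx$end),
            all(tx$start >= 1))
  tx[, c("gene_id", "name", "chrom", "strand", "start", "end")]
}

# BED with >= 6 columns; the name column identifies the gene, repeated names
# are isoforms
.read_tx_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BED gene models need >= 6 columns (incl. strand)")
  data.frame(gene_id = df[[4]], name = df[[4]], chrom = df[[1]],
             strand = df[[6]],
             start = as.integer(df[[2]]) + 1L,   # 0-based -> 1-based
             end = as.integer(df[[3]]),
             stringsAsFactors = FALSE)
}

#' Construct a GeneModelSet
#'
#' @param df data.frame with columns `gene_id`, `name`, `chrom`, `strand`
#'   (`+`/`-`), `tss`, `end3` (1-based positions).
#' @param chrom_sizes Optional named vector used for bounds validation.
#' @return A `GeneModelSet`.
#' @export
as_gene_model_set <- function(df, chrom_sizes = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "end3") %in%
                  names(df)))
  if (is.null(df$name)) df$name <- df$gene_id
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene models")
  stopifnot(all(df$strand %in% c("+", "-")))
  plus <- df$strand == "+"
  stopifnot(all(df$tss[plus] <= df$end3[plus]),
            all(df$tss[!plus] >= df$end3[!plus]),
            all(df$tss >= 1), all(df$end3 >= 1))
  if (!is.null(chrom_sizes)) {
    known <- df$chrom %in% names(chrom_sizes)
    if (any(!known)) {
      gc_log("dropping ", sum(!known), " gene models on unknown chromosomes")
      df <- df[known, ]
    }
    stopifnot(all(pmax(df$tss, df$end3) <= unname(chrom_sizes[df$chrom])))
  }
  rownames(df) <- NULL
  structure(df[, c("gene_id", "name", "chrom", "strand", "tss", "end3")],
            chrom_sizes = chrom_sizes,
            class = c("GeneModelSet", "data.frame"))
}

#' Read a barcode-to-cluster assignment table
#'
#' Tab-separated with a header; required columns `barcode` and `cluster`,
#' optional per-cluster metadata columns `sex` (`F`/`M`/`NA`), `stage`
#' (ordinal 0-3 or `NA`) and `lineage` (`germline`/`soma`). Metadata must be
#' constant within a cluster.
#'
#' @param path Input TSV.
#' @return A `ClusterAssignment`.
#' @export
read_cluster_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("barcode", "cluster") %in% names(df)))
  meta_cols <- intersect(c("sex", "stage", "lineage"), names(df))
  meta <- unique(df[, c("cluster", meta_cols), drop = FALSE])
  if (anyDuplicated(meta$cluster)) {
    stop("inconsistent cluster metadata across barcodes")
  }
  cluster_assignment(df[, c("barcode", "cluster")], meta)
}

#' Construct a ClusterAssignment
#'
#' @param barcodes data.frame with columns `barcode`, `cluster`.
#' @param clusters Optional per-cluster metadata data.frame with column
#'   `cluster` plus any of `sex`, `stage`, `lineage`.
#' @return A `ClusterAssignment` (list with `barcodes` and `clusters`).
#' @export
cluster_assignment <- function(barcodes, clusters = NULL) {
  stopifnot(all(c("barcode", "cluster") %in% names(barcodes)))
  if (anyDuplicated(barcodes$barcode)) {
    stop("duplicate barcode in cluster map: ",
         barcodes$barcode[anyDuplicated(barcodes$barcode)])
  }
  labs <- unique(barcodes$cluster)
  if (is.null(clusters)) {
    clusters <- data.frame(cluster = labs, stringsAsFactors = FALSE)
  }
  if (!all(labs %in% clusters$cluster)) {
    stop("metadata missing for cluster(s): ",
         paste(setdiff(labs, clusters$cluster), collapse = ", "))
  }
  for (col in c("sex", "stage", "lineage")) {
    if (is.null(clusters[[col]])) clusters[[col]] <- NA
  }
  rownames(barcodes) <- rownames(clusters) <- NULL
  structure(list(barcodes = barcodes[, c("barcode", "cluster")],
                 clusters = clusters[, c("cluster", "sex", "stage",
                                         "lineage")]),
            class = "ClusterAssignment")
}

#' Write a cluster assignment table
#' @param clusters A `ClusterAssignment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_map <- function(clusters, path) {
  df <- merge(clusters$barcodes, clusters$clusters, by = "cluster",
              sort = FALSE)
  write.table(df[, c("barcode", "cluster", "sex", "stage", "lineage")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-cell count matrix in MatrixMarket triplet format
#'
#' @param mtx Path to the `.mtx` file (1-based triplet indices).
#' @param rows Path to gene ids, one per line (matrix rows).
#' @param cols Path to cell barcodes, one per line (matrix columns).
#' @param clusters Optional `ClusterAssignment`; when given, matrix columns
#'   must be a subset of its barcodes.
#' @return A sparse `dgCMatrix` with gene ids as rownames and barcodes as
#'   colnames.
#' @export
read_count_matrix <- function(mtx, rows, cols, clusters = NULL) {
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readLines(rows)
  cells <- readLines(cols)
  stopifnot(nrow(m) == length(genes), ncol(m) == length(cells))
  if (anyDuplicated(genes)) stop("duplicate gene ids in row labels")
  if (anyDuplicated(cells)) stop("duplicate barcodes in column labels")
  if (any(m@x < 0)) stop("negative entries in count matrix")
  dimnames(m) <- list(genes, cells)
  if (!is.null(clusters)) {
    missing <- setdiff(cells, clusters$barcodes$barcode)
    if (length(missing)) {
      stop("matrix columns absent from cluster map: ",
           paste(head(missing, 5), collapse = ", "))
    }
  }
  m
}

#' Write a count matrix as MTX plus label files
#' @param m Matrix (genes x cells) with dimnames.
#' @param mtx,rows,cols Output paths.
#' @return `mtx`, invisibly.
#' @export
write_count_matrix <- function(m, mtx, rows, cols) {
  Matrix::writeMM(as(as(m, "dMatrix"), "CsparseMatrix"), mtx)
  writeLines(rownames(m), rows)
  writeLines(colnames(m), cols)
  invisible(mtx)
}

#' Read peak intervals from a BED file
#'
#' @param path BED3+ file (0-based half-open).
#' @return An `IntervalSet`: data.frame with `chrom`, `start`, `end`,
#'   `name`.
#' @export
read_peaks <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  iv <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                   end = as.integer(df[[3]]),
                   name = if (ncol(df) >= 4) df[[4]] else
                     paste0("peak_", seq_len(nrow(df))),
                   stringsAsFactors = FALSE)
  as_interval_set(iv)
}

#' Construct an IntervalSet (0-based half-open records)
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`
#'   and `strand`.
#' @return An `IntervalSet`.
#' @export
as_interval_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)),
            all(df$start < df$end), all(df$start >= 0))
  if (is.null(df$name)) df$name <- paste0("iv_", seq_len(nrow(df)))
  rownames(df) <- NULL
  structure(df, class = c("IntervalSet", "data.frame"))
}

#' Write an IntervalSet as BED
#' @param iv An `IntervalSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(iv, path) {
  out <- as.data.frame(iv)[, c("chrom", "start", "end", "name")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# interval data.frame -> GRanges (0-based half-open -> 1-based closed)
.iv_granges <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand)
}

#' Read position frequency matrices
#'
#' Supports the JASPAR text format (`>id name` header, four `A/C/G/T [ ... ]`
#' rows) and the minimal MEME format (`MOTIF` blocks with
#' `letter-probability matrix` sections; a `Background letter frequencies`
#' line, when present, supplies the background). Each column receives a
#' pseudocount of `pseudocount` (in count units) and is renormalized to sum
#' to one, so all entries are strictly positive.
#'
#' @param path Input file.
#' @param format `"jaspar"` or `"meme"`.
#' @param pseudocount Added to every cell before renormalization.
#' @return List of `MotifPWM` objects (fields `id`, `name`, `mat` -- a 4 x w
#'   probability matrix with rows A, C, G, T -- and `bg`).
#' @export
read_pwms <- function(path, format = c("jaspar", "meme"),
                      pseudocount = 0.01) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "jaspar") .parse_jaspar(lines, pseudocount)
  else .parse_meme(lines, pseudocount)
}

.finish_pwm <- function(id, name, counts, bg, pseudocount) {
  counts <- counts + pseudocount
  sums <- colSums(counts)
  if (any(sums <= 0)) stop("PWM column sums to zero in motif ", id)
  mat <- sweep(counts, 2, sums, "/")
  if (ncol(mat) < 4) stop("motif ", id, " narrower than 4 columns")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, name = name, mat = mat, bg = bg),
            class = "MotifPWM")
}

.parse_jaspar <- function(lines, pseudocount) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR headers ('>') found")
  bounds <- c(hdr, length(lines) + 1L)
  lapply(seq_along(hdr), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    fields <- strsplit(trimws(sub("^>", "", lines[hdr[i]])), "[ \t]+")[[1]]
    id <- fields[1]
    name <- if (length(fields) > 1) fields[2] else id
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(paste0("^", b, "[ \t\\[]"), block)]
      if (length(ln) != 1) stop("motif ", id, ": missing ", b, " row")
      as.numeric(strsplit(trimws(gsub("[][]", " ",
                                      sub("^[ACGT]", "", ln))),
                          "[ \t]+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1) stop("motif ", id, ": ragged rows")
    .finish_pwm(id, name, do.call(rbind, rows), rep(0.25, 4), pseudocount)
  })
}

.parse_meme <- function(lines, pseudocount) {
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1L]), "[ \t]+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- unname(vals[c("A", "C", "G", "T")])
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF blocks found")
  lapply(starts, function(s) {
    fields <- strsplit(trimws(lines[s]), "[ \t]+")[[1]]
    id <- fields[2]
    name <- if (length(fields) > 2) fields[3] else id
    lp <- grep("letter-probability matrix", lines)
    lp <- lp[lp > s][1]
    if (is.na(lp)) stop("motif ", id, ": no letter-probability matrix")
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1L):(lp + w)]
    m <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1]][1:4])
    }, numeric(4)))
    .finish_pwm(id, name, t(m), bg, pseudocount)
  })
}

#' Extract region sequences from a genome
#'
#' @param regions An `IntervalSet` (0-based half-open), optionally with a
#'   `strand` column.
#' @param genome A `DNAStringSet` (or path to a FASTA file) keyed by
#'   chromosome name.
#' @param strand_aware When `TRUE`, minus-strand regions are
#'   reverse-complemented.
#' @return A `DNAStringSet` named by the regions' `name` column.
#' @export
region_sequences <- function(regions, genome, strand_aware = TRUE) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("[ \t].*", "", names(genome))
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(regions)),
    function(i) {
      as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                      start = regions$start[i] + 1L,
                                      end = regions$end[i]))
    }, ""))
  names(seqs) <- regions$name
  if (strand_aware && !is.null(regions$strand)) {
    neg <- regions$strand == "-"
    if (any(neg)) {
      seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
    }
  }
  seqs
}

#' Write region sequences to FASTA
#'
#' @inheritParams region_sequences
#' @param path Output FASTA path.
#' @return The extracted `DNAStringSet`, invisibly.
#' @export
write_fasta <- function(regions, genome, path, strand_aware = TRUE) {
  seqs <- region_sequences(regions, genome, strand_aware = strand_aware)
  Biostrings::writeXStringSet(seqs, path)
  invisible(seqs)
}
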