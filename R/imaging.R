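#' Normalize per-nucleus histone H3 intensities
#'
#' Each nucleus's mean H3 intensity is divided by its mean DAPI intensity;
#' germ-cell values are then divided by the mean of this ratio over all
#' SGP nuclei of the same gonad, which cancels per-gonad staining
#' efficiency exactly. SGP nuclei receive no score.
#'
#' @param records data.frame with columns `gonad_id`, `cell_type`
#'   (`germ`/`SGP`), `sex`, `stage`, `h3_mean`, `dapi_mean` (one row per
#'   nucleus, `dapi_mean > 0`).
#' @return data.frame of germ nuclei with an added `score` column.
#' @export
normalize_h3 <- function(records) {
  stopifnot(all(c("gonad_id", "cell_type", "sex", "stage", "h3_mean",
                  "dapi_mean") %in% names(records)),
            all(records$dapi_mean > 0),
            all(records$cell_type %in% c("germ", "SGP")))
  r <- records$h3_mean / records$dapi_mean
  sgp <- records$cell_type == "SGP"
  sgp_mean <- tapply(r[sgp], records$gonad_id[sgp], mean)
  germ <- records[records$cell_type == "germ", ]
  orphan <- setdiff(unique(germ$gonad_id), names(sgp_mean))
  if (length(orphan)) {
    stop("gonad(s) with germ nuclei but no SGP reference: ",
         paste(orphan, collapse = ", "))
  }
  germ$score <- r[records$cell_type == "germ"] /
    unname(sgp_mean[germ$gonad_id])
  rownames(germ) <- NULL
  germ
}

#' Compare normalized H3 scores between sexes within stages
#'
#' Two-sided Wilcoxon rank-sum test of female versus male germ-cell scores
#' within each stage (exact for groups of up to 8; normal approximation
#' with continuity correction otherwise), plus quartile summaries per
#' group. Stages where either sex has fewer than `min_n` scores are
#' skipped.
#'
#' @param scores Output of [normalize_h3()] (needs `sex`, `stage`,
#'   `score`).
#' @param min_n Minimum group size for a comparison.
#' @return List with `tests` (per-stage statistic and p) and `summary`
#'   (per sex/stage quartiles).
#' @export
compare_h3_groups <- function(scores, min_n = 3) {
  stages <- unique(scores$stage)
  tests <- list()
  for (st in stages) {
    f <- scores$score[scores$stage == st & scores$sex == "F"]
    m <- scores$score[scores$stage == st & scores$sex == "M"]
    if (length(f) < min_n || length(m) < min_n) {
      gc_log("compare_h3_groups: skipping stage ", st,
             " (group below ", min_n, " scores)")
      next
    }
    exact <- max(length(f), length(m)) <= 8
    wt <- suppressWarnings(wilcox.test(f, m, exact = exact,
                                       correct = TRUE))
    tests[[length(tests) + 1L]] <- data.frame(
      stage = st, n_f = length(f), n_m = length(m),
      statistic = unname(wt$statistic), p = wt$p.value,
      stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(stage = character(), n_f = integer(), n_m = integer(),
               statistic = numeric(), p = numeric())
  summ <- do.call(rbind, lapply(split(scores$score,
                                      list(scores$sex, scores$stage),
                                      drop = TRUE), function(v) {
    data.frame(n = length(v), q25 = quantile(v, 0.25, names = FALSE),
               median = median(v), q75 = quantile(v, 0.75, names = FALSE))
  }))
  summ <- cbind(data.frame(group = rownames(summ),
                           stringsAsFactors = FALSE), summ)
  rownames(summ) <- NULL
  list(tests = tests, summary = summ)
}
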