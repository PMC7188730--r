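#' Boxplot statistics as numbers
#'
#' Median, quartiles (linear interpolation), whiskers at the most extreme
#' values within 1.5 IQR of the quartiles, and the outlier count — the
#' numeric content of a boxplot, exported instead of a rendered figure.
#'
#' @param x numeric vector (non-finite values dropped).
#' @return named list: `n`, `median`, `q25`, `q75`, `whisker_lo`,
#'   `whisker_hi`, `n_outliers`.
#' @export
boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    return(list(n = 0L, median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                whisker_lo = NA_real_, whisker_hi = NA_real_,
                n_outliers = 0L))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(n = length(x), median = q[2], q25 = q[1], q75 = q[3],
       whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
       n_outliers = sum(!inside))
}

#' Aggregate per-patient results into a cohort report
#'
#' Collects per-patient hotspot, Dice and subregion tables (as produced by
#' [run_overlap_analysis()]), summarises relative hotspot volumes and Dice
#' scores per cohort x compartment x item with boxplot statistics, and runs
#' pairwise between-cohort rank-sum comparisons for every summarised item.
#' Ordering is deterministic (cohort, compartment, measure, item).
#'
#' @param results list of [run_overlap_analysis()] outputs (one per
#'   patient), or a single such output.
#' @param cohort named character vector mapping patient id to cohort label;
#'   patients not named fall into `"all"`.
#' @param biopsy optional [correlate_with_histology()] result attached to
#'   the bundle unchanged.
#' @return object of class `cohort_report`: list with `cohort_summary`,
#'   `comparisons`, `subregions` (row-bound per-patient subregion stats with
#'   cohort column), and `biopsy`.
#' @export
build_report <- function(results, cohort = NULL, biopsy = NULL) {
  if (!is.null(results$hotspots)) results <- list(results)
  hot <- do.call(rbind, lapply(results, `[[`, "hotspots"))
  dc <- do.call(rbind, lapply(results, `[[`, "dice"))
  sub <- do.call(rbind, lapply(results, `[[`, "subregions"))
  if (is.null(hot) || nrow(hot) == 0L)
    stop("build_report: no analyzed patients", call. = FALSE)
  coh <- function(p) {
    if (is.null(cohort)) return(rep("all", length(p)))
    out <- unname(cohort[p]); out[is.na(out)] <- "all"; out
  }
  hot$cohort <- coh(hot$patient)
  dc$cohort <- coh(dc$patient)
  if (!is.null(sub)) sub$cohort <- coh(sub$patient)

  long <- rbind(
    data.frame(cohort = hot$cohort, compartment = hot$compartment,
               measure = "relative_volume", item = hot$modality,
               patient = hot$patient, value = hot$relative_volume),
    data.frame(cohort = dc$cohort, compartment = dc$compartment,
               measure = "dice", item = dc$pair,
               patient = dc$patient, value = dc$dice))
  long <- long[is.finite(long$value), ]

  keys <- unique(long[, c("cohort", "compartment", "measure", "item")])
  keys <- keys[order(keys$cohort, keys$compartment, keys$measure,
                     keys$item), , drop = FALSE]
  summ <- do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
    k <- keys[r, ]
    v <- long$value[long$cohort == k$cohort &
                    long$compartment == k$compartment &
                    long$measure == k$measure & long$item == k$item]
    cbind(k, as.data.frame(boxplot_stats(v)), row.names = NULL)
  }))

  cohorts <- sort(unique(long$cohort))
  comp_rows <- list()
  if (length(cohorts) >= 2L) {
    items <- unique(long[, c("compartment", "measure", "item")])
    for (r in seq_len(nrow(items))) {
      k <- items[r, ]
      sel <- long$compartment == k$compartment &
             long$measure == k$measure & long$item == k$item
      for (i in seq_along(cohorts)) for (j in seq_along(cohorts)) {
        if (j <= i) next
        va <- long$value[sel & long$cohort == cohorts[i]]
        vb <- long$value[sel & long$cohort == cohorts[j]]
        if (length(va) == 0L || length(vb) == 0L) next
        gc <- rank_sum_test(va, vb, labels = c(cohorts[i], cohorts[j]))
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          compartment = k$compartment, measure = k$measure, item = k$item,
          cohort_a = cohorts[i], cohort_b = cohorts[j],
          n_a = gc$n[1], n_b = gc$n[2],
          median_a = gc$medians[1], median_b = gc$medians[2],
          p_value = gc$p_value, significant = gc$significant)
      }
    }
  }
  structure(list(cohort_summary = summ,
                 comparisons = do.call(rbind, comp_rows),
                 subregions = sub, biopsy = biopsy),
            class = "cohort_report")
}

#' Write a cohort report to disk
#'
#' `cohort_summary.csv`, `comparisons.csv` (when present) and a `report.json`
#' bundle with everything, including biopsy correlations.
#'
#' @param report [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cohort_summary,
                   file.path(dir, "cohort_summary.csv"), row.names = FALSE)
  if (!is.null(report$comparisons))
    utils::write.csv(report$comparisons,
                     file.path(dir, "comparisons.csv"), row.names = FALSE)
  if (!is.null(report$subregions))
    utils::write.csv(report$subregions,
                     file.path(dir, "subregion_stats.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
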