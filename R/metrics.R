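# Clinical biopsy outcome metrics.
#
# * HR (hit rate): fraction of fired needles that intersect the lesion.
# * CCL (cancer core length): total needle-lesion intersection length, mm.
# * N.CCL: CCL normalised by the maximum attainable with five ideally
#   placed needles (5 x the lesion's longest needle-axis chord).
# * N.Coverage: in-plane needle spread, std_x * std_y * pi / Area_L, with
#   population (divide-by-n) standard deviations of the fired needles'
#   world x and y positions and Area_L the lesion's area projected onto
#   the transverse plane.
# * CCL coefficient: Pearson correlation across cases between lesion size
#   (voxels) and measured CCL — how representative sampled core lengths
#   are of true disease burden.

#' Hit rate of a set of needle records
#'
#' @param records data.frame with logical columns `fired`, `hit` (an
#'   `episode_result$records`).
#' @return hits / fired; `NaN` with a warning when nothing was fired.
#' @export
hit_rate <- function(records) {
  fired <- sum(records$fired)
  if (fired == 0L) {
    warning("no fired needles; hit rate undefined")
    return(NaN)
  }
  sum(records$hit) / fired
}

#' Total cancer core length in mm
#' @param records needle records data.frame with `ccl_mm`.
#' @return total CCL over fired needles, mm.
#' @export
ccl_total <- function(records) {
  sum(records$ccl_mm[records$fired])
}

#' Normalised cancer core length
#'
#' @param records needle records.
#' @param case the `patient_case` (provides the lesion), or a precomputed
#'   maximal chord via `max_chord_mm`.
#' @param n_needles needles in the normalising denominator (5).
#' @param max_chord_mm optional precomputed longest needle-axis chord.
#' @param normalization `"five_needle"` (denominator
#'   `n_needles * max chord`) or `"single"` (one chord).
#' @return N.CCL in `[0, 1]` up to raster tolerance.
#' @export
n_ccl <- function(records, case = NULL, n_needles = 5L, max_chord_mm = NULL,
                  normalization = c("five_needle", "single")) {
  normalization <- match.arg(normalization)
  chord <- max_chord_mm %||% max_axis_chord_mm(case$lesion)
  if (chord <= 0) stop("empty lesion")
  denom <- if (normalization == "five_needle") n_needles * chord else chord
  ccl_total(records) / denom
}

#' Needle coverage normalised by lesion area
#'
#' @param records needle records with columns `fired` and either world
#'   coordinates `x_mm`, `y_mm` (as produced by the environment) or grid
#'   indices `i`, `j` together with `grid`.
#' @param case the `patient_case`, or supply `area_mm2`.
#' @param area_mm2 optional precomputed projected lesion area.
#' @param grid a `template_grid`, only needed when records lack `x_mm`.
#' @return `std_x * std_y * pi / Area_L` (population standard
#'   deviations); `NaN` with a warning for fewer than two fired needles.
#' @export
n_coverage <- function(records, case = NULL, area_mm2 = NULL, grid = NULL) {
  area <- area_mm2 %||% projected_area_mm2(case$lesion)
  f <- records[records$fired, , drop = FALSE]
  if (nrow(f) < 2L) {
    warning("fewer than two fired needles; coverage undefined")
    return(NaN)
  }
  if (!is.null(f$x_mm)) {
    xy <- cbind(f$x_mm, f$y_mm)
  } else {
    if (is.null(grid)) stop("records lack x_mm/y_mm; supply a grid")
    xy <- grid_node_xy(grid, f$i, f$j)
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  pop_sd(xy[, 1]) * pop_sd(xy[, 2]) * pi / area
}

#' Correlation between lesion size and measured CCL
#'
#' @param lesion_sizes_voxels lesion sizes (voxel counts), one per case.
#' @param ccls_mm measured total CCL per case.
#' @return Pearson correlation; `NaN` with a warning when either input is
#'   constant or fewer than 3 cases are given.
#' @export
ccl_coefficient <- function(lesion_sizes_voxels, ccls_mm) {
  if (length(lesion_sizes_voxels) != length(ccls_mm)) {
    stop("inputs must be paired per case")
  }
  if (length(ccls_mm) < 3L) {
    warning("need at least 3 cases for a correlation")
    return(NaN)
  }
  if (stats::sd(lesion_sizes_voxels) == 0 || stats::sd(ccls_mm) == 0) {
    warning("constant input; correlation undefined")
    return(NaN)
  }
  stats::cor(lesion_sizes_voxels, ccls_mm, method = "pearson")
}

#' Aggregate episodes into a metrics report
#'
#' Episodes of the same case are pooled before computing that case's
#' metrics; the aggregate rows are mean and across-case standard
#' deviation per metric, plus the across-case CCL coefficient.
#'
#' @param episodes list of `episode_result` objects (each carries its
#'   lesion geometry summaries).
#' @param label optional label for the mismatch setting evaluated.
#' @return object of class `metrics_report`: list with `per_case`
#'   (data.frame), `aggregate` (named list of mean/sd), `ccl_coefficient`,
#'   `label`.
#' @export
metrics_report <- function(episodes, label = NA_character_) {
  ids <- vapply(episodes, `[[`, "", "case_id")
  per_case <- lapply(split(seq_along(episodes), ids), function(idx) {
    recs <- do.call(rbind, lapply(episodes[idx], `[[`, "records"))
    ep1 <- episodes[[idx[1]]]
    fired <- sum(recs$fired)
    data.frame(
      case_id = ep1$case_id,
      episodes = length(idx),
      fired = fired,
      hits = sum(recs$hit),
      hr = if (fired > 0) sum(recs$hit) / fired else NaN,
      ccl_mm = ccl_total(recs) / length(idx),
      n_ccl = n_ccl(recs, max_chord_mm = ep1$lesion_chord_mm) / length(idx),
      n_coverage = suppressWarnings(
        n_coverage(recs, area_mm2 = ep1$lesion_area_mm2)),
      lesion_voxels = ep1$lesion_voxels,
      total_reward = mean(vapply(episodes[idx], `[[`, 0, "total_reward")),
      stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, per_case)
  rownames(per_case) <- NULL
  agg <- function(v) c(mean = mean(v[is.finite(v)]),
                       sd = stats::sd(v[is.finite(v)]))
  aggregate <- list(hr = agg(per_case$hr), ccl_mm = agg(per_case$ccl_mm),
                    n_ccl = agg(per_case$n_ccl),
                    n_coverage = agg(per_case$n_coverage),
                    total_reward = agg(per_case$total_reward))
  cc <- if (nrow(per_case) >= 3L) {
    suppressWarnings(ccl_coefficient(per_case$lesion_voxels, per_case$ccl_mm))
  } else NaN
  structure(list(per_case = per_case, aggregate = aggregate,
                 ccl_coefficient = cc, label = label),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "metrics_report (%s): %d cases\n  HR %.3f +/- %.3f | CCL %.2f +/- %.2f mm | N.CCL %.3f +/- %.3f\n  N.Coverage %.3f +/- %.3f | CCL coeff %.3f\n",
    ifelse(is.na(x$label), "no mismatch label", x$label), nrow(x$per_case),
    a$hr["mean"], a$hr["sd"], a$ccl_mm["mean"], a$ccl_mm["sd"],
    a$n_ccl["mean"], a$n_ccl["sd"], a$n_coverage["mean"], a$n_coverage["sd"],
    x$ccl_coefficient))
  invisible(x)
}

#' Write a metrics report to CSV (per case) and JSON (aggregate)
#'
#' @param report a `metrics_report`.
#' @param csv_path,json_path output paths (`NULL` skips either).
#' @return invisibly, the report.
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_case, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- list(label = report$label, aggregate = report$aggregate,
                    ccl_coefficient = report$ccl_coefficient)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                na = "null"), json_path)
  }
  invisible(report)
}

#' Paired comparison of two policies' metric reports
#'
#' Paired Student's t-tests per metric at significance level `alpha`,
#' pairing cases by `case_id`; both reports must cover the same cases.
#' When the paired differences are exactly zero for a metric the test is
#' reported as `t = 0`, `p = 1` (no evidence of a difference).
#'
#' @param report_a,report_b `metrics_report` objects over the same case
#'   set.
#' @param alpha significance level (0.05).
#' @param metrics which per-case columns to compare.
#' @return data.frame with columns `metric`, `mean_a`, `mean_b`, `t`,
#'   `p`, `significant`.
#' @export
compare_policies <- function(report_a, report_b, alpha = 0.05,
                             metrics = c("hr", "ccl_mm", "n_ccl", "n_coverage")) {
  a <- report_a$per_case
  b <- report_b$per_case
  if (!identical(sort(a$case_id), sort(b$case_id))) {
    stop("reports are not paired: case sets differ")
  }
  b <- b[match(a$case_id, b$case_id), , drop = FALSE]
  rows <- lapply(metrics, function(m) {
    va <- a[[m]]; vb <- b[[m]]
    ok <- is.finite(va) & is.finite(vb)
    d <- va[ok] - vb[ok]
    if (length(d) < 2L || stats::sd(d) == 0) {
      t_stat <- if (all(d == 0)) 0 else NaN
      p <- if (all(d == 0)) 1 else NaN
    } else {
      tt <- stats::t.test(va[ok], vb[ok], paired = TRUE)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(metric = m, mean_a = mean(va[ok]), mean_b = mean(vb[ok]),
               t = t_stat, p = p,
               significant = is.finite(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
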