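# Per-reagent CV of a block of calibrator columns, formula chosen by
# scale: linear readouts use sd/mean directly; log2-scale readouts
# (NPX) use the log-normal identity sqrt(exp((ln 2 * sd)^2) - 1), i.e.
# the CV of the implied linear-scale quantity.
cv_block <- function(values, scale) {
  s <- row_sds(values)
  if (scale == "LINEAR_RFU") {
    s / rowMeans(values)
  } else {
    sqrt(exp((log(2) * s)^2) - 1)
  }
}

cal_columns <- function(m, plates) {
  cal <- plates[plates$role == "CALIBRATOR", , drop = FALSE]
  cal <- cal[cal$sample_id %in% sample_ids(m), , drop = FALSE]
  cal
}

#' Intra-assay coefficient of variation
#'
#' Precision within a plate: for each plate carrying at least two
#' calibrator replicates, the per-reagent CV over that plate's
#' calibrators is computed on the raw (pre-harmonization) scale, then
#' averaged (unweighted) across plates.  Linear RFU readouts use
#' `sd / mean`; log2 NPX readouts use the log-normal identity
#' `sqrt(exp((ln 2 * sd_NPX)^2) - 1)`.
#'
#' @param m An `expression_matrix` on scale `LINEAR_RFU` or
#'   `NPX_LOG2`/`LOG2` containing the calibrator columns.
#' @param plates A [plate_map()] naming the calibrators.
#' @return `data.frame(reagent_id, platform, cv_intra)`.
#' @export
intra_assay_cv <- function(m, plates) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale == "ZSCORED") {
    stop("CVs are computed on raw values, not z-scores")
  }
  cal <- cal_columns(m, plates)
  per_plate <- list()
  for (p in unique(cal$plate_id)) {
    ids <- cal$sample_id[cal$plate_id == p]
    if (length(ids) < 2L) {
      warning("plate ", p, " has fewer than 2 calibrators; skipped")
      next
    }
    per_plate[[p]] <- cv_block(m$values[, ids, drop = FALSE], m$scale)
  }
  if (!length(per_plate)) stop("no plate with at least 2 calibrators")
  cv <- rowMeans(do.call(cbind, per_plate))
  data.frame(reagent_id = reagent_ids(m), platform = m$platform,
             cv_intra = unname(cv), stringsAsFactors = FALSE)
}

#' Inter-assay coefficient of variation
#'
#' Precision across plates: one CV per reagent over all calibrator
#' samples pooled across plates, same per-scale formula as
#' [intra_assay_cv()].  With plate-to-plate shifts present this
#' exceeds the intra-assay CV.
#'
#' @inheritParams intra_assay_cv
#' @return `data.frame(reagent_id, platform, cv_inter)`.
#' @export
inter_assay_cv <- function(m, plates) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale == "ZSCORED") {
    stop("CVs are computed on raw values, not z-scores")
  }
  cal <- cal_columns(m, plates)
  if (nrow(cal) < 2L) stop("need at least 2 calibrators in total")
  cv <- cv_block(m$values[, cal$sample_id, drop = FALSE], m$scale)
  data.frame(reagent_id = reagent_ids(m), platform = m$platform,
             cv_inter = unname(cv), stringsAsFactors = FALSE)
}

#' Summarize a CV distribution, optionally comparing two platforms
#'
#' Reports the 10th, 25th, 50th, 75th and 90th percentiles (linear
#' interpolation) and the fraction of reagents with CV below 20%.
#' When a second CV list is supplied, CV outliers beyond
#' `trim_fold x IQR` are removed from each list and a two-sample
#' Mann-Whitney (Wilcoxon rank-sum) test compares the distributions.
#'
#' @param cvs Numeric vector of CVs.
#' @param other Optional second vector to compare against.
#' @param trim_fold IQR multiplier for outlier trimming before the
#'   rank-sum test.
#' @return List with `percentiles`, `frac_below_0.20`, `n`, and (when
#'   `other` is given) `comparison` with the Mann-Whitney statistic
#'   and p-value.
#' @export
cv_summary <- function(cvs, other = NULL, trim_fold = 1.5) {
  cvs <- cvs[!is.na(cvs)]
  if (!length(cvs)) stop("empty CV list")
  pct <- stats::quantile(cvs, c(0.10, 0.25, 0.50, 0.75, 0.90),
                         type = 7)
  out <- list(percentiles = pct,
              frac_below_0.20 = mean(cvs < 0.20),
              n = length(cvs))
  if (!is.null(other)) {
    other <- other[!is.na(other)]
    if (!length(other)) stop("empty comparison CV list")
    trim <- function(x) {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      x[x >= q[1] - trim_fold * iqr & x <= q[2] + trim_fold * iqr]
    }
    wt <- stats::wilcox.test(trim(cvs), trim(other), exact = FALSE)
    out$comparison <- list(statistic = unname(wt$statistic),
                           p_value = wt$p.value)
  }
  out
}
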