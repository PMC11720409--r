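#' Principal component analysis of a harmonized matrix
#'
#' PCA on samples (reagents as variables) of a z-scored matrix, as used
#' to audit what each proteomic platform's variance is tracking.
#' Components are ordered by decreasing explained variance; for a
#' deterministic sign convention the loading with the largest absolute
#' value on each component is made positive.
#'
#' @param m An `expression_matrix` with scale `ZSCORED`.
#' @param n_components Number of components to retain in `scores` and
#'   `loadings` (default: all).  Explained-variance fractions are
#'   always reported for the full decomposition.
#' @return An object of class `pca_result`: list with
#'   `explained_variance` (fractions), `cumulative`, `scores`
#'   (samples x components), `loadings` (reagents x components), and
#'   `center` (per-reagent means removed before rotation).
#' @export
run_pca <- function(m, n_components = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "ZSCORED") {
    stop("run_pca expects a z-scored matrix; call log2_zscale() first")
  }
  if (ncol(m$values) < 2L) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(t(m$values), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k_all <- ncol(pc$rotation)
  k <- if (is.null(n_components)) k_all else min(n_components, k_all)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  structure(list(explained_variance = ev,
                 cumulative = cumsum(ev),
                 scores = sco,
                 loadings = rot,
                 center = pc$center),
            class = "pca_result")
}

#' @export
#' @method print pca_result
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components retained; PC1 explains %.1f%%\n",
              ncol(x$scores), 100 * x$explained_variance[1]))
  invisible(x)
}

#' Number of components needed to reach a variance target
#'
#' @param p A `pca_result`.
#' @param target Cumulative explained-variance target in (0, 1].
#' @return Smallest k with cumulative fraction >= `target`.
#' @export
pcs_for_variance <- function(p, target = 0.95) {
  stopifnot(inherits(p, "pca_result"))
  if (target <= 0 || target > 1) stop("target must lie in (0, 1]")
  which(p$cumulative >= target - 1e-12)[1L]
}

#' Top contributing reagents of a component
#'
#' Reagents ranked by absolute loading on one component, ties broken by
#' reagent id so the ranking is deterministic.
#'
#' @param p A `pca_result`.
#' @param component Component index.
#' @param k Number of reagents to return (truncated to the reagent
#'   count; `k = 0` gives an empty table).
#' @return `data.frame(reagent_id, loading)` in rank order.
#' @export
top_loadings <- function(p, component = 1L, k = 15L) {
  stopifnot(inherits(p, "pca_result"))
  if (component < 1L || component > ncol(p$loadings)) {
    stop("component ", component, " not available")
  }
  l <- p$loadings[, component]
  ord <- order(-abs(l), names(l))
  k <- min(k, length(l))
  idx <- ord[seq_len(k)]
  data.frame(reagent_id = names(l)[idx], loading = unname(l[idx]),
             stringsAsFactors = FALSE)
}

# Coerce a phenotype column to numeric for correlation/regression;
# two-level factors/characters become 0/1, others are rejected.
pheno_numeric <- function(x, name) {
  if (is.numeric(x)) return(x)
  u <- sort(unique(stats::na.omit(as.character(x))))
  if (length(u) == 2L) {
    return(as.numeric(match(as.character(x), u)) - 1)
  }
  stop("cannot coerce phenotype '", name, "' to numeric")
}

#' Screen principal components against clinical phenotypes
#'
#' Two modes mirroring the usual pair of audits: `UNADJUSTED` computes
#' the Pearson correlation (and p-value) of each top PC with each
#' phenotype separately; `JOINT` fits, per PC, one linear model of the
#' PC score on all phenotypes simultaneously and reports each
#' variable's coefficient and p-value, isolating independent
#' contributors to the variance.  Significance stars use the
#' conventional 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param scores Samples x components score matrix (row names = sample
#'   ids), e.g. `run_pca(...)$scores`.
#' @param phenotypes Phenotype `data.frame` with a `sample_id` column.
#' @param variables Phenotype columns to use (default: every column
#'   except `sample_id` that is numeric or two-level).
#' @param top_k Number of leading PCs to screen.
#' @param mode `"UNADJUSTED"` or `"JOINT"`.
#' @return `data.frame(pc, variable, estimate, p_value, stars, n)`.
#' @export
pc_phenotype_screen <- function(scores, phenotypes, variables = NULL,
                                top_k = 5L,
                                mode = c("UNADJUSTED", "JOINT")) {
  mode <- match.arg(mode)
  if (top_k > ncol(scores)) stop("top_k exceeds available components")
  idx <- match(rownames(scores), phenotypes$sample_id)
  if (anyNA(idx)) stop("phenotype table is missing some scored samples")
  ph <- phenotypes[idx, , drop = FALSE]
  if (is.null(variables)) {
    variables <- setdiff(names(ph), "sample_id")
  }
  cols <- list()
  for (v in variables) {
    x <- tryCatch(pheno_numeric(ph[[v]], v), error = function(e) NULL)
    if (is.null(x)) next
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      warning("dropping zero-variance phenotype: ", v)
      next
    }
    cols[[v]] <- x
  }
  if (!length(cols)) stop("no usable phenotype variables")
  star <- function(p) {
    ifelse(is.na(p), "",
           ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                  ifelse(p < 0.05, "*", ""))))
  }
  out <- list()
  for (j in seq_len(top_k)) {
    s <- scores[, j]
    if (mode == "UNADJUSTED") {
      for (v in names(cols)) {
        ok <- stats::complete.cases(s, cols[[v]])
        ct <- stats::cor.test(s[ok], cols[[v]][ok])
        out[[length(out) + 1L]] <- data.frame(
          pc = j, variable = v, estimate = unname(ct$estimate),
          p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
      }
    } else {
      d <- as.data.frame(cols)
      ok <- stats::complete.cases(s, d)
      fit <- stats::lm(s[ok] ~ ., data = d[ok, , drop = FALSE])
      cf <- summary(fit)$coefficients
      vars <- setdiff(rownames(cf), "(Intercept)")
      out[[length(out) + 1L]] <- data.frame(
        pc = j, variable = vars, estimate = cf[vars, 1],
        p_value = cf[vars, 4], n = sum(ok), row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$stars <- star(res$p_value)
  res[, c("pc", "variable", "estimate", "p_value", "stars", "n")]
}

#' Flag outlier samples by the IQR rule on PC scores
#'
#' A sample is excluded when, on any listed component, its score falls
#' below `Q1 - fold * IQR` or above `Q3 + fold * IQR` (quartiles by
#' linear interpolation).
#'
#' @param scores Samples x components score matrix with sample-id row
#'   names.
#' @param components Component indices to test (default PC1 and PC2).
#' @param fold IQR multiplier (> 0), conventionally 1.5.
#' @return Character vector of excluded sample ids (possibly empty).
#' @export
iqr_outlier_samples <- function(scores, components = c(1L, 2L),
                                fold = 1.5) {
  if (fold <= 0) stop("fold must be positive")
  if (!is.finite(fold)) return(character())
  components <- components[components <= ncol(scores)]
  bad <- rep(FALSE, nrow(scores))
  for (j in components) {
    s <- scores[, j]
    q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    bad <- bad | s < q[1] - fold * iqr | s > q[2] + fold * iqr
  }
  rownames(scores)[bad]
}
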