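#' Classify a Spearman coefficient into a correlation category
#'
#' The three-way scheme used throughout the reproducibility metric:
#' GOOD when rho >= 0.5, MODERATE when 0.3 <= rho < 0.5, POOR
#' otherwise (all negative coefficients are POOR).  Both boundaries
#' are inclusive on the side of the better category.
#'
#' @param rho Numeric vector of Spearman coefficients in [-1, 1].
#' @return Character vector of `"GOOD"`, `"MODERATE"`, `"POOR"`.
#' @export
classify_rho <- function(rho) {
  if (any(rho < -1 - 1e-12 | rho > 1 + 1e-12, na.rm = TRUE)) {
    stop("rho outside [-1, 1]")
  }
  ifelse(rho >= 0.5, "GOOD", ifelse(rho >= 0.3, "MODERATE", "POOR"))
}

#' Spearman correlation of matched reagent pairs
#'
#' For every pair, the Spearman rank correlation (average ranks for
#' ties) of the two reagents' values over the overlapping samples,
#' using complete observations per pair.  Pairs with fewer than
#' `min_n` complete overlapping observations, or with a constant
#' value vector, are omitted with a message.
#'
#' @param a,b `expression_matrix` objects (harmonized or log2; the
#'   coefficient is rank-based so any monotone per-reagent transform
#'   gives identical results).
#' @param pairs `data.frame` with columns `reagent_a`, `reagent_b`
#'   referencing rows of `a` and `b`; for intra-run correlation of the
#'   same physical reagents, both columns carry the same ids.
#' @param comparison Label stored on each record, e.g. `"INTRA_AB"`,
#'   `"INTER_A_OLINK"`, `"INTER_B_OLINK"`.
#' @param min_n Minimum complete overlapping observations per pair.
#' @return `data.frame(reagent_a, reagent_b, comparison, rho, n,
#'   category)`.
#' @export
correlate_pairs <- function(a, b, pairs, comparison = "INTRA_AB",
                            min_n = 10L) {
  al <- align_overlap(a, b)
  miss_a <- setdiff(pairs$reagent_a, reagent_ids(al$a))
  miss_b <- setdiff(pairs$reagent_b, reagent_ids(al$b))
  if (length(miss_a) || length(miss_b)) {
    stop("pairs reference reagents absent from the matrices: ",
         paste(utils::head(c(miss_a, miss_b), 5L), collapse = ", "))
  }
  if (!nrow(pairs)) {
    warning("no pairs to correlate")
    return(data.frame(reagent_a = character(), reagent_b = character(),
                      comparison = character(), rho = numeric(),
                      n = integer(), category = character()))
  }
  va <- al$a$values[pairs$reagent_a, , drop = FALSE]
  vb <- al$b$values[pairs$reagent_b, , drop = FALSE]
  n_pairs <- nrow(pairs)
  rho <- rep(NA_real_, n_pairs)
  nn <- integer(n_pairs)
  complete <- !anyNA(va) && !anyNA(vb)
  if (complete) {
    nn[] <- ncol(va)
    ra <- row_ranks(va)
    rb <- row_ranks(vb)
    ca <- ra - rowMeans(ra)
    cb <- rb - rowMeans(rb)
    den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
    num <- rowSums(ca * cb)
    rho <- ifelse(den > 0, num / den, NA_real_)
  } else {
    for (i in seq_len(n_pairs)) {
      ok <- stats::complete.cases(va[i, ], vb[i, ])
      nn[i] <- sum(ok)
      if (nn[i] >= 2L) {
        rho[i] <- suppressWarnings(
          stats::cor(va[i, ok], vb[i, ok], method = "spearman"))
      }
    }
  }
  keep <- !is.na(rho) & nn >= min_n
  dropped <- n_pairs - sum(keep)
  if (dropped > 0L) {
    message(dropped, " pair(s) omitted (fewer than ", min_n,
            " complete observations or undefined rho)")
  }
  data.frame(reagent_a = pairs$reagent_a[keep],
             reagent_b = pairs$reagent_b[keep],
             comparison = rep_len(comparison, sum(keep)),
             rho = rho[keep], n = nn[keep],
             category = as.character(classify_rho(rho[keep])),
             row.names = NULL, stringsAsFactors = FALSE)
}

# The 12-cell score map: intra category x best inter category -> 1-9,
# and intra category alone -> A-C for reagents with no antibody match.
.score_grid <- matrix(as.character(1:9), nrow = 3, byrow = TRUE,
                      dimnames = list(c("GOOD", "MODERATE", "POOR"),
                                      c("GOOD", "MODERATE", "POOR")))
.score_noolink <- c(GOOD = "A", MODERATE = "B", POOR = "C")

#' Combine intra- and inter-platform categories into the 1-9/A-C score
#'
#' The reproducibility-and-reliability score of a single aptamer:
#' scores 1-9 cross the intra-run category (rows) with the best
#' inter-platform category (columns); aptamers whose protein has no
#' antibody-panel assay get A/B/C from the intra-run category alone.
#' When both inter-platform comparisons are available, the one with
#' the highest rho decides the column.
#'
#' @param intra_category `"GOOD"`, `"MODERATE"` or `"POOR"` from the
#'   intra-run correlation.
#' @param inter Optional `data.frame(category, rho)` with at most one
#'   row per inter-platform comparison (0-2 rows).
#' @return A single score string in `1`-`9` or `A`-`C`.
#' @export
assign_score <- function(intra_category, inter = NULL) {
  intra_category <- match.arg(intra_category,
                              c("GOOD", "MODERATE", "POOR"))
  if (is.null(inter) || nrow(inter) == 0L) {
    return(unname(.score_noolink[intra_category]))
  }
  if (nrow(inter) > 2L) {
    stop("at most one record per inter-platform comparison (2 total)")
  }
  best <- inter[which.max(inter$rho), ]
  unname(.score_grid[intra_category, best$category])
}

#' Score every aptamer from its correlation records
#'
#' Joins the intra-run records with the (optional) inter-platform
#' records and applies [assign_score()] per aptamer.  When an aptamer
#' has several antibody matches within one comparison (multi-panel
#' assays) the maximum rho within that comparison is used, in keeping
#' with the best-rho tie-break.
#'
#' @param intra Correlation records from the two aptamer runs
#'   (`reagent_a == reagent_b`, comparison `INTRA_AB`).
#' @param inter_a,inter_b Optional inter-platform records for the two
#'   aptamer runs vs the antibody panel (aptamer ids in `reagent_a`).
#' @return `data.frame(reagent_id, intra_rho, intra_category,
#'   inter_rho_a, inter_rho_b, best_inter_rho, best_inter_category,
#'   score)`.
#' @export
score_reproducibility <- function(intra, inter_a = NULL, inter_b = NULL) {
  best_per_reagent <- function(rec) {
    if (is.null(rec) || !nrow(rec)) return(NULL)
    o <- rec[order(rec$reagent_a, -rec$rho), ]
    o[!duplicated(o$reagent_a), c("reagent_a", "rho", "category")]
  }
  ba <- best_per_reagent(inter_a)
  bb <- best_per_reagent(inter_b)
  out <- data.frame(reagent_id = intra$reagent_a,
                    intra_rho = intra$rho,
                    intra_category = intra$category,
                    stringsAsFactors = FALSE)
  out$inter_rho_a <- if (is.null(ba)) NA_real_ else
    ba$rho[match(out$reagent_id, ba$reagent_a)]
  out$inter_rho_b <- if (is.null(bb)) NA_real_ else
    bb$rho[match(out$reagent_id, bb$reagent_a)]
  out$best_inter_rho <- pmax(out$inter_rho_a, out$inter_rho_b,
                             na.rm = TRUE)
  out$best_inter_rho[is.infinite(out$best_inter_rho)] <- NA_real_
  out$best_inter_category <- ifelse(is.na(out$best_inter_rho),
                                    NA_character_,
                                    classify_rho(out$best_inter_rho))
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    if (is.na(out$best_inter_rho[i])) {
      assign_score(out$intra_category[i])
    } else {
      assign_score(out$intra_category[i],
                   data.frame(category = out$best_inter_category[i],
                              rho = out$best_inter_rho[i]))
    }
  }, character(1))
  out
}

#' Tabulate reproducibility scores
#'
#' Counts and percentages per score over the grand total of scored
#' reagents, with separate totals for the 1-9 branch (proteins on both
#' platforms) and the A-C branch (aptamer-only), the reproducible set
#' (scores 1, 2, 3 and A), and optionally the unique-protein collapse
#' of each count via an annotation table.
#'
#' @param scores Either the table from [score_reproducibility()] or a
#'   character vector of scores; in the vector case reagent ids are
#'   taken from names when present.
#' @param annotation Optional `reagent_annotation` for the
#'   unique-protein collapse.
#' @return List with `table` (`score`, `n`, `percent`, and
#'   `n_proteins` when annotation given), `n_total`, `n_both`
#'   (scores 1-9), `n_soma_only` (A-C), `reproducible_ids`,
#'   `n_reproducible`, and `n_reproducible_proteins` when annotation
#'   given.
#' @export
summarize_scores <- function(scores, annotation = NULL) {
  if (is.data.frame(scores)) {
    sc <- scores$score
    ids <- scores$reagent_id
  } else {
    sc <- as.character(scores)
    ids <- if (!is.null(names(scores))) names(scores) else
      as.character(seq_along(scores))
  }
  if (!length(sc)) stop("empty score list")
  levels <- c(as.character(1:9), "A", "B", "C")
  bad <- setdiff(unique(sc), levels)
  if (length(bad)) stop("unknown scores: ", paste(bad, collapse = ", "))
  counts <- table(factor(sc, levels = levels))
  present <- counts > 0
  tab <- data.frame(score = names(counts)[present],
                    n = as.integer(counts[present]),
                    percent = 100 * as.integer(counts[present]) / length(sc),
                    stringsAsFactors = FALSE)
  repro <- sc %in% c("1", "2", "3", "A")
  out <- list(table = tab,
              n_total = length(sc),
              n_both = sum(sc %in% as.character(1:9)),
              n_soma_only = sum(sc %in% c("A", "B", "C")),
              reproducible_ids = ids[repro],
              n_reproducible = sum(repro))
  if (!is.null(annotation)) {
    out$table$n_proteins <- vapply(out$table$score, function(s) {
      length(collapse_to_proteins(ids[sc == s], annotation))
    }, integer(1))
    out$n_reproducible_proteins <-
      length(collapse_to_proteins(ids[repro], annotation))
  }
  out
}
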