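#' Top-K identifiers of a ranked association table
#'
#' @param ranked A ranked per-phenotype table from
#'   [association_screen()] (or any `data.frame` with `reagent_id` in
#'   rank order).
#' @param k Number of leading identifiers (when the ranking is shorter
#'   than `k`, all are returned with a warning).
#' @return Character vector of the first `k` reagent ids.
#' @export
top_k <- function(ranked, k = 500L) {
  if (!nrow(ranked)) stop("empty ranking")
  if (k > nrow(ranked)) {
    warning("ranking has only ", nrow(ranked), " entries; taking all")
    k <- nrow(ranked)
  }
  ranked$reagent_id[seq_len(k)]
}

#' Intersection of several identifier sets
#'
#' The m-way intersection at reagent level, plus the unique-protein
#' collapse through an annotation table when one is supplied (several
#' reagents can target one protein, so the two sizes differ).
#'
#' @param sets List of >= 2 character vectors.
#' @param annotation Optional `reagent_annotation` for the protein
#'   collapse.
#' @return List with `reagents` (intersection), `n_reagents`, and when
#'   annotation is given `proteins`, `n_proteins`.
#' @export
multi_overlap <- function(sets, annotation = NULL) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  inter <- Reduce(intersect, lapply(sets, unique))
  out <- list(reagents = inter, n_reagents = length(inter))
  if (!is.null(annotation)) {
    out$proteins <- if (length(inter)) {
      collapse_to_proteins(inter, annotation)
    } else character()
    out$n_proteins <- length(out$proteins)
  }
  out
}

#' Bootstrap null distribution of a top-K multi-set overlap
#'
#' Per iteration, draws `m` multisets of `k` uniform with-replacement
#' draws from a universe of `N` identifiers, reduces each to its
#' unique elements, and records the size of the m-way intersection.
#' The mean of this null has the closed form
#' `N * (1 - (1 - 1/N)^k)^m`, which the simulation reproduces within
#' Monte-Carlo error.
#'
#' @param N Universe size (>= 1).
#' @param k Draws per set (>= 1).
#' @param m Number of sets.
#' @param B Iterations.
#' @param seed Optional seed (RNG state restored afterwards).
#' @return Object of class `overlap_null`: list with `N, k, m, B,
#'   seed, sizes` (the B intersection sizes), `sim_mean`, `sim_sd`
#'   (n-1 denominator), and `expected` (closed form).
#' @export
bootstrap_overlap_null <- function(N, k = 500L, m = 3L, B = 10000L,
                                   seed = NULL) {
  if (N < 1 || k < 1 || B < 1 || m < 1) stop("invalid sizes")
  sizes <- with_seed(seed, {
    s <- integer(B)
    for (b in seq_len(B)) {
      acc <- integer(N)
      for (j in seq_len(m)) {
        u <- unique(sample.int(N, k, replace = TRUE))
        acc[u] <- acc[u] + 1L
      }
      s[b] <- sum(acc == m)
    }
    s
  })
  structure(list(N = N, k = k, m = m, B = B, seed = seed,
                 sizes = sizes,
                 sim_mean = mean(sizes),
                 sim_sd = stats::sd(sizes),
                 expected = N * (1 - (1 - 1 / N)^k)^m),
            class = "overlap_null")
}

#' @export
#' @method print overlap_null
print.overlap_null <- function(x, ...) {
  cat(sprintf(
    "<overlap_null> N=%d k=%d m=%d B=%d | mean %.3f sd %.3f (closed form %.3f)\n",
    x$N, x$k, x$m, x$B, x$sim_mean, x$sim_sd, x$expected))
  invisible(x)
}

#' Empirical p-value of an observed overlap against a simulated null
#'
#' Add-one convention: `(count(sim >= observed) + 1) / (B + 1)`, so an
#' observation exceeding every simulated value reports
#' `1 / (B + 1)` rather than zero.
#'
#' @param observed Observed overlap size.
#' @param simulated Numeric vector of simulated sizes (e.g.
#'   `bootstrap_overlap_null(...)$sizes`).
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, simulated) {
  if (!length(simulated)) stop("empty simulation list")
  (sum(simulated >= observed) + 1) / (length(simulated) + 1)
}

#' 2x2 enrichment statistics for overlap hits in two reagent sets
#'
#' Builds the table (hits vs non-hits) x (set A vs set B), and reports
#' the odds ratio with its 95% normal-approximation confidence
#' interval on the log scale and the Pearson chi-square p-value
#' (without continuity correction).  When any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to all four cells and
#' flagged.
#'
#' @param hits_a,n_a Hits and total in set A.
#' @param hits_b,n_b Hits and total in set B.
#' @return List with `table`, `odds_ratio`, `ci95`, `chi2_p`,
#'   `corrected`.
#' @export
enrichment_stats <- function(hits_a, n_a, hits_b, n_b) {
  if (hits_a < 0 || hits_b < 0 || hits_a > n_a || hits_b > n_b) {
    stop("need 0 <= hits <= n in both sets")
  }
  if (n_a == 0 && n_b == 0) stop("both sets empty")
  tab <- matrix(c(hits_a, n_a - hits_a, hits_b, n_b - hits_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("A", "B"),
                                outcome = c("hit", "non_hit")))
  corrected <- any(tab == 0)
  ct <- if (corrected) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se_log <- sqrt(sum(1 / ct))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, odds_ratio = or, ci95 = ci,
       chi2_p = chi$p.value, corrected = corrected)
}
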