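#' Bonferroni-corrected significance threshold
#'
#' @param alpha Familywise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

# Linear fit of y on design X (first column intercept) with Wald
# statistics for the column named in `term`.  Uses lm.fit directly so
# a whole screen of reagents against one fixed design stays fast.
fast_lm <- function(X, y, term) {
  fit <- stats::lm.fit(X, y)
  p <- fit$rank
  if (p < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  res <- fit$residuals
  df <- length(y) - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  covp <- chol2inv(R) * sigma2
  se <- numeric(ncol(X))
  se[piv] <- sqrt(diag(covp))
  names(se) <- colnames(X)
  beta <- fit$coefficients[term]
  tval <- beta / se[term]
  list(beta = unname(beta), se = unname(se[term]),
       p = 2 * stats::pt(-abs(tval), df), converged = TRUE)
}

#' Fit one protein-phenotype association model
#'
#' `LINEAR`: the (z-scored) protein level is regressed on the
#' phenotype plus covariates, and the two-sided Wald p-value of the
#' phenotype coefficient is reported, so `beta` is the change in
#' protein level (in SD units) per unit of phenotype.  `LOGISTIC`
#' (used for sex): the binary phenotype is the outcome and the protein
#' a predictor alongside the covariates.  Non-converged logistic fits
#' (e.g. perfect separation) are flagged with a missing p-value.
#'
#' @param protein Numeric vector of z-scored protein levels.
#' @param phenotype Numeric (LINEAR) or two-level (LOGISTIC) vector.
#' @param covariates Optional `data.frame` of covariate columns.
#' @param family `"LINEAR"` or `"LOGISTIC"`.
#' @return One-row `data.frame(beta, se, p, n_used, converged)`.
#' @export
fit_association <- function(protein, phenotype, covariates = NULL,
                            family = c("LINEAR", "LOGISTIC")) {
  family <- match.arg(family)
  cov_df <- if (is.null(covariates)) {
    data.frame(row.names = seq_along(protein))
  } else {
    as.data.frame(covariates)
  }
  n_cov <- ncol(cov_df)
  ok <- if (n_cov) {
    stats::complete.cases(protein, phenotype, cov_df)
  } else {
    stats::complete.cases(protein, phenotype)
  }
  n_used <- sum(ok)
  if (n_used < n_cov + 3L) stop("too few complete cases")
  cov_ok <- cov_df[ok, , drop = FALSE]
  Xcov <- if (n_cov) stats::model.matrix(~ ., data = cov_ok)[, -1, drop = FALSE]
  else matrix(nrow = n_used, ncol = 0)
  if (family == "LINEAR") {
    ph <- pheno_numeric(phenotype, "phenotype")[ok]
    X <- cbind("(Intercept)" = 1, phenotype = ph, Xcov)
    f <- fast_lm(X, protein[ok], "phenotype")
    data.frame(beta = f$beta, se = f$se, p = f$p, n_used = n_used,
               converged = TRUE, family = family)
  } else {
    yb <- pheno_numeric(phenotype, "phenotype")[ok]
    if (length(unique(yb)) < 2L) stop("phenotype has a single class")
    X <- cbind("(Intercept)" = 1, protein = protein[ok], Xcov)
    fit <- suppressWarnings(
      stats::glm.fit(X, yb, family = stats::binomial()))
    cf <- fit$coefficients
    if (any(is.na(cf))) {
      stop("rank-deficient design; collinear columns: ",
           paste(colnames(X)[is.na(cf)], collapse = ", "))
    }
    # Wald statistics from the IRLS weights
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    covm <- tryCatch(solve(XtWX), error = function(e) NULL)
    se <- if (is.null(covm)) NA_real_ else sqrt(diag(covm))["protein"]
    conv <- fit$converged && !is.null(covm) &&
      is.finite(se) && se < 50
    z <- cf["protein"] / se
    data.frame(beta = unname(cf["protein"]), se = unname(se),
               p = if (conv) 2 * stats::pnorm(-abs(z)) else NA_real_,
               n_used = n_used, converged = conv, family = family)
  }
}

#' Covariate set used when screening one phenotype
#'
#' The default adjustment policy: sex, age and CSF total protein
#' always; assay technique additionally when the phenotype is a CSF
#' core biomarker; and a covariate equal to the tested phenotype is
#' dropped (no self-adjustment).
#'
#' @param phenotype Phenotype being screened.
#' @param phenotypes Phenotype table (to check availability).
#' @param covariates Base covariate set.
#' @param technique_for Phenotypes that additionally adjust for
#'   technique.
#' @return Character vector of covariate column names.
#' @export
screen_covariates <- function(phenotype, phenotypes,
                              covariates = c("sex", "age",
                                             "csf_total_protein"),
                              technique_for = c("csf_ab42", "csf_ptau")) {
  covs <- setdiff(covariates, phenotype)
  if (phenotype %in% technique_for && "technique" %in% names(phenotypes)) {
    covs <- c(covs, "technique")
  }
  intersect(covs, names(phenotypes))
}

#' Screen every reagent against a set of phenotypes
#'
#' One covariate-adjusted association per (reagent, phenotype), with
#' per-phenotype ranking by ascending p-value (ties broken by
#' descending absolute effect, then reagent id) and a significance
#' flag at the Bonferroni threshold `alpha / n_reagents_tested`.  Sex
#' is screened with the logistic orientation; every other phenotype
#' with the linear orientation (protein as outcome).  Total tau is
#' deliberately never screened: it is nearly collinear with p-tau.
#'
#' @param m A z-scored `expression_matrix`.
#' @param phenotypes Phenotype table with `sample_id`.
#' @param phenotype_names Phenotypes to screen.
#' @param alpha Familywise error rate for the Bonferroni flag.
#' @param covariates Base covariate set (self-adjustment is removed
#'   automatically).
#' @param technique_for Phenotypes that additionally adjust for assay
#'   technique.
#' @param scores Optional reproducibility table
#'   ([score_reproducibility()]) joined onto the rows.
#' @return `data.frame` with one row per (reagent, phenotype), ranked
#'   within phenotype, columns `reagent_id, phenotype, family, beta,
#'   se, p, n_used, rank, significant` (+ `score` when given).
#' @export
association_screen <- function(m, phenotypes,
                               phenotype_names,
                               alpha = 0.05,
                               covariates = c("sex", "age",
                                              "csf_total_protein"),
                               technique_for = c("csf_ab42", "csf_ptau"),
                               scores = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "ZSCORED") {
    stop("association_screen expects z-scored protein levels")
  }
  if ("csf_ttau" %in% phenotype_names) {
    warning("t-tau is not screened (collinear with p-tau); dropping it")
    phenotype_names <- setdiff(phenotype_names, "csf_ttau")
  }
  idx <- match(sample_ids(m), phenotypes$sample_id)
  keep <- !is.na(idx)
  ph <- phenotypes[idx[keep], , drop = FALSE]
  V <- m$values[, keep, drop = FALSE]
  n_reagents <- nrow(V)
  thr <- bonferroni_threshold(alpha, n_reagents)
  out <- list()
  for (pn in phenotype_names) {
    if (!pn %in% names(ph)) {
      warning("phenotype not found, skipped: ", pn)
      next
    }
    covs <- screen_covariates(pn, ph, covariates, technique_for)
    cov_df <- ph[, covs, drop = FALSE]
    family <- if (pn == "sex") "LOGISTIC" else "LINEAR"
    pheno <- ph[[pn]]
    ok <- stats::complete.cases(pheno, cov_df)
    if (family == "LINEAR") {
      # one QR for the whole screen: the design is fixed, only the
      # protein outcome changes
      pnum <- pheno_numeric(pheno, pn)[ok]
      Xcov <- if (length(covs)) {
        stats::model.matrix(~ ., data = cov_df[ok, , drop = FALSE])[, -1,
                                                                    drop = FALSE]
      } else matrix(nrow = sum(ok), ncol = 0)
      X <- cbind("(Intercept)" = 1, phenotype = pnum, Xcov)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        stop("rank-deficient design for ", pn, "; collinear columns: ",
             paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]],
                   collapse = ", "))
      }
      R <- qr.R(qrX)
      xtx_diag <- numeric(ncol(X))
      xtx_diag[qrX$pivot] <- diag(chol2inv(R))
      df_res <- sum(ok) - ncol(X)
      coefs <- qr.coef(qrX, t(V[, ok, drop = FALSE]))
      resid <- qr.resid(qrX, t(V[, ok, drop = FALSE]))
      sigma2 <- colSums(resid^2) / df_res
      beta <- coefs["phenotype", ]
      se <- sqrt(sigma2 * xtx_diag[match("phenotype", colnames(X))])
      pval <- 2 * stats::pt(-abs(beta / se), df_res)
      res <- data.frame(reagent_id = rownames(V), phenotype = pn,
                        family = family, beta = unname(beta),
                        se = unname(se), p = unname(pval),
                        n_used = sum(ok), converged = TRUE,
                        stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_len(n_reagents), function(i) {
        fit_association(V[i, ], pheno, cov_df, family = "LOGISTIC")
      })
      res <- do.call(rbind, rows)
      res <- data.frame(reagent_id = rownames(V), phenotype = pn,
                        family = family, beta = res$beta, se = res$se,
                        p = res$p, n_used = res$n_used,
                        converged = res$converged,
                        stringsAsFactors = FALSE)
    }
    ord <- order(res$p, -abs(res$beta), res$reagent_id, na.last = TRUE)
    res <- res[ord, ]
    res$rank <- seq_len(nrow(res))
    res$significant <- !is.na(res$p) & res$p < thr
    out[[pn]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(scores)) {
    res$score <- scores$score[match(res$reagent_id, scores$reagent_id)]
  }
  attr(res, "bonferroni_threshold") <- thr
  attr(res, "n_reagents_tested") <- n_reagents
  res
}

# Rank-based AUC (equivalent to the Mann-Whitney statistic).
auc_rank <- function(y, score) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out performance of an L1-penalized proteomic signature
#'
#' Splits the samples 80/20 (stratified for a binary phenotype), tunes
#' the LASSO penalty on the training portion by 5-fold
#' cross-validation repeated 5 times over the data-derived lambda path
#' (selection by RMSE for continuous phenotypes, AUC for binary), then
#' reports performance on the untouched 20%: held-out R-squared, or
#' AUC with sensitivity and specificity at the 0.5 probability
#' threshold.
#'
#' @param m A z-scored `expression_matrix`.
#' @param phenotypes Phenotype table with `sample_id`.
#' @param phenotype Phenotype column name.
#' @param features Reagent ids to use as predictors (default all).
#' @param n_folds,n_repeats Cross-validation scheme (5 x 5 default).
#' @param train_frac Training fraction of the split.
#' @param seed Seed controlling split, folds and fit.
#' @return List of class `lasso_report` with the metric(s), the chosen
#'   lambda, the feature-set label and the scheme descriptor.
#' @export
lasso_performance <- function(m, phenotypes, phenotype,
                              features = NULL,
                              n_folds = 5L, n_repeats = 5L,
                              train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(m, "expression_matrix"))
  if (is.null(features)) features <- reagent_ids(m)
  if (length(features) < 2L) stop("need at least 2 features")
  idx <- match(sample_ids(m), phenotypes$sample_id)
  keep <- !is.na(idx) & !is.na(phenotypes[[phenotype]][idx])
  X <- t(m$values[features, keep, drop = FALSE])
  yraw <- phenotypes[[phenotype]][idx[keep]]
  n <- nrow(X)
  if (n < 50L) stop("need at least 50 samples")
  if (length(unique(stats::na.omit(yraw))) < 2L) {
    stop("degenerate phenotype: a single class")
  }
  binary <- !is.numeric(yraw) ||
    length(unique(stats::na.omit(yraw))) == 2L
  y <- pheno_numeric(yraw, phenotype)
  fam <- if (binary) "binomial" else "gaussian"
  with_seed(seed, {
    if (binary) {
      tr <- unlist(lapply(split(seq_len(n), y), function(ix) {
        sample(ix, round(train_frac * length(ix)))
      }), use.names = FALSE)
    } else {
      tr <- sample(seq_len(n), round(train_frac * n))
    }
    te <- setdiff(seq_len(n), tr)
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    path <- glmnet::glmnet(Xtr, ytr, family = fam)
    lam <- path$lambda
    metric <- matrix(NA_real_, nrow = length(lam),
                     ncol = n_folds * n_repeats)
    col <- 0L
    for (r in seq_len(n_repeats)) {
      folds <- if (binary) {
        f <- integer(length(ytr))
        for (cl in unique(ytr)) {
          ix <- which(ytr == cl)
          f[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
        }
        f
      } else {
        sample(rep_len(seq_len(n_folds), length(ytr)))
      }
      for (k in seq_len(n_folds)) {
        col <- col + 1L
        hold <- folds == k
        fit <- glmnet::glmnet(Xtr[!hold, , drop = FALSE], ytr[!hold],
                              family = fam, lambda = lam)
        pred <- stats::predict(fit, Xtr[hold, , drop = FALSE],
                               s = lam, type = "response")
        if (binary) {
          metric[, col] <- apply(pred, 2L, function(p)
            auc_rank(ytr[hold], p))
        } else {
          metric[, col] <- sqrt(colMeans((pred - ytr[hold])^2))
        }
      }
    }
    mbar <- rowMeans(metric, na.rm = TRUE)
    best <- if (binary) which.max(mbar) else which.min(mbar)
    lambda_opt <- lam[best]
    pred_te <- as.vector(
      stats::predict(path, X[te, , drop = FALSE], s = lambda_opt,
                     type = "response"))
    if (binary) {
      yte <- y[te]
      cls <- as.integer(pred_te >= 0.5)
      report <- list(metric = "AUC",
                     auc = auc_rank(yte, pred_te),
                     sensitivity = sum(cls == 1 & yte == 1) /
                       max(1L, sum(yte == 1)),
                     specificity = sum(cls == 0 & yte == 0) /
                       max(1L, sum(yte == 0)))
    } else {
      yte <- y[te]
      r2 <- 1 - sum((yte - pred_te)^2) / sum((yte - mean(yte))^2)
      report <- list(metric = "R2", r2 = r2)
    }
    structure(c(report,
                list(phenotype = phenotype,
                     n_features = length(features),
                     lambda = lambda_opt,
                     scheme = sprintf("%d-fold CV repeated %d times, %d/%d split",
                                      n_folds, n_repeats,
                                      round(100 * train_frac),
                                      round(100 * (1 - train_frac))),
                     n_train = length(tr), n_test = length(te),
                     seed = seed)),
              class = "lasso_report")
  })
}

#' @export
#' @method print lasso_report
print.lasso_report <- function(x, ...) {
  cat(sprintf("<lasso_report> %s | %s | ", x$phenotype, x$scheme))
  if (x$metric == "AUC") {
    cat(sprintf("held-out AUC %.4f (sens %.3f, spec %.3f)\n",
                x$auc, x$sensitivity, x$specificity))
  } else {
    cat(sprintf("held-out R2 %.4f\n", x$r2))
  }
  invisible(x)
}
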