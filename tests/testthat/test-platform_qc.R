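test_that("PCA recovers rank-1 structure and reconstructs the data", {
  with_seed(3, {
    base <- rnorm(20)
    v <- rbind(base, 2 * base)  # perfectly collinear reagents
    m <- log2_zscale(make_matrix(2^v * 100, "LINEAR_RFU"))
    p <- run_pca(m)
    expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)
    expect_equal(pcs_for_variance(p), 1L)

    z <- random_zscored(15, 25, seed = 8)
    p2 <- run_pca(z)
    expect_true(all(diff(p2$cumulative) >= -1e-12))
    expect_true(all(p2$explained_variance >= 0))
    expect_lte(sum(p2$explained_variance), 1 + 1e-9)
    recon <- p2$scores %*% t(p2$loadings)
    recon <- sweep(recon, 2, p2$center, "+")
    expect_equal(unname(recon), unname(t(z$values)), tolerance = 1e-8)
  })
})

test_that("isotropic data spreads variance across components", {
  z <- random_zscored(50, 500, seed = 21)
  p <- run_pca(z)
  ev <- p$explained_variance[p$explained_variance > 1e-12]
  expect_lt(max(ev), 3 * mean(ev))
})

test_that("pcs_for_variance finds the smallest sufficient k", {
  fake <- structure(list(explained_variance = c(0.5, 0.3, 0.2),
                         cumulative = cumsum(c(0.5, 0.3, 0.2))),
                    class = "pca_result")
  expect_equal(pcs_for_variance(fake, 0.95), 3L)
  expect_equal(pcs_for_variance(fake, 0.80), 2L)
  fake2 <- structure(list(explained_variance = c(0.96, 0.04),
                          cumulative = c(0.96, 1)), class = "pca_result")
  expect_equal(pcs_for_variance(fake2, 0.95), 1L)
  expect_error(pcs_for_variance(fake, 0), "\\(0, 1\\]")
  expect_error(pcs_for_variance(fake, 1.1), "\\(0, 1\\]")
})

test_that("top_loadings ranks by absolute contribution", {
  loads <- matrix(c(0.9, -0.95, 0.1), ncol = 1,
                  dimnames = list(c("rA", "rB", "rC"), "PC1"))
  fake <- structure(list(loadings = loads), class = "pca_result")
  tl <- top_loadings(fake, 1, 2)
  expect_identical(tl$reagent_id, c("rB", "rA"))
  expect_equal(tl$loading, c(-0.95, 0.9))
  expect_equal(nrow(top_loadings(fake, 1, 0)), 0L)
  expect_equal(nrow(top_loadings(fake, 1, 99)), 3L)
  expect_error(top_loadings(fake, 5), "not available")
})

test_that("a planted dominant reagent tops the PC1 loadings", {
  with_seed(13, {
    v <- matrix(rnorm(30 * 40), nrow = 30)
    shared <- rnorm(40, sd = 4)
    v[7, ] <- shared + rnorm(40, sd = 0.2)
    v[8, ] <- 0.9 * shared + rnorm(40, sd = 0.5)
    m <- make_matrix(2^v * 1000, "LINEAR_RFU")
    p <- run_pca(log2_zscale(m))
    expect_true(top_loadings(p, 1, 1)$reagent_id %in% c("r7", "r8"))
  })
})

test_that("PC-phenotype screens recover constructed associations", {
  st <- small_study()
  co <- st$cohort
  scores <- cbind(PC1 = co$age,
                  PC2 = with_seed(4, rnorm(nrow(co))))
  rownames(scores) <- co$sample_id
  un <- pc_phenotype_screen(scores, co, variables = c("age", "mmse"),
                            top_k = 2, mode = "UNADJUSTED")
  r_age <- un[un$pc == 1 & un$variable == "age", ]
  expect_equal(r_age$estimate, 1, tolerance = 1e-12)
  expect_lt(r_age$p_value, 1e-100)
  expect_identical(r_age$stars, "***")
  # an independent noise PC should not correlate strongly
  r_noise <- un[un$pc == 2 & un$variable == "age", ]
  expect_lt(abs(r_noise$estimate), 0.25)

  # joint model: PC built from p-tau recovers the sign at p < 0.001
  pt <- scale(co$csf_ptau)[, 1]
  scores2 <- cbind(PC1 = 0.8 * pt + with_seed(5, rnorm(nrow(co), sd = 0.5)))
  rownames(scores2) <- co$sample_id
  jt <- pc_phenotype_screen(scores2, co,
                            variables = c("csf_ptau", "age", "sex"),
                            top_k = 1, mode = "JOINT")
  r_pt <- jt[jt$variable == "csf_ptau", ]
  expect_gt(r_pt$estimate, 0)
  expect_lt(r_pt$p_value, 0.001)
})

test_that("IQR outlier rule flags extreme PC scores only", {
  s <- matrix(c(0, 0, 0, 0, 100), ncol = 1,
              dimnames = list(sprintf("s%d", 1:5), "PC1"))
  expect_identical(iqr_outlier_samples(s, components = 1), "s5")
  same <- matrix(rep(2, 6), ncol = 1,
                 dimnames = list(sprintf("s%d", 1:6), "PC1"))
  expect_length(iqr_outlier_samples(same, components = 1), 0L)
  expect_length(iqr_outlier_samples(s, components = 1, fold = Inf), 0L)
  expect_error(iqr_outlier_samples(s, fold = -1), "positive")
})

test_that("intra-assay CV matches hand computations", {
  # calibrators (90, 110): sd = 14.1421 (n-1), mean = 100 -> 0.1414
  v <- rbind(c(90, 110), c(100, 100))
  m <- make_matrix(v, "LINEAR_RFU", samples = c("c1", "c2"))
  pm <- plate_map(c("c1", "c2"), "P1", "CALIBRATOR")
  cv <- intra_assay_cv(m, pm)
  expect_equal(cv$cv_intra[1], sqrt(200) / 100, tolerance = 1e-9)
  expect_equal(cv$cv_intra[1], 0.1414, tolerance = 1e-3)
  expect_equal(cv$cv_intra[2], 0)  # zero variance
})

test_that("NPX CVs use the base-2 log-normal identity", {
  # sigma_NPX = 1 -> sqrt(exp((ln 2)^2) - 1) = 0.7854
  x <- c(0, 2)  # sd = sqrt(2); rescale to sd exactly 1
  x <- (x - mean(x)) / sd(x) + 3
  m <- make_matrix(rbind(x), "NPX_LOG2", "OLINK",
                   samples = c("c1", "c2"))
  pm <- plate_map(c("c1", "c2"), "P1", "CALIBRATOR")
  cv <- intra_assay_cv(m, pm)
  expect_equal(cv$cv_intra[1], sqrt(exp(log(2)^2) - 1), tolerance = 1e-9)
  expect_equal(cv$cv_intra[1], 0.7854, tolerance = 1e-4)
})

test_that("inter-assay CV pools calibrators across plates", {
  with_seed(9, {
    x <- rnorm(32)
    x <- (x - mean(x)) / sd(x) * 5 + 100  # mean 100, SD exactly 5
    m <- make_matrix(rbind(x), "LINEAR_RFU",
                     samples = sprintf("c%d", 1:32))
    pm <- plate_map(sprintf("c%d", 1:32),
                    rep(sprintf("P%d", 1:16), each = 2), "CALIBRATOR")
    cv <- inter_assay_cv(m, pm)
    expect_equal(cv$cv_inter[1], 0.05, tolerance = 1e-12)
    # identical calibrator values -> 0
    m0 <- make_matrix(rbind(rep(7, 32)), "LINEAR_RFU",
                      samples = sprintf("c%d", 1:32))
    expect_equal(inter_assay_cv(m0, pm)$cv_inter[1], 0)
    expect_error(inter_assay_cv(
      make_matrix(rbind(1), "LINEAR_RFU", samples = "c1"),
      pm), "at least 2")
  })
})

test_that("plate shifts force inter above intra CV", {
  cfg <- sim_config(n_samples = 20, n_proteins = 30,
                    n_soma_reagents = 30, n_olink_reagents = 10,
                    plate_count = 8, sigma_intra = 0, tau_inter = 0.3)
  st <- simulate_study(cfg)
  ci <- intra_assay_cv(st$assays$soma_a, st$assays$plate_map)
  cx <- inter_assay_cv(st$assays$soma_a, st$assays$plate_map)
  expect_true(all(ci$cv_intra < 1e-9))
  expect_true(all(cx$cv_inter > ci$cv_intra))
})

test_that("CV formulas carry their scale invariances", {
  with_seed(6, {
    cal <- sprintf("c%d", 1:10)
    pm <- plate_map(cal, rep(c("P1", "P2"), each = 5), "CALIBRATOR")
    lin <- matrix(2^rnorm(50, 8), nrow = 5)
    m1 <- make_matrix(lin, "LINEAR_RFU", samples = cal)
    m2 <- make_matrix(lin * 37.5, "LINEAR_RFU", samples = cal)
    expect_equal(intra_assay_cv(m1, pm)$cv_intra,
                 intra_assay_cv(m2, pm)$cv_intra, tolerance = 1e-12)
    expect_equal(inter_assay_cv(m1, pm)$cv_inter,
                 inter_assay_cv(m2, pm)$cv_inter, tolerance = 1e-12)
    npx <- matrix(rnorm(50), nrow = 5)
    n1 <- make_matrix(npx, "NPX_LOG2", "OLINK", samples = cal)
    n2 <- make_matrix(npx + 4.2, "NPX_LOG2", "OLINK", samples = cal)
    expect_equal(intra_assay_cv(n1, pm)$cv_intra,
                 intra_assay_cv(n2, pm)$cv_intra, tolerance = 1e-12)
    expect_equal(inter_assay_cv(n1, pm)$cv_inter,
                 inter_assay_cv(n2, pm)$cv_inter, tolerance = 1e-12)
    # monotone in sigma_NPX, tending to 0
    sds <- c(0.01, 0.1, 0.5, 1, 2)
    cvs <- sqrt(exp((log(2) * sds)^2) - 1)
    expect_true(all(diff(cvs) > 0))
    expect_lt(cvs[1], 0.01)
  })
})

test_that("cv_summary reports percentiles and compares platforms", {
  const <- rep(0.07, 12)
  s <- cv_summary(const)
  expect_true(all(s$percentiles == 0.07))
  expect_equal(s$frac_below_0.20, 1)
  even <- seq(0.01, 0.99, by = 0.01)
  expect_equal(unname(cv_summary(even)$percentiles[3]), 0.50)
  with_seed(14, {
    a <- rexp(200, 20)
    b <- rexp(200, 20) + 0.05
    cmp <- cv_summary(a, b)$comparison
    expect_lt(cmp$p_value, 0.01)  # clearly shifted distributions
    same <- cv_summary(a, a)$comparison
    expect_gt(same$p_value, 0.9)
  })
  expect_error(cv_summary(numeric()), "empty")
})
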