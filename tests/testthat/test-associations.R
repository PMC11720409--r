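test_that("Bonferroni threshold is plain division", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("linear fits agree with stats::lm as an independent check", {
  with_seed(23, {
    n <- 120
    cov_df <- data.frame(age = rnorm(n, 70, 8),
                         sex = sample(c("F", "M"), n, TRUE))
    pheno <- rnorm(n, 50, 10)
    prot <- 0.03 * pheno + 0.01 * cov_df$age + rnorm(n)
    fa <- fit_association(prot, pheno, cov_df, "LINEAR")
    ref <- summary(lm(prot ~ pheno + age + sex, data = cov_df))
    expect_equal(fa$beta, ref$coefficients["pheno", 1], tolerance = 1e-10)
    expect_equal(fa$se, ref$coefficients["pheno", 2], tolerance = 1e-10)
    expect_equal(fa$p, ref$coefficients["pheno", 4], tolerance = 1e-10)
  })
})

test_that("covariate-free standardized fit returns the Pearson r", {
  with_seed(24, {
    x <- scale(rnorm(200))[, 1]
    y <- scale(0.4 * x + rnorm(200))[, 1]
    # rescale to exact unit SD so beta == r in closed form
    x <- x / sd(x); y <- y / sd(y)
    fa <- fit_association(y, x, NULL, "LINEAR")
    expect_equal(fa$beta, cor(x, y), tolerance = 1e-10)
  })
})

test_that("logistic orientation matches stats::glm and flags separation", {
  with_seed(25, {
    n <- 150
    prot <- rnorm(n)
    sex <- rbinom(n, 1, plogis(0.8 * prot))
    cov_df <- data.frame(age = rnorm(n, 70, 8))
    fa <- fit_association(prot, sex, cov_df, "LOGISTIC")
    ref <- summary(glm(sex ~ prot + age, data = cov_df,
                       family = binomial))
    expect_equal(fa$beta, ref$coefficients["prot", 1], tolerance = 1e-6)
    expect_equal(fa$p, ref$coefficients["prot", 4], tolerance = 1e-6)
    # perfect separation: flagged, p missing
    sep <- as.integer(prot > 0)
    fs <- fit_association(prot, sep, NULL, "LOGISTIC")
    expect_false(fs$converged)
    expect_true(is.na(fs$p))
  })
})

test_that("degenerate designs raise errors naming the problem", {
  with_seed(26, {
    prot <- rnorm(60)
    expect_error(fit_association(prot, rep(3, 60), NULL, "LINEAR"),
                 "collinear|rank")
    cov_df <- data.frame(a = rnorm(60))
    cov_df$b <- 2 * cov_df$a
    expect_error(fit_association(prot, rnorm(60), cov_df, "LINEAR"),
                 "collinear")
  })
})

test_that("screen recovers planted effects at the top ranks", {
  eff <- data.frame(protein = sprintf("PR%05d", 1:15),
                    phenotype = "csf_ptau", beta = 1.2)
  cfg <- sim_config(n_samples = 264, n_proteins = 150,
                    n_soma_reagents = 150, n_olink_reagents = 50,
                    f_good = 1, good_range = c(0.9, 0.95),
                    plate_count = 4, effects = eff, seed = 63L)
  st <- simulate_study(cfg)
  za <- study_only(log2_zscale(st$assays$soma_a), st$cohort)
  scr <- association_screen(za, st$cohort, "csf_ptau")
  planted <- st$reagents$truth$reagent_id[
    st$reagents$truth$protein %in% eff$protein &
      st$reagents$truth$platform == "SOMA"]
  expect_setequal(scr$reagent_id[scr$rank <= 15], planted)
  expect_true(all(scr$significant[scr$rank <= 15]))
  # deterministic under refit
  scr2 <- association_screen(za, st$cohort, "csf_ptau")
  expect_identical(scr$reagent_id, scr2$reagent_id)
})

test_that("self-adjustment and technique covariates follow the policy", {
  ph <- data.frame(sample_id = "x", age = 1, sex = "F",
                   csf_total_protein = 1, technique = "ELISA",
                   csf_ab42 = 1)
  expect_setequal(screen_covariates("age", ph),
                  c("sex", "csf_total_protein"))
  expect_setequal(screen_covariates("csf_ab42", ph),
                  c("sex", "age", "csf_total_protein", "technique"))
  expect_setequal(screen_covariates("mmse", ph),
                  c("sex", "age", "csf_total_protein"))
})

test_that("the familywise flag is conservative under the global null", {
  # 200 null reagents; expected count of Bonferroni-significant
  # phenotype coefficients is alpha = 0.05 per screen
  cfg <- sim_config(n_samples = 150, n_proteins = 200,
                    n_soma_reagents = 200, n_olink_reagents = 60,
                    f_good = 0.5, plate_count = 4, seed = 77L)
  st <- simulate_study(cfg)
  za <- study_only(log2_zscale(st$assays$soma_a), st$cohort)
  scr <- association_screen(za, st$cohort, c("age", "qalb"))
  expect_lte(sum(scr$significant), 1L)
})

test_that("restricting features is an exact sub-selection", {
  st <- small_study()
  za <- study_only(log2_zscale(st$assays$soma_a), st$cohort)
  full <- association_screen(za, st$cohort, "age")
  subset_ids <- reagent_ids(za)[1:40]
  vs <- expression_matrix(za$values[subset_ids, ], "ZSCORED", "SOMA_A")
  part <- association_screen(vs, st$cohort, "age")
  m <- merge(full[full$reagent_id %in% subset_ids,
                  c("reagent_id", "beta", "se", "p")],
             part[, c("reagent_id", "beta", "se", "p")],
             by = "reagent_id")
  expect_equal(m$beta.x, m$beta.y, tolerance = 1e-12)
  expect_equal(m$p.x, m$p.y, tolerance = 1e-12)
})

test_that("LASSO reports are deterministic and recover planted signal", {
  with_seed(52, {
    n <- 250; p <- 120
    X <- matrix(rnorm(n * p), nrow = n)
    beta <- c(rep(0.35, 30), rep(0, p - 30))
    lin <- X %*% beta
    # calibrate noise for R2_true = 0.8
    y <- as.vector(lin + rnorm(n, sd = sqrt(var(lin) * 0.25)))
    m <- make_matrix(t(X), "ZSCORED",
                     reagents = sprintf("f%03d", 1:p),
                     samples = sprintf("s%03d", 1:n))
    ph <- data.frame(sample_id = sprintf("s%03d", 1:n), y = y)
    rep1 <- lasso_performance(m, ph, "y", seed = 3L)
    rep2 <- lasso_performance(m, ph, "y", seed = 3L)
    expect_identical(rep1$r2, rep2$r2)
    expect_gte(rep1$r2, 0.6)
  })
})

test_that("a pure-noise binary phenotype gives chance-level AUC", {
  with_seed(53, {
    n <- 200; p <- 80
    X <- matrix(rnorm(n * p), nrow = n)
    yb <- rbinom(n, 1, 0.5)
    m <- make_matrix(t(X), "ZSCORED",
                     reagents = sprintf("f%03d", 1:p),
                     samples = sprintf("s%03d", 1:n))
    ph <- data.frame(sample_id = sprintf("s%03d", 1:n), y = yb)
    aucs <- vapply(1:3, function(s)
      lasso_performance(m, ph, "y", seed = s)$auc, numeric(1))
    expect_true(all(aucs > 0.25 & aucs < 0.75))
    expect_error(lasso_performance(
      m, transform(ph, y = 1), "y", seed = 1L), "single class|degenerate")
  })
})
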