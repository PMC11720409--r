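#' Configuration for the synthetic two-platform study
#'
#' The generator emulates the statistical structure every downstream
#' stage assumes: a shared latent proteome read out by two aptamer runs
#' and one antibody panel, bimodal reagent fidelity (so intra- and
#' inter-platform Spearman distributions come out bimodal),
#' multi-reagent and multi-accession annotations, plate structure with
#' replicated calibrators whose between-plate variation exceeds the
#' within-plate variation, and planted linear/logistic phenotype
#' effects entering the latent proteins so both platforms inherit the
#' same biology.
#'
#' @param n_samples Cohort size (default 264).
#' @param n_proteins Number of latent proteins.
#' @param n_soma_reagents Aptamer count; the surplus over `n_proteins`
#'   is assigned as extra aptamers on randomly chosen proteins.
#' @param n_olink_reagents Antibody assay count, spread over the
#'   overlapping proteins (surplus becomes multi-panel assays).
#' @param overlap_fraction Fraction of proteins measured on both
#'   platforms.
#' @param f_good Fraction of reagents drawn from the high-fidelity
#'   class.
#' @param good_range,poor_range Fidelity (alpha) ranges of the two
#'   classes; alpha is the loading of the reagent on its latent
#'   protein, so two reagents sharing a protein correlate at
#'   `alpha1 * alpha2` (Pearson) on the latent scale.
#' @param complex_fraction Fraction of proteins annotated as
#'   two-accession complexes (consistently on both platforms).
#' @param plate_count,calibrators_per_plate Plate structure; each plate
#'   carries `calibrators_per_plate` replicates of one fixed pooled
#'   calibrator.
#' @param sigma_intra,tau_inter Within-plate replicate noise SD and
#'   between-plate shift SD for calibrators, in log2 units.  With
#'   `tau_inter > sigma_intra` the inter-assay CV exceeds the
#'   intra-assay CV by construction.
#' @param rfu_baseline Multiplier taking log2 aptamer signal to a
#'   positive, realistically scaled RFU export.
#' @param effects Optional `data.frame(protein, phenotype, beta)` of
#'   planted effects (beta per SD of the standardized phenotype).
#' @param seed Integer seed used by [simulate_study()].
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(n_samples = 264L,
                       n_proteins = 1000L,
                       n_soma_reagents = 1100L,
                       n_olink_reagents = 450L,
                       overlap_fraction = 0.30,
                       f_good = 1 / 3,
                       good_range = c(0.75, 0.95),
                       poor_range = c(0.00, 0.25),
                       complex_fraction = 0.05,
                       plate_count = 16L,
                       calibrators_per_plate = 2L,
                       sigma_intra = 0.07,
                       tau_inter = 0.15,
                       rfu_baseline = 1000,
                       effects = NULL,
                       seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]")
  }
  if (f_good < 0 || f_good > 1) stop("f_good must lie in [0, 1]")
  counts <- c(n_samples, n_proteins, n_soma_reagents, n_olink_reagents,
              plate_count, calibrators_per_plate)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (calibrators_per_plate < 2L) {
    stop("calibrators_per_plate must be at least 2 for CV computation")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_proteins = as.integer(n_proteins),
                 n_soma_reagents = as.integer(n_soma_reagents),
                 n_olink_reagents = as.integer(n_olink_reagents),
                 overlap_fraction = overlap_fraction,
                 f_good = f_good,
                 good_range = good_range,
                 poor_range = poor_range,
                 complex_fraction = complex_fraction,
                 plate_count = as.integer(plate_count),
                 calibrators_per_plate = as.integer(calibrators_per_plate),
                 sigma_intra = sigma_intra,
                 tau_inter = tau_inter,
                 rfu_baseline = rfu_baseline,
                 effects = effects,
                 seed = seed),
            class = "sim_config")
}

# Truncated-normal draw by rejection; truncation far in the tail never
# occurs for the clinical defaults used here.
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic memory-clinic cohort
#'
#' Samples a phenotype table whose marginal summaries match a
#' real-world CSF cohort of healthy controls and MCI patients: mostly
#' MCI (230/264), 55.7% female, overall mean age about 71 years, core
#' CSF biomarkers drawn per (diagnosis, technique) cell, MMSE drawn per
#' diagnosis and clipped to [0, 30], plus CSF biochemistry (albumin,
#' globulins, total protein, red-cell count, Qalb), APOE-e4 carrier
#' status and storage duration.
#'
#' @param n_samples Number of individuals (>= 2).
#' @param seed Optional seed (RNG state restored afterwards).
#' @return A phenotype `data.frame`, one row per sample.
#' @export
generate_cohort <- function(n_samples = 264L, seed = NULL) {
  if (n_samples < 2L) stop("n_samples must be at least 2")
  with_seed(seed, {
    n <- as.integer(n_samples)
    diagnosis <- ifelse(stats::runif(n) < 230 / 264, "MCI", "HC")
    sex <- ifelse(stats::runif(n) < 0.557, "F", "M")
    technique <- ifelse(stats::runif(n) < 190 / 264, "ELISA", "CLEIA")
    age <- numeric(n)
    hc <- diagnosis == "HC"
    age[hc] <- rnorm_trunc(sum(hc), 64.9, 5.54, lower = 40)
    age[!hc] <- rnorm_trunc(sum(!hc), 71.9, 8.25, lower = 40)
    mmse <- numeric(n)
    mmse[hc] <- stats::rnorm(sum(hc), 29.6, 0.565)
    mmse[!hc] <- stats::rnorm(sum(!hc), 25.5, 3.44)
    mmse <- as.integer(pmin(30, pmax(0, round(mmse))))
    ab_mu <- ifelse(technique == "ELISA", ifelse(hc, 1080, 760),
                    ifelse(hc, 1210, 977))
    ab_sd <- ifelse(technique == "ELISA", ifelse(hc, 202, 323),
                    ifelse(hc, 121, 393))
    pt_mu <- ifelse(technique == "ELISA", ifelse(hc, 43.3, 70.2),
                    ifelse(hc, 33.7, 54.2))
    pt_sd <- ifelse(technique == "ELISA", ifelse(hc, 9.97, 36.6),
                    ifelse(hc, 4.73, 31.8))
    csf_ab42 <- rnorm_trunc(n, ab_mu, ab_sd, lower = 1)
    csf_ptau <- rnorm_trunc(n, pt_mu, pt_sd, lower = 1)
    # Red-cell counts are heavily right-skewed; log-normal with moments
    # matched to mean 53.9, SD 135.
    rbc_s2 <- log(1 + (135 / 53.9)^2)
    csf_rbc <- stats::rlnorm(n, log(53.9) - rbc_s2 / 2, sqrt(rbc_s2))
    df <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, diagnosis = diagnosis, mmse = mmse,
      technique = technique,
      csf_ab42 = csf_ab42, csf_ptau = csf_ptau,
      csf_albumin = rnorm_trunc(n, 0.239, 0.0902, lower = 0.01),
      csf_globulins = rnorm_trunc(n, 0.191, 0.0616, lower = 0.01),
      csf_total_protein = rnorm_trunc(n, 0.453, 0.145, lower = 0.05),
      csf_rbc = csf_rbc,
      qalb = rnorm_trunc(n, 862, 100, lower = 100),
      apoe_e4 = as.integer(stats::runif(n) < 0.295),
      storage_years = rnorm_trunc(n, 4.30, 0.768, lower = 0.5),
      stringsAsFactors = FALSE)
    validate_phenotypes(df)
  })
}

#' Generate reagent panels and their ground truth
#'
#' Builds annotation tables for the aptamer panel (shared by both
#' aptamer runs) and the antibody panel, plus a truth table recording
#' each reagent's target protein, fidelity alpha and planted class.
#' Aptamer fidelity is a property of the physical reagent and is
#' therefore shared between the two aptamer runs; antibody fidelity is
#' drawn independently, so a reagent that replicates across aptamer
#' runs need not replicate cross-platform.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List with `soma` and `olink` annotation tables, and `truth`
#'   (`data.frame(reagent_id, platform, protein, alpha, class)`).
#' @export
generate_reagents <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    np <- config$n_proteins
    proteins <- sprintf("PR%05d", seq_len(np))
    acc <- sprintf("P%05d", seq_len(np))
    n_complex <- round(config$complex_fraction * np)
    complex <- sample.int(np, n_complex)
    acc[complex] <- paste(acc[complex], sprintf("Q%05d", complex), sep = "|")
    genes <- sprintf("GENE%d", seq_len(np))

    draw_alpha <- function(n) {
      good <- stats::runif(n) < config$f_good
      a <- numeric(n)
      a[good] <- stats::runif(sum(good), config$good_range[1],
                              config$good_range[2])
      a[!good] <- stats::runif(sum(!good), config$poor_range[1],
                               config$poor_range[2])
      list(alpha = a, class = ifelse(good, "GOOD-planted", "POOR-planted"))
    }

    ns <- config$n_soma_reagents
    soma_target <- if (ns >= np) {
      c(seq_len(np), sample.int(np, ns - np, replace = TRUE))
    } else {
      sample.int(np, ns)
    }
    soma_ids <- sprintf("seq.%04d.%d", soma_target,
                        stats::ave(soma_target, soma_target,
                                   FUN = seq_along))
    soma_fid <- draw_alpha(ns)
    soma <- reagent_annotation(soma_ids, "SOMA_A", acc[soma_target],
                               gene_symbol = genes[soma_target])

    n_overlap <- round(config$overlap_fraction * np)
    olink_proteins <- sort(sample.int(np, n_overlap))
    no <- config$n_olink_reagents
    olink_target <- if (no >= n_overlap) {
      c(olink_proteins,
        sample(olink_proteins, no - n_overlap, replace = TRUE))
    } else {
      sample(olink_proteins, no)
    }
    olink_ids <- sprintf("OID%05d.%d", olink_target,
                         stats::ave(olink_target, olink_target,
                                    FUN = seq_along))
    olink_fid <- draw_alpha(length(olink_target))
    panels <- paste0("Panel_", ((seq_along(olink_target) - 1L) %% 4L) + 1L)
    olink <- reagent_annotation(olink_ids, "OLINK", acc[olink_target],
                                gene_symbol = genes[olink_target],
                                panel = panels)

    truth <- rbind(
      data.frame(reagent_id = soma_ids, platform = "SOMA",
                 protein = proteins[soma_target],
                 alpha = soma_fid$alpha, class = soma_fid$class,
                 stringsAsFactors = FALSE),
      data.frame(reagent_id = olink_ids, platform = "OLINK",
                 protein = proteins[olink_target],
                 alpha = olink_fid$alpha, class = olink_fid$class,
                 stringsAsFactors = FALSE))
    list(soma = soma, olink = olink, truth = truth,
         proteins = data.frame(protein = proteins, uniprot_ids = acc,
                               stringsAsFactors = FALSE))
  })
}

#' Generate the three assay matrices and the plate map
#'
#' Latent protein levels are standardized combinations of the planted
#' phenotype effects plus biological noise; each reagent reads its
#' protein with log2 signal `y = alpha * L + sqrt(1 - alpha^2) * e`
#' plus a reagent baseline and a per-(reagent, plate) shift.
#' Calibrator wells share one fixed latent vector across all plates and
#' receive the plate shift (SD `tau_inter`) plus replicate noise (SD
#' `sigma_intra`), so their within-plate spread reflects only technical
#' noise.  Aptamer runs are exported on the linear RFU scale
#' (`rfu_baseline * 2^y`), the antibody run as NPX (log2).
#'
#' @param cohort Phenotype table from [generate_cohort()].
#' @param reagents Panel list from [generate_reagents()].
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List with `soma_a`, `soma_b`, `olink` expression matrices
#'   (study plus calibrator columns), `plate_map`, and the latent
#'   matrices used.
#' @export
generate_assays <- function(cohort, reagents, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- nrow(cohort)
    if (n != config$n_samples) {
      stop("cohort size does not match config$n_samples")
    }
    np <- config$n_proteins
    proteins <- reagents$proteins$protein

    # Latent protein levels for study samples, unit variance by
    # construction: (sum beta * z(pheno) + eps) / sqrt(1 + sum beta^2).
    latent <- matrix(stats::rnorm(np * n), nrow = np,
                     dimnames = list(proteins, cohort$sample_id))
    eff <- config$effects
    if (!is.null(eff) && nrow(eff)) {
      for (p in unique(eff$protein)) {
        rows <- eff[eff$protein == p, , drop = FALSE]
        idx <- match(p, proteins)
        if (is.na(idx)) stop("effect planted on unknown protein: ", p)
        contrib <- 0
        for (j in seq_len(nrow(rows))) {
          x <- cohort[[rows$phenotype[j]]]
          if (is.null(x)) stop("unknown phenotype in effects: ",
                               rows$phenotype[j])
          if (!is.numeric(x)) x <- as.numeric(factor(x))
          z <- (x - mean(x)) / stats::sd(x)
          contrib <- contrib + rows$beta[j] * z
        }
        latent[idx, ] <- (contrib + latent[idx, ]) /
          sqrt(1 + sum(rows$beta^2))
      }
    }
    latent_cal <- stats::rnorm(np)
    names(latent_cal) <- proteins

    plates <- sprintf("PL%02d", seq_len(config$plate_count))
    study_plate <- rep_len(plates, n)
    cal_ids <- as.vector(t(outer(plates, seq_len(config$calibrators_per_plate),
                                 function(p, j) sprintf("CAL_%s_%d", p, j))))
    cal_plate <- rep(plates, each = config$calibrators_per_plate)
    pm <- plate_map(c(cohort$sample_id, cal_ids),
                    c(study_plate, cal_plate),
                    c(rep("STUDY", n), rep("CALIBRATOR", length(cal_ids))))

    truth <- reagents$truth
    soma_truth <- truth[truth$platform == "SOMA", , drop = FALSE]
    olink_truth <- truth[truth$platform == "OLINK", , drop = FALSE]
    soma_baseline <- stats::rnorm(nrow(soma_truth), 0, 1)
    olink_baseline <- stats::rnorm(nrow(olink_truth), 0, 1)

    run_matrix <- function(tr, baseline) {
      nr <- nrow(tr)
      pidx <- match(tr$protein, proteins)
      alpha <- tr$alpha
      shift <- matrix(stats::rnorm(nr * config$plate_count, 0,
                                   config$tau_inter),
                      nrow = nr, dimnames = list(NULL, plates))
      y_study <- baseline +
        alpha * latent[pidx, , drop = FALSE] +
        sqrt(1 - alpha^2) * matrix(stats::rnorm(nr * n), nrow = nr) +
        shift[, study_plate, drop = FALSE]
      y_cal <- baseline + alpha * latent_cal[pidx] +
        shift[, cal_plate, drop = FALSE] +
        matrix(stats::rnorm(nr * length(cal_ids), 0, config$sigma_intra),
               nrow = nr)
      y <- cbind(y_study, y_cal)
      dimnames(y) <- list(tr$reagent_id, c(cohort$sample_id, cal_ids))
      y
    }

    ya <- run_matrix(soma_truth, soma_baseline)
    yb <- run_matrix(soma_truth, soma_baseline)
    yo <- run_matrix(olink_truth, olink_baseline)

    list(soma_a = expression_matrix(config$rfu_baseline * 2^ya,
                                    "LINEAR_RFU", "SOMA_A"),
         soma_b = expression_matrix(config$rfu_baseline * 2^yb,
                                    "LINEAR_RFU", "SOMA_B"),
         olink = expression_matrix(yo, "NPX_LOG2", "OLINK"),
         plate_map = pm,
         latent = latent, latent_cal = latent_cal)
  })
}

#' Run the full synthetic study
#'
#' Convenience wrapper: seeds the RNG from `config$seed` and chains
#' [generate_cohort()], [generate_reagents()] and [generate_assays()].
#'
#' @param config A [sim_config()].
#' @return List with `cohort`, `reagents` (annotations + truth),
#'   `assays` (three matrices + plate map).
#' @export
simulate_study <- function(config = sim_config()) {
  with_seed(config$seed, {
    cohort <- generate_cohort(config$n_samples)
    reagents <- generate_reagents(config)
    assays <- generate_assays(cohort, reagents, config)
    list(cohort = cohort, reagents = reagents, assays = assays,
         config = config)
  })
}

#' Expected correlation between two reagents sharing a protein
#'
#' Closed-form oracle for the generator's attenuation model: with unit
#' variances, the Pearson correlation of two reagents with fidelities
#' `alpha1`, `alpha2` reading the same latent protein is
#' `alpha1 * alpha2`, and the population Spearman correlation of a
#' bivariate normal with Pearson correlation r is
#' `(6 / pi) * asin(r / 2)`.
#'
#' @param alpha1,alpha2 Fidelities in [0, 1].
#' @return Named numeric vector `c(pearson, spearman)`.
#' @export
expected_pair_correlation <- function(alpha1, alpha2) {
  if (alpha1 < 0 || alpha1 > 1 || alpha2 < 0 || alpha2 > 1) {
    stop("fidelities must lie in [0, 1]")
  }
  r <- alpha1 * alpha2
  c(pearson = r, spearman = (6 / pi) * asin(r / 2))
}
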