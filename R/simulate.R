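#' Configure a synthetic longitudinal allergy cohort
#'
#' Builds the configuration object consumed by all `simulate_*()` generators.
#' Defaults reproduce the marginal structure of a mid-size German birth-cohort
#' subsample with methylation measured at two time points: maternal smoking in
#' pregnancy around 7.5%, a positive family history of allergies around 64.5%,
#' 57.7% boys, aeroallergen sensitization rising from 31.6% at baseline to
#' 44.9% at follow-up. Mediation paths are planted explicitly in either causal
#' direction and everything else is null.
#'
#' Two kinds of paths can be planted. `planted_h1` rows describe
#' exposure -> methylation -> sensitization paths: `a` is the exposure effect
#' on the CpG's M-value, `b` the M-value effect on follow-up sensitization
#' log-odds. `planted_h2` rows describe exposure -> sensitization ->
#' methylation paths: `c` is the exposure effect on baseline-sensitization
#' log-odds and `d` the shift in the follow-up M-value for sensitized
#' children.
#'
#' @param n_samples,n_cpgs,n_snps cohort, methylation-array and genotype sizes.
#' @param exposure_prevalence named probabilities for the binary exposures.
#' @param male_fraction probability of male sex.
#' @param baseline_rate,followup_rate target marginal sensitization
#'   prevalences at the two time points.
#' @param persistence_logodds log-odds carried from baseline to follow-up
#'   sensitization, so that prevalence rises over time.
#' @param planted_h1 tibble from [plant_h1()] (may have zero rows).
#' @param planted_h2 tibble from [plant_h2()].
#' @param direct_logodds named exposure effects on follow-up sensitization
#'   that bypass any mediator.
#' @param confounder_effects named list mapping a covariate name to a numeric
#'   vector with any of the elements `exposure`, `mediator`, `outcome`, the
#'   per-SD effect of that covariate on each stage. Empty by default: the
#'   joint covariate distribution is independent unless configured.
#' @param noise_sd residual SD of CpG M-values.
#' @param cpg_mean_sd SD of per-CpG mean M-values (centred at 0, i.e. beta
#'   values centred at 0.5).
#' @param cell_alpha Dirichlet concentration for the six blood-cell
#'   proportions.
#' @param rare_fraction,lowqual_fraction,multiallelic_fraction fractions of
#'   simulated SNPs flagged rare (MAF < 1%), poorly imputed (quality < 0.4)
#'   or multiallelic, to exercise the PRS filters.
#' @param seed one integer seed; every generator expands it into its own
#'   named substream, so e.g. changing `n_cpgs` never perturbs the phenotype
#'   draws.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 200, n_cpgs = 50,
#'                   planted_h1 = plant_h1(1, a = 0.5, b = 0.5))
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_samples = 234,
                       n_cpgs = 1000,
                       n_snps = 500,
                       exposure_prevalence = c(maternal_smoking = 0.075,
                                               family_history = 0.645),
                       male_fraction = 0.577,
                       baseline_rate = 0.316,
                       followup_rate = 0.449,
                       persistence_logodds = 2,
                       planted_h1 = plant_h1(),
                       planted_h2 = plant_h2(),
                       direct_logodds = c(maternal_smoking = 0,
                                          family_history = 0, prs = 0),
                       confounder_effects = list(),
                       noise_sd = 0.5,
                       cpg_mean_sd = 1,
                       cell_alpha = 40 * c(CD4T = 0.20, CD8T = 0.12,
                                           NK = 0.05, Bcell = 0.10,
                                           Mono = 0.08, Neu = 0.45),
                       rare_fraction = 0.05,
                       lowqual_fraction = 0.10,
                       multiallelic_fraction = 0.05,
                       seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples")
  n_cpgs <- assert_count(n_cpgs, "n_cpgs")
  n_snps <- assert_count(n_snps, "n_snps")
  assert_probability(exposure_prevalence, "exposure_prevalence")
  assert_probability(male_fraction, "male_fraction")
  assert_probability(baseline_rate, "baseline_rate")
  assert_probability(followup_rate, "followup_rate")
  assert_probability(rare_fraction, "rare_fraction")
  assert_probability(lowqual_fraction, "lowqual_fraction")
  assert_probability(multiallelic_fraction, "multiallelic_fraction")
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort("`noise_sd` must be positive.", class = "epimediate_config_error")
  }
  planted_h1 <- validate_planted(planted_h1, c("cpg_index", "a", "b"))
  planted_h2 <- validate_planted(planted_h2, c("cpg_index", "c", "d"))
  all_idx <- c(planted_h1$cpg_index, planted_h2$cpg_index)
  if (anyDuplicated(all_idx)) {
    abort("planted CpG indices must be unique across H1 and H2.",
          class = "epimediate_config_error")
  }
  if (length(all_idx) && max(all_idx) > n_cpgs) {
    abort("planted CpG index exceeds `n_cpgs`.",
          class = "epimediate_config_error")
  }
  structure(
    list(n_samples = n_samples, n_cpgs = n_cpgs, n_snps = n_snps,
         exposure_prevalence = exposure_prevalence,
         male_fraction = male_fraction, baseline_rate = baseline_rate,
         followup_rate = followup_rate,
         persistence_logodds = persistence_logodds,
         planted_h1 = planted_h1, planted_h2 = planted_h2,
         direct_logodds = direct_logodds,
         confounder_effects = confounder_effects, noise_sd = noise_sd,
         cpg_mean_sd = cpg_mean_sd, cell_alpha = cell_alpha,
         rare_fraction = rare_fraction,
         lowqual_fraction = lowqual_fraction,
         multiallelic_fraction = multiallelic_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

validate_planted <- function(x, cols) {
  x <- tibble::as_tibble(x)
  if (!all(cols %in% names(x))) {
    abort(sprintf("planted table needs columns %s",
                  paste(cols, collapse = ", ")),
          class = "epimediate_config_error")
  }
  if (!"exposure" %in% names(x)) x$exposure <- rep("maternal_smoking",
                                                   nrow(x))
  if (nrow(x) && anyDuplicated(x$cpg_index)) {
    abort("planted CpG indices must be unique.",
          class = "epimediate_config_error")
  }
  if (nrow(x) && any(x$cpg_index < 1)) {
    abort("planted CpG indices must be >= 1.",
          class = "epimediate_config_error")
  }
  x
}

#' Declare planted mediation paths
#'
#' `plant_h1()` plants exposure -> CpG -> sensitization paths (methylation as
#' the mediator); `plant_h2()` plants exposure -> sensitization -> CpG paths
#' (methylation as the downstream outcome).
#'
#' @param cpg_index index of the carrier CpG (1-based, within `n_cpgs`).
#' @param a exposure effect on the baseline M-value (H1).
#' @param b M-value effect on follow-up sensitization log-odds (H1).
#' @param c exposure effect on baseline sensitization log-odds (H2).
#' @param d M-value shift at follow-up for sensitized children (H2).
#' @param exposure which exposure carries the path.
#' @return a tibble suitable for [sim_config()].
#' @export
plant_h1 <- function(cpg_index = integer(), a = numeric(), b = numeric(),
                     exposure = "maternal_smoking") {
  tibble::tibble(cpg_index = as.integer(cpg_index), a = a, b = b,
                 exposure = rep_len(exposure, length(cpg_index)))
}

#' @rdname plant_h1
#' @export
plant_h2 <- function(cpg_index = integer(), c = numeric(), d = numeric(),
                     exposure = "maternal_smoking") {
  tibble::tibble(cpg_index = as.integer(cpg_index), c = c, d = d,
                 exposure = rep_len(exposure, length(cpg_index)))
}

cpg_ids <- function(config) sprintf("cg%06d", seq_len(config$n_cpgs))

# standardized covariate columns used when applying confounder effects
confounder_design <- function(cohort, config) {
  nm <- names(config$confounder_effects)
  if (length(nm) == 0L) return(NULL)
  cols <- lapply(nm, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) abort(sprintf("unknown confounder `%s`", v),
                          class = "epimediate_config_error")
    s <- sd(x)
    if (s == 0) return(x - mean(x))
    (x - mean(x)) / s
  })
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

conf_effect <- function(config, stage) {
  vapply(config$confounder_effects, function(e) {
    if (stage %in% names(e)) e[[stage]] else 0
  }, numeric(1))
}

# Per-CpG mean M-values plus the residual draws for planted H1 CpGs, all from
# the "planted" substream so that simulate_cohort() (which needs the planted
# mediator values to generate the outcome) and simulate_methylation()
# reproduce the same values independently.
planted_components <- function(config) {
  with_seed(substream_seed(config$seed, "planted"), {
    mu <- rnorm(config$n_cpgs, 0, config$cpg_mean_sd)
    h1 <- config$planted_h1
    noise <- if (nrow(h1)) {
      matrix(rnorm(config$n_samples * nrow(h1), 0, config$noise_sd),
             nrow = config$n_samples)
    } else {
      matrix(numeric(0), nrow = config$n_samples, ncol = 0)
    }
    list(mu = mu, h1_noise = noise)
  })
}

# planted H1 mediator M-values for a generated cohort (samples x paths)
h1_mediator_values <- function(cohort, config, components = NULL) {
  h1 <- config$planted_h1
  if (nrow(h1) == 0L) {
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  }
  comp <- components %||% planted_components(config)
  cd <- confounder_design(cohort, config)
  med_eff <- conf_effect(config, "mediator")
  conf_term <- if (is.null(cd)) 0 else as.numeric(cd %*% med_eff)
  vals <- vapply(seq_len(nrow(h1)), function(i) {
    x <- cohort[[h1$exposure[i]]]
    comp$mu[h1$cpg_index[i]] + h1$a[i] * x + conf_term + comp$h1_noise[, i]
  }, numeric(nrow(cohort)))
  matrix(vals, nrow = nrow(cohort))
}

#' Simulate the phenotype table of a longitudinal cohort
#'
#' Draws covariates (sex, ages at both time points, season of blood draw,
#' BMI, parental education as SES, NO2 at the birth address and a 6-part
#' blood-cell composition on the simplex), exposures (maternal smoking,
#' family history, a continuous polygenic score) and sensitization at
#' baseline and follow-up. Planted H1 paths feed the follow-up outcome
#' through the mediator CpG values; planted H2 paths feed baseline
#' sensitization directly.
#'
#' @param config a [sim_config()].
#' @return a tibble with one row per child.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  with_seed(substream_seed(config$seed, "cohort"), {
    cohort <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      sex = rbinom(n, 1, config$male_fraction),
      age_baseline = rnorm(n, 6.1, 0.2),
      age_followup = NA_real_,
      season = rbinom(n, 1, 0.675),
      bmi = rnorm(n, 15.3, 1.3),
      ses = rbinom(n, 1, 0.802),
      no2 = rnorm(n, 21.4, 6.1)
    )
    cohort$age_followup <- cohort$age_baseline +
      pmax(0.5, 4.1 + rnorm(n, 0, 0.15))
    cells <- vapply(config$cell_alpha,
                    function(a) rgamma(n, shape = a, rate = 1),
                    numeric(n))
    cells <- cells / rowSums(cells)
    colnames(cells) <- paste0("cell_", names(config$cell_alpha))
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(cells))

    cd <- confounder_design(cohort, config)
    exp_eff <- conf_effect(config, "exposure")
    exp_term <- if (is.null(cd)) 0 else as.numeric(cd %*% exp_eff)
    prev <- config$exposure_prevalence
    cohort$maternal_smoking <-
      rbinom(n, 1, plogis(qlogis(prev[["maternal_smoking"]]) + exp_term))
    cohort$family_history <-
      rbinom(n, 1, plogis(qlogis(prev[["family_history"]]) + exp_term))
    cohort$prs <- rnorm(n, 0.2, 1) + exp_term

    out_eff <- conf_effect(config, "outcome")
    out_term <- if (is.null(cd)) 0 else as.numeric(cd %*% out_eff)

    # baseline sensitization: base rate + planted H2 exposure paths
    logit_b <- rep(qlogis(config$baseline_rate), n) + out_term
    h2 <- config$planted_h2
    for (i in seq_len(nrow(h2))) {
      x <- cohort[[h2$exposure[i]]]
      logit_b <- logit_b + h2$c[i] * (x - mean(x))
    }
    cohort$sensitized_baseline <- rbinom(n, 1, plogis(logit_b))

    # follow-up sensitization: persistence + planted H1 mediator paths +
    # any direct exposure effects
    M <- h1_mediator_values(cohort, config)
    logit_f <- rep(qlogis(config$followup_rate), n) + out_term +
      config$persistence_logodds *
        (cohort$sensitized_baseline - mean(cohort$sensitized_baseline))
    h1 <- config$planted_h1
    for (i in seq_len(nrow(h1))) {
      logit_f <- logit_f + h1$b[i] * (M[, i] - mean(M[, i]))
    }
    for (e in names(config$direct_logodds)) {
      de <- config$direct_logodds[[e]]
      if (de != 0) {
        x <- cohort[[e]]
        logit_f <- logit_f + de * (x - mean(x))
      }
    }
    cohort$sensitized_followup <- rbinom(n, 1, plogis(logit_f))
    dplyr::relocate(cohort, "sample_id", "maternal_smoking",
                    "family_history", "prs", "sensitized_baseline",
                    "sensitized_followup")
  })
}

#' Simulate a methylation beta matrix for one time point
#'
#' CpGs are simulated on the M-value (logit) scale, where Gaussian residual
#' noise is natural, and converted to beta values through the inverse logit,
#' which guarantees the open-interval (0,1) codomain. At baseline the planted
#' H1 CpGs carry the exposure signal; at follow-up the planted H2 CpGs are
#' shifted in sensitized children. All other CpGs are null: independent of
#' exposures and outcomes given any configured confounders.
#'
#' @param cohort the phenotype tibble from [simulate_cohort()].
#' @param config the same [sim_config()].
#' @param timepoint `"baseline"` or `"followup"`.
#' @return a tibble with columns `cpg_id`, `chrom`, `pos` and one column per
#'   sample, values strictly in (0,1).
#' @export
simulate_methylation <- function(cohort, config,
                                 timepoint = c("baseline", "followup")) {
  stopifnot(inherits(config, "sim_config"))
  timepoint <- match.arg(timepoint)
  n <- nrow(cohort)
  if (n != config$n_samples) {
    abort("cohort does not match `config$n_samples`.",
          class = "epimediate_config_error")
  }
  comp <- planted_components(config)
  stream <- if (timepoint == "baseline") "meth_baseline" else "meth_followup"
  M <- with_seed(substream_seed(config$seed, stream), {
    matrix(rnorm(n * config$n_cpgs, 0, config$noise_sd), nrow = n)
  })
  M <- sweep(M, 2, comp$mu, `+`)
  cd <- confounder_design(cohort, config)
  if (!is.null(cd)) {
    med_eff <- conf_effect(config, "mediator")
    M <- M + matrix(as.numeric(cd %*% med_eff), nrow = n,
                    ncol = config$n_cpgs)
  }
  if (timepoint == "baseline") {
    h1 <- config$planted_h1
    if (nrow(h1)) {
      M[, h1$cpg_index] <- h1_mediator_values(cohort, config, comp)
    }
  } else {
    h2 <- config$planted_h2
    for (i in seq_len(nrow(h2))) {
      M[, h2$cpg_index[i]] <- M[, h2$cpg_index[i]] +
        h2$d[i] * cohort$sensitized_baseline
    }
  }
  beta <- plogis(M)
  beta <- pmin(pmax(beta, 1e-12), 1 - 1e-12)
  pos <- cpg_positions(config)
  out <- tibble::tibble(cpg_id = cpg_ids(config), chrom = "chr1", pos = pos)
  mat <- t(beta)
  colnames(mat) <- cohort$sample_id
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

cpg_positions <- function(config) {
  region <- config$n_cpgs * 1000L
  with_seed(substream_seed(config$seed, "positions"), {
    sort(sample.int(region, config$n_cpgs))
  })
}

#' Simulate a gene annotation track
#'
#' Genes are laid out on the same synthetic chromosome as the CpGs, with
#' random starts and lengths, and written in BED convention (0-based,
#' half-open) by [write_bed()].
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes.
#' @return a tibble with `chrom`, `start` (0-based), `end`, `gene_id`.
#' @export
simulate_gene_annotation <- function(config,
                                     n_genes = max(5L, config$n_cpgs %/% 20L)) {
  region <- config$n_cpgs * 1000L
  with_seed(substream_seed(config$seed, "genes"), {
    start <- sort(sample.int(region, n_genes))
    len <- pmax(500L, as.integer(round(runif(n_genes, 1000, 30000))))
    tibble::tibble(chrom = "chr1", start = start - 1L,
                   end = pmin(start - 1L + len, region + 50000L),
                   gene_id = sprintf("GENE%04d", seq_len(n_genes)))
  })
}

#' Ground truth of the planted mediation structure
#'
#' One row per planted CpG with its direction, path coefficients and the
#' linear-scale indirect effect (the product of the two path coefficients);
#' the indices of all unplanted (null) CpGs are attached as the
#' `null_indices` attribute.
#'
#' @param config a [sim_config()].
#' @return a tibble of class `truth_record`.
#' @export
simulate_truth <- function(config) {
  ids <- cpg_ids(config)
  h1 <- config$planted_h1
  h2 <- config$planted_h2
  truth <- dplyr::bind_rows(
    tibble::tibble(cpg_index = h1$cpg_index, cpg_id = ids[h1$cpg_index],
                   direction = rep("H1", nrow(h1)), exposure = h1$exposure,
                   true_a = h1$a, true_b = h1$b,
                   true_indirect = h1$a * h1$b),
    tibble::tibble(cpg_index = h2$cpg_index, cpg_id = ids[h2$cpg_index],
                   direction = rep("H2", nrow(h2)), exposure = h2$exposure,
                   true_a = h2$c, true_b = h2$d,
                   true_indirect = h2$c * h2$d)
  )
  attr(truth, "null_indices") <-
    setdiff(seq_len(config$n_cpgs), truth$cpg_index)
  class(truth) <- c("truth_record", class(truth))
  truth
}

#' Simulate a SNP dosage matrix with marker metadata and GWAS-like weights
#'
#' Dosages are drawn per SNP as Binomial(2, MAF) under Hardy-Weinberg
#' independence; configured fractions of SNPs are flagged rare (MAF < 1%),
#' poorly imputed (quality < 0.4) or multiallelic so the PRS filters have
#' something to remove.
#'
#' @param config a [sim_config()].
#' @return a list with `genotypes` (tibble: `snp_id`, `maf`,
#'   `imputation_quality`, `is_multiallelic`, one column per sample) and
#'   `weights` (tibble: `marker_id`, `effect`, `p`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  m <- config$n_snps
  with_seed(substream_seed(config$seed, "genotypes"), {
    maf <- runif(m, 0.05, 0.5)
    n_rare <- round(config$rare_fraction * m)
    n_lowq <- round(config$lowqual_fraction * m)
    n_multi <- round(config$multiallelic_fraction * m)
    flags <- sample.int(m)  # disjoint flag assignment
    rare_idx <- flags[seq_len(n_rare)]
    lowq_idx <- flags[n_rare + seq_len(n_lowq)]
    multi_idx <- flags[n_rare + n_lowq + seq_len(n_multi)]
    maf[rare_idx] <- runif(n_rare, 0.001, 0.0099)
    quality <- runif(m, 0.7, 1)
    quality[lowq_idx] <- runif(n_lowq, 0.05, 0.39)
    multi <- rep(FALSE, m)
    multi[multi_idx] <- TRUE
    dosage <- t(vapply(maf, function(f) rbinom(n, 2, f), numeric(n)))
    colnames(dosage) <- sprintf("S%04d", seq_len(n))
    geno <- tibble::tibble(snp_id = sprintf("rs%06d", seq_len(m)),
                           maf = maf, imputation_quality = quality,
                           is_multiallelic = multi)
    geno <- dplyr::bind_cols(geno, tibble::as_tibble(dosage))
    weights <- tibble::tibble(marker_id = geno$snp_id,
                              effect = rnorm(m, 0, 0.15),
                              p = runif(m))
    list(genotypes = geno, weights = weights)
  })
}

#' Simulate EWAS-style weight tables for methylation risk scores
#'
#' Emulates a set of published allergy EWAS summary tables: each table lists
#' marker effect sizes and p-values over a subset of the simulated CpGs. All
#' planted CpGs are included with effects aligned to their planted direction
#' (so a score built from the table responds to the planted signal), padded
#' with null CpGs carrying small noise effects.
#'
#' @param config a [sim_config()].
#' @param truth the matching [simulate_truth()] record.
#' @param n_tables number of weight tables (six mirrors the usual set of
#'   allergy phenotypes: total IgE, atopy, aeroallergen sensitization,
#'   asthma, any allergy, atopy by skin-prick test).
#' @param markers_per_table total markers per table.
#' @return a named list of weight tibbles (`marker_id`, `effect`, `p`).
#' @export
simulate_weight_tables <- function(config, truth = simulate_truth(config),
                                   n_tables = 6L, markers_per_table = 100L) {
  ids <- cpg_ids(config)
  nulls <- attr(truth, "null_indices")
  with_seed(substream_seed(config$seed, "weights"), {
    tabs <- lapply(seq_len(n_tables), function(k) {
      n_fill <- max(0L, markers_per_table - nrow(truth))
      fill <- sample(nulls, min(n_fill, length(nulls)))
      planted_eff <- runif(nrow(truth), 0.2, 0.6) * sign(truth$true_b + 1e-12)
      tibble::tibble(
        marker_id = c(truth$cpg_id, ids[fill]),
        effect = c(planted_eff, rnorm(length(fill), 0, 0.05)),
        p = c(10^runif(nrow(truth), -10, -5), 10^runif(length(fill), -4, 0))
      )
    })
    names(tabs) <- sprintf("ewas_%d", seq_len(n_tables))
    tabs
  })
}

#' Simulate a complete study: cohort, methylation, weights, genotypes
#'
#' Convenience wrapper bundling every generator with consistent substreams.
#'
#' @param config a [sim_config()].
#' @return a list of class `epimediate_study` with elements `config`,
#'   `cohort`, `truth`, `methylation_baseline`, `methylation_followup`,
#'   `weight_tables`, `annotation`, `genotypes`, `snp_weights`.
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  truth <- simulate_truth(config)
  geno <- simulate_genotypes(config)
  structure(
    list(config = config, cohort = cohort, truth = truth,
         methylation_baseline = simulate_methylation(cohort, config,
                                                     "baseline"),
         methylation_followup = simulate_methylation(cohort, config,
                                                     "followup"),
         weight_tables = simulate_weight_tables(config, truth),
         annotation = simulate_gene_annotation(config),
         genotypes = geno$genotypes, snp_weights = geno$weights),
    class = "epimediate_study"
  )
}
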