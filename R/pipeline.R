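#' Configure a bidirectional mediation run
#'
#' Collects everything the orchestration needs: which exposures to run,
#' which causal directions, the per-exposure exposure-mediator adjustment
#' sets, the shared mediator-outcome adjustment set, method switches and
#' their parameters, the FDR level and the seed. Defaults encode the
#' conventional settings: pruning at r-squared 0.7, a 20 kb gene window,
#' kernel threshold 0.8 from the usual \{0.7, 0.8, 0.9\} ladder, FDR 0.05.
#'
#' @param exposures exposures to analyse (columns of the phenotype table).
#' @param direction `"both"`, `"h1"` (methylation as mediator) or `"h2"`
#'   (sensitization as mediator).
#' @param outcome_baseline,outcome_followup sensitization columns at the
#'   two time points.
#' @param adjustment_em named list: exposure -> exposure-mediator
#'   adjustment set (minimal sufficient sets from the causal diagram).
#' @param covariates_mo mediator-outcome adjustment set; `NULL` means the
#'   full covariate list (sex, baseline age, season, BMI, SES, NO2 and all
#'   cell-proportion columns) resolved from the cohort at run time.
#' @param methods named logical vector switching `dact`, `hima`, `ghma`.
#' @param fdr false-discovery-rate level for validation.
#' @param nominate_alpha per-marker significance level used by the
#'   high-dimensional nomination step.
#' @param r2_threshold pruning ceiling for risk scores.
#' @param window CpG-to-gene assignment window in bp.
#' @param kernel_threshold explained-variance threshold for the gene-based
#'   test.
#' @param sis_multiplier screening-cap multiplier.
#' @param p_threshold_grid thresholds scanned when picking each MRS.
#' @param n_draws quasi-Bayesian draws per mediation.
#' @param prior_cpgs prior-knowledge CpG list for the composite-null path;
#'   `NULL` uses the union of all weight-table markers.
#' @param min_stratum smallest stratum size the sensitivity suite will fit.
#' @param seed one integer governing every stochastic stage via named
#'   substreams.
#' @return an object of class `run_config`.
#' @export
run_config <- function(exposures = c("maternal_smoking", "family_history",
                                     "prs"),
                       direction = c("both", "h1", "h2"),
                       outcome_baseline = "sensitized_baseline",
                       outcome_followup = "sensitized_followup",
                       adjustment_em = list(
                         maternal_smoking = "ses",
                         family_history = c("ses", "no2"),
                         prs = "sex"),
                       covariates_mo = NULL,
                       methods = c(dact = TRUE, hima = TRUE, ghma = TRUE),
                       fdr = 0.05, nominate_alpha = 0.05,
                       r2_threshold = 0.7, window = 20000,
                       kernel_threshold = 0.8, sis_multiplier = 2,
                       p_threshold_grid = c(5e-8, 1e-5, 1e-3, 0.01, 0.05,
                                            1),
                       n_draws = 1000, prior_cpgs = NULL,
                       min_stratum = 30, seed = 1L) {
  direction <- match.arg(direction)
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
    abort("`fdr` must lie in (0, 1).", class = "epimediate_config_error")
  }
  missing_adj <- setdiff(exposures, names(adjustment_em))
  if (length(missing_adj)) {
    abort(sprintf("no exposure-mediator adjustment set for: %s.",
                  paste(missing_adj, collapse = ", ")),
          class = "epimediate_config_error")
  }
  structure(
    list(exposures = exposures, direction = direction,
         outcome_baseline = outcome_baseline,
         outcome_followup = outcome_followup,
         adjustment_em = adjustment_em, covariates_mo = covariates_mo,
         methods = methods, fdr = fdr, nominate_alpha = nominate_alpha,
         r2_threshold = r2_threshold, window = window,
         kernel_threshold = kernel_threshold,
         sis_multiplier = sis_multiplier,
         p_threshold_grid = p_threshold_grid, n_draws = n_draws,
         prior_cpgs = prior_cpgs, min_stratum = min_stratum,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# full mediator-outcome covariate list resolved against the cohort
resolve_covariates_mo <- function(config, cohort) {
  if (!is.null(config$covariates_mo)) {
    missing <- setdiff(config$covariates_mo, names(cohort))
    if (length(missing)) {
      abort(sprintf("configured covariates missing from cohort: %s.",
                    paste(missing, collapse = ", ")),
            class = "epimediate_config_error")
    }
    return(config$covariates_mo)
  }
  base <- intersect(c("sex", "age_baseline", "season", "bmi", "ses",
                      "no2"), names(cohort))
  cells <- grep("^cell_", names(cohort), value = TRUE)
  # drop one cell column: proportions sum to one, keeping all would make
  # the design rank-deficient
  if (length(cells) > 1) cells <- cells[-length(cells)]
  c(base, cells)
}

default_prior_cpgs <- function(config, study) {
  config$prior_cpgs %||%
    unique(unlist(lapply(study$weight_tables, `[[`, "marker_id")))
}

#' Prior-knowledge candidate pre-selection
#'
#' Intersects a prior CpG list with the measured matrix, then keeps the
#' CpGs whose association with baseline sensitization (logistic regression
#' adjusted for cell-type proportions) survives Benjamini-Hochberg FDR
#' control. Counts are reported at each step of the filter chain.
#'
#' @param cohort phenotype tibble.
#' @param methylation methylation tibble.
#' @param prior_cpgs character vector of previously reported CpGs.
#' @param outcome baseline sensitization column name.
#' @param covariates adjustment columns (cell proportions by default,
#'   resolved from the cohort).
#' @param fdr selection level.
#' @return list with `candidates` (character) and `counts`
#'   (`n_prior`, `n_available`, `n_selected`).
#' @export
preselect_candidates <- function(cohort, methylation, prior_cpgs, outcome,
                                 covariates = NULL, fdr = 0.05) {
  if (length(prior_cpgs) == 0L) {
    abort("prior CpG list is empty.", class = "epimediate_config_error")
  }
  if (is.null(covariates)) {
    covariates <- grep("^cell_", names(cohort), value = TRUE)
    if (length(covariates) > 1) covariates <- covariates[-length(covariates)]
  }
  available <- intersect(prior_cpgs, methylation$cpg_id)
  if (length(available) == 0L) {
    abort(sprintf("none of the %d prior CpGs are measured (100%% missing).",
                  length(prior_cpgs)),
          class = "epimediate_data_error")
  }
  sub <- methylation[match(available, methylation$cpg_id), , drop = FALSE]
  cc <- complete.cases(cohort[, c(outcome, covariates), drop = FALSE])
  X0 <- design_matrix(cohort[cc, , drop = FALSE], covariates)
  M <- meth_matrix(sub)[cc, , drop = FALSE]
  keep <- apply(M, 2, sd) > 0
  sc <- logistic_scan(X0, M[, keep, drop = FALSE],
                      cohort[[outcome]][cc])
  p <- sc$p
  ok <- is.finite(p)
  q <- adjust_fdr(p[ok])
  candidates <- colnames(M[, keep, drop = FALSE])[ok][q <= fdr]
  list(candidates = candidates,
       counts = c(n_prior = length(prior_cpgs),
                  n_available = length(available),
                  n_selected = length(candidates)))
}

# seeded mediation wrapper used by the validation loops
validate_marker <- function(cohort, treatment, mediator_values, outcome,
                            covariates_em, covariates_mo, family_m,
                            family_y, n_draws, seed,
                            outcome_values = NULL) {
  df <- cohort
  df$.mediator <- mediator_values
  out_var <- outcome
  if (!is.null(outcome_values)) {
    df$.outcome <- outcome_values
    out_var <- ".outcome"
  }
  mediate(df, treatment = treatment, mediator = ".mediator",
          outcome = out_var, covariates_m = covariates_em,
          covariates_y = covariates_mo, family_m = family_m,
          family_y = family_y, n_draws = n_draws, seed = seed)
}

mediation_row <- function(res, exposure, marker) {
  tibble::tibble(
    exposure = exposure, marker = marker, acme = res$acme,
    acme_low = res$acme_ci[1], acme_high = res$acme_ci[2],
    p_acme = res$p_acme, ade = res$ade, ade_low = res$ade_ci[1],
    ade_high = res$ade_ci[2], total = res$total,
    total_low = res$total_ci[1], total_high = res$total_ci[2],
    prop_mediated = res$prop_mediated,
    prop_low = res$prop_mediated_ci[1],
    prop_high = res$prop_mediated_ci[2], n = res$n)
}

#' Run the forward (H1) analysis: methylation as mediator
#'
#' For every configured exposure this (1) evaluates each methylation risk
#' score as a mediator of the exposure effect on follow-up sensitization,
#' (2) nominates single-CpG mediators with the enabled high-dimensional
#' methods (composite-null test on the prior-knowledge candidates,
#' screen-penalize-joint-test over all CpGs, gene-based kernel test), and
#' (3) validates every nominated CpG by counterfactual mediation, pooling
#' the Benjamini-Hochberg correction over all H1 validations.
#'
#' @param study an `epimediate_study` (or equivalent list of tables).
#' @param config a [run_config()].
#' @return an `analysis_report` list.
#' @export
run_h1 <- function(study, config = run_config()) {
  cohort <- study$cohort
  meth <- study$methylation_baseline
  covars_mo <- resolve_covariates_mo(config, cohort)
  out_fu <- config$outcome_followup
  out_bl <- config$outcome_baseline
  med_seed <- substream_seed(config$seed, "mediation")

  mrs_rows <- list()
  nominations <- list()
  model_ns <- list()

  for (exposure in config$exposures) {
    covars_em <- config$adjustment_em[[exposure]]
    model_ns[[exposure]] <- sum(complete.cases(
      cohort[, unique(c(exposure, out_fu, covars_em, covars_mo)),
             drop = FALSE]))

    # --- methylation risk scores as mediators
    for (nm in names(study$weight_tables)) {
      sel <- best_mrs(meth, study$weight_tables[[nm]],
                      cohort[[out_bl]],
                      thresholds = config$p_threshold_grid,
                      prune = TRUE, r2_threshold = config$r2_threshold)
      res <- validate_marker(cohort, exposure, sel$score$z_score, out_fu,
                             covars_em, covars_mo, "continuous", "binary",
                             config$n_draws,
                             med_seed + length(mrs_rows) + 1L)
      row <- mediation_row(res, exposure, nm)
      row$threshold <- sel$threshold
      mrs_rows[[paste(exposure, nm)]] <- row
    }

    # --- single-CpG nomination
    if (isTRUE(config$methods[["dact"]])) {
      pres <- preselect_candidates(
        cohort, meth, default_prior_cpgs(config, study), out_bl,
        fdr = config$fdr)
      if (length(pres$candidates)) {
        sub <- meth[match(pres$candidates, meth$cpg_id), , drop = FALSE]
        scan <- marginal_scan(cohort, sub, exposure, outcome = out_fu,
                              covariates_em = covars_em,
                              covariates_mo = covars_mo,
                              direction = "h1")
        dres <- dact(scan, calibrate = length(pres$candidates) >= 100)
        hits <- dres$marker[dres$p_calibrated < config$nominate_alpha]
        if (length(hits)) {
          nominations[[paste(exposure, "dact")]] <-
            tibble::tibble(exposure = exposure, method = "dact",
                           marker = hits)
        }
      }
    }
    if (isTRUE(config$methods[["hima"]])) {
      hres <- hima(cohort, meth, exposure, out_fu,
                   covariates_em = covars_em, covariates_mo = covars_mo,
                   multiplier = config$sis_multiplier, fdr = config$fdr)
      if (length(hres$significant)) {
        nominations[[paste(exposure, "hima")]] <-
          tibble::tibble(exposure = exposure, method = "hima",
                         marker = hres$significant)
      }
    }
    if (isTRUE(config$methods[["ghma"]])) {
      gmap <- map_cpgs_to_genes(meth[, c("cpg_id", "chrom", "pos")],
                                study$annotation, window = config$window)
      gres <- ghma_scan(cohort, meth, gmap, exposure, out_fu,
                        covariates_em = covars_em,
                        covariates_mo = covars_mo,
                        kernel_threshold = config$kernel_threshold,
                        outcome_family = "binary")
      sig_genes <- gres$gene_id[gres$p_adjusted < config$fdr]
      if (length(sig_genes)) {
        members <- unique(gmap$cpg_id[gmap$gene_id %in% sig_genes])
        nominations[[paste(exposure, "ghma")]] <-
          tibble::tibble(exposure = exposure, method = "ghma",
                         marker = members)
      }
    }
  }

  nominations <- dplyr::bind_rows(nominations)
  validations <- validate_nominations(
    nominations, cohort, meth, out_fu, config, covars_mo,
    direction = "h1", seed_base = med_seed + 10000L)
  mrs_tbl <- dplyr::bind_rows(mrs_rows)
  if (nrow(mrs_tbl)) mrs_tbl$q_acme <- adjust_fdr(mrs_tbl$p_acme)

  new_report("H1", mrs_tbl, nominations, validations, model_ns, config)
}

# shared validation loop: one counterfactual mediation per nominated
# (exposure, marker) pair, then one pooled BH correction per direction
validate_nominations <- function(nominations, cohort, meth, outcome,
                                 config, covars_mo, direction,
                                 seed_base) {
  empty <- tibble::tibble(
    exposure = character(), marker = character(), acme = numeric(),
    acme_low = numeric(), acme_high = numeric(), p_acme = numeric(),
    ade = numeric(), ade_low = numeric(), ade_high = numeric(),
    total = numeric(), total_low = numeric(), total_high = numeric(),
    prop_mediated = numeric(), prop_low = numeric(),
    prop_high = numeric(), n = integer(), q_acme = numeric(),
    validated = logical())
  if (is.null(nominations) || nrow(nominations) == 0L) return(empty)
  pairs <- dplyr::distinct(nominations[, c("exposure", "marker")])
  vals <- meth_matrix(meth)
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    exposure <- pairs$exposure[i]
    marker <- pairs$marker[i]
    covars_em <- config$adjustment_em[[exposure]]
    res <- tryCatch({
      if (direction == "h1") {
        validate_marker(cohort, exposure, vals[, marker],
                        outcome, covars_em, covars_mo, "continuous",
                        "binary", config$n_draws, seed_base + i)
      } else {
        validate_marker(cohort, exposure, cohort[[outcome]], NULL,
                        covars_em, covars_mo, "binary", "continuous",
                        config$n_draws, seed_base + i,
                        outcome_values = vals[, marker])
      }
    }, epimediate_data_error = function(e) {
      warn(sprintf("validation of %s (%s) skipped: %s", marker, exposure,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    mediation_row(res, exposure, marker)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  out$q_acme <- adjust_fdr(out$p_acme)
  out$validated <- out$q_acme < config$fdr
  out
}

new_report <- function(direction, mrs, nominations, validations, model_ns,
                       config) {
  structure(
    list(direction = direction, mrs = mrs, nominations = nominations,
         validations = validations,
         model_n = unlist(model_ns),
         counts = c(n_nominated = nrow(nominations %||%
                                         tibble::tibble()),
                    n_validated = sum(validations$validated %||% logical())),
         config = config, seed = config$seed,
         provenance = list(
           package_version = as.character(utils::packageVersion(
             "epimediate")),
           config_hash = rlang::hash(config))),
    class = "analysis_report")
}

#' Run the reverse (H2) analysis: sensitization as mediator
#'
#' Tests whether baseline sensitization mediates the exposure effects on
#' follow-up methylation. The mediator model is logistic (binary
#' sensitization); outcomes are the follow-up methylation risk scores (one
#' mediation per weight table) and single CpGs, with linear outcome models.
#' Single-CpG nomination uses the composite-null test only: the
#' screen-penalize and gene-based strategies require a high-dimensional
#' mediator, not a high-dimensional outcome. Validation pools the BH
#' correction over all H2 validations.
#'
#' @inheritParams run_h1
#' @return an `analysis_report` list.
#' @export
run_h2 <- function(study, config = run_config()) {
  cohort <- study$cohort
  meth_fu <- study$methylation_followup
  meth_bl <- study$methylation_baseline
  covars_mo <- resolve_covariates_mo(config, cohort)
  out_bl <- config$outcome_baseline
  med_seed <- substream_seed(config$seed, "mediation") + 500000L

  mrs_rows <- list()
  nominations <- list()
  model_ns <- list()

  for (exposure in config$exposures) {
    covars_em <- config$adjustment_em[[exposure]]
    model_ns[[exposure]] <- sum(complete.cases(
      cohort[, unique(c(exposure, out_bl, covars_em, covars_mo)),
             drop = FALSE]))

    # --- follow-up MRS as outcomes, sensitization as mediator; the score
    # threshold is chosen cross-sectionally at baseline, then applied to
    # the follow-up matrix
    for (nm in names(study$weight_tables)) {
      w <- study$weight_tables[[nm]]
      sel <- best_mrs(meth_bl, w, cohort[[out_bl]],
                      thresholds = config$p_threshold_grid,
                      prune = TRUE, r2_threshold = config$r2_threshold)
      thr <- sel$score$p_threshold_used[1]
      fu_score <- compute_mrs(meth_fu, w, thr)
      res <- validate_marker(cohort, exposure, cohort[[out_bl]], NULL,
                             covars_em, covars_mo, "binary",
                             "continuous", config$n_draws,
                             med_seed + length(mrs_rows) + 1L,
                             outcome_values = fu_score$z_score)
      row <- mediation_row(res, exposure, nm)
      row$threshold <- sel$threshold
      mrs_rows[[paste(exposure, nm)]] <- row
    }

    # --- single CpGs: composite-null nomination only
    if (isTRUE(config$methods[["dact"]])) {
      pres <- preselect_candidates(
        cohort, meth_fu, default_prior_cpgs(config, study), out_bl,
        fdr = config$fdr)
      if (length(pres$candidates)) {
        sub <- meth_fu[match(pres$candidates, meth_fu$cpg_id),
                       , drop = FALSE]
        scan <- marginal_scan(cohort, sub, exposure, mediator = out_bl,
                              covariates_em = covars_em,
                              covariates_mo = covars_mo,
                              direction = "h2")
        dres <- dact(scan, calibrate = length(pres$candidates) >= 100)
        hits <- dres$marker[dres$p_calibrated < config$nominate_alpha]
        if (length(hits)) {
          nominations[[paste(exposure, "dact")]] <-
            tibble::tibble(exposure = exposure, method = "dact",
                           marker = hits)
        }
      }
    }
  }

  nominations <- dplyr::bind_rows(nominations)
  validations <- validate_nominations(
    nominations, cohort, meth_fu, out_bl, config, covars_mo,
    direction = "h2", seed_base = med_seed + 10000L)
  mrs_tbl <- dplyr::bind_rows(mrs_rows)
  if (nrow(mrs_tbl)) mrs_tbl$q_acme <- adjust_fdr(mrs_tbl$p_acme)

  new_report("H2", mrs_tbl, nominations, validations, model_ns, config)
}

#' Run both causal directions
#'
#' @inheritParams run_h1
#' @return a named list with elements `h1` and/or `h2` per the configured
#'   direction.
#' @export
run_pipeline <- function(study, config = run_config()) {
  out <- list()
  if (config$direction %in% c("both", "h1")) {
    out$h1 <- run_h1(study, config)
  }
  if (config$direction %in% c("both", "h2")) {
    out$h2 <- run_h2(study, config)
  }
  out
}

#' Sensitivity analyses for validated markers
#'
#' Re-estimates every validated mediation under (i) cell-type-augmented
#' exposure-mediator adjustment, (ii) exclusion of children already
#' sensitized at baseline (forward direction only) and (iii) sex
#' stratification, reporting effect estimates side by side with the main
#' analysis. Strata smaller than `config$min_stratum` are skipped with a
#' warning.
#'
#' @param study the study list.
#' @param config the [run_config()].
#' @param report an `analysis_report` with at least one validated marker.
#' @return tibble with one row per marker and analysis variant.
#' @export
sensitivity_suite <- function(study, config, report) {
  stopifnot(inherits(report, "analysis_report"))
  v <- report$validations
  v <- v[v$validated, , drop = FALSE]
  if (nrow(v) == 0L) {
    abort("no validated markers to analyse.",
          class = "epimediate_data_error")
  }
  cohort <- study$cohort
  h1 <- report$direction == "H1"
  meth <- if (h1) study$methylation_baseline else
    study$methylation_followup
  vals <- meth_matrix(meth)
  covars_mo <- resolve_covariates_mo(config, cohort)
  cells <- grep("^cell_", names(cohort), value = TRUE)
  if (length(cells) > 1) cells <- cells[-length(cells)]
  out_var <- if (h1) config$outcome_followup else config$outcome_baseline
  seed0 <- substream_seed(config$seed, "mediation") + 900000L

  one <- function(rows, exposure, marker, covars_em, label, i) {
    sub <- cohort[rows, , drop = FALSE]
    res <- tryCatch({
      if (h1) {
        validate_marker(sub, exposure, vals[rows, marker], out_var,
                        covars_em, covars_mo, "continuous", "binary",
                        config$n_draws, seed0 + i)
      } else {
        validate_marker(sub, exposure, sub[[out_var]], NULL, covars_em,
                        covars_mo, "binary", "continuous",
                        config$n_draws, seed0 + i,
                        outcome_values = vals[rows, marker])
      }
    }, epimediate_data_error = function(e) {
      warn(sprintf("sensitivity analysis `%s` skipped for %s: %s", label,
                   marker, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    row <- mediation_row(res, exposure, marker)
    row$analysis <- label
    row
  }

  rows <- list()
  i <- 0L
  for (k in seq_len(nrow(v))) {
    exposure <- v$exposure[k]
    marker <- v$marker[k]
    covars_em <- config$adjustment_em[[exposure]]
    all_rows <- seq_len(nrow(cohort))
    variants <- list(
      main = list(rows = all_rows, em = covars_em),
      cell_adjusted = list(rows = all_rows,
                           em = unique(c(covars_em, cells)))
    )
    if (h1) {
      variants$exclude_baseline_sensitized <- list(
        rows = which(cohort[[config$outcome_baseline]] == 0),
        em = covars_em)
    }
    for (sx in c(0, 1)) {
      idx <- which(cohort$sex == sx)
      lab <- if (sx == 1) "males" else "females"
      if (length(idx) < config$min_stratum) {
        warn(sprintf("stratum `%s` has %d samples (< %d); skipped.", lab,
                     length(idx), config$min_stratum))
        next
      }
      em <- setdiff(covars_em, "sex")
      variants[[lab]] <- list(rows = idx, em = em)
    }
    for (label in names(variants)) {
      i <- i + 1L
      rows[[length(rows) + 1L]] <-
        one(variants[[label]]$rows, exposure, marker,
            variants[[label]]$em, label, i)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write an analysis report to disk
#'
#' Emits the validation and MRS tables both as raw delimited tables and as
#' formatted tables (estimate with bracketed 95% interval per effect), the
#' nomination list, and a machine-readable JSON manifest with the seed,
#' configuration hash, per-model sample sizes and step counts. Tables with
#' no rows are still written with their header so downstream tooling can
#' rely on the files existing.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- tolower(report$direction)
  paths <- c(
    validations = file.path(dir, paste0(tag, "_validations.tsv")),
    formatted = file.path(dir, paste0(tag, "_validations_formatted.tsv")),
    nominations = file.path(dir, paste0(tag, "_nominations.tsv")),
    mrs = file.path(dir, paste0(tag, "_mrs.tsv")),
    manifest = file.path(dir, paste0(tag, "_manifest.json"))
  )
  readr::write_tsv(report$validations, paths[["validations"]])
  readr::write_tsv(format_effect_table(report$validations),
                   paths[["formatted"]])
  nom <- report$nominations %||%
    tibble::tibble(exposure = character(), method = character(),
                   marker = character())
  readr::write_tsv(nom, paths[["nominations"]])
  readr::write_tsv(report$mrs %||% tibble::tibble(),
                   paths[["mrs"]])
  manifest <- list(direction = report$direction, seed = report$seed,
                   config_hash = report$provenance$config_hash,
                   package_version = report$provenance$package_version,
                   model_n = as.list(report$model_n),
                   counts = as.list(report$counts))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

format_effect_table <- function(v) {
  if (nrow(v) == 0L) {
    return(tibble::tibble(exposure = character(), marker = character(),
                          indirect = character(), direct = character(),
                          total = character(),
                          prop_mediated = character(),
                          q_value = numeric()))
  }
  fmt <- function(est, lo, hi) sprintf("%.3f [%.3f; %.3f]", est, lo, hi)
  tibble::tibble(
    exposure = v$exposure, marker = v$marker,
    indirect = fmt(v$acme, v$acme_low, v$acme_high),
    direct = fmt(v$ade, v$ade_low, v$ade_high),
    total = fmt(v$total, v$total_low, v$total_high),
    prop_mediated = fmt(v$prop_mediated, v$prop_low, v$prop_high),
    q_value = v$q_acme)
}

#' Stable content hash of an analysis report
#'
#' Hashes the result tables (not the provenance timestamps), so two runs of
#' the same configuration and seed yield the same value.
#'
#' @param report an `analysis_report`.
#' @return a character hash.
#' @export
report_hash <- function(report) {
  rlang::hash(list(report$direction, report$mrs, report$nominations,
                   report$validations, report$model_n))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> direction %s: %d nominated, %d validated\n",
              x$direction, x$counts[["n_nominated"]],
              x$counts[["n_validated"]]))
  if (!is.null(x$validations) && nrow(x$validations)) {
    print(format_effect_table(x$validations))
  }
  invisible(x)
}

#' @describeIn run_h1 tidy method: the pooled validation table.
#' @param x an `analysis_report`.
#' @param ... unused.
#' @export
tidy.analysis_report <- function(x, ...) {
  tibble::as_tibble(x$validations)
}

#' @describeIn run_h1 glance method: one-row run summary.
#' @export
glance.analysis_report <- function(x, ...) {
  tibble::tibble(direction = x$direction,
                 n_nominated = x$counts[["n_nominated"]],
                 n_validated = x$counts[["n_validated"]],
                 n_mrs_models = nrow(x$mrs %||% tibble::tibble()),
                 seed = x$seed)
}

#' @describeIn run_h1 forest plot of indirect effects for all validated
#'   (or, if none, all tested) markers.
#' @param object an `analysis_report`.
#' @export
autoplot.analysis_report <- function(object, ...) {
  v <- object$validations
  if (is.null(v) || nrow(v) == 0L) v <- object$mrs
  if (is.null(v) || nrow(v) == 0L) {
    abort("nothing to plot.", class = "epimediate_data_error")
  }
  ggplot2::ggplot(v, ggplot2::aes(x = .data$acme, y = .data$marker)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$acme_low,
                                          xmax = .data$acme_high)) +
    ggplot2::facet_wrap(~exposure, scales = "free_y") +
    ggplot2::labs(x = "indirect effect (ACME)", y = NULL,
                  title = sprintf("%s mediation", object$direction)) +
    ggplot2::theme_minimal()
}
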