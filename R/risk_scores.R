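#' Greedy pruning of correlated markers
#'
#' Markers are visited in ascending p-value order; a marker is retained only
#' if its squared Pearson correlation with every already-retained marker is
#' at or below `r2_threshold`. This is the clumping convention used when
#' building both methylation and polygenic risk scores. Zero-variance markers
#' cannot be correlated and are excluded with a warning.
#'
#' @param weights tibble with columns `marker_id`, `effect`, `p`.
#' @param values numeric marker-by-sample matrix with marker ids as row
#'   names, covering all markers in `weights`.
#' @param r2_threshold squared-correlation ceiling in (0, 1].
#' @return character vector of retained marker ids, in ascending p-value
#'   order.
#' @export
prune_markers <- function(weights, values, r2_threshold = 0.7) {
  stopifnot(is.data.frame(weights),
            all(c("marker_id", "p") %in% names(weights)))
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    abort("`r2_threshold` must be in (0, 1].",
          class = "epimediate_config_error")
  }
  if (anyDuplicated(weights$marker_id)) {
    abort("duplicate marker ids in weight table.",
          class = "epimediate_data_error")
  }
  missing <- setdiff(weights$marker_id, rownames(values))
  if (length(missing)) {
    abort(sprintf("values matrix lacks %d markers (e.g. %s).",
                  length(missing), missing[1]),
          class = "epimediate_data_error")
  }
  ord <- weights$marker_id[order(weights$p)]
  v <- t(values[ord, , drop = FALSE])  # samples x markers
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d zero-variance marker(s) from pruning.",
                 sum(sds == 0)))
    ord <- ord[sds > 0]
    v <- v[, sds > 0, drop = FALSE]
  }
  retained <- character(0)
  for (m in ord) {
    if (length(retained) == 0L) {
      retained <- m
      next
    }
    r2 <- cor(v[, m], v[, retained, drop = FALSE])^2
    if (all(r2 <= r2_threshold)) retained <- c(retained, m)
  }
  retained
}

score_from_weights <- function(values, weights) {
  # values: marker x sample; weights aligned to rownames(values)
  raw <- as.numeric(crossprod(values, weights))
  names(raw) <- colnames(values)
  raw
}

#' Compute a methylation risk score
#'
#' The score for each sample is the sum of CpG beta values weighted by the
#' EWAS effect sizes of all markers passing the p-value threshold, optionally
#' pruned for inter-marker correlation, then z-scored across the cohort
#' (sample standard deviation). Markers in the weight table but absent from
#' the methylation matrix are skipped and counted, never imputed.
#'
#' @param methylation tibble as returned by [simulate_methylation()] (or read
#'   with [read_methylation()]).
#' @param weights tibble with `marker_id`, `effect`, `p`.
#' @param p_threshold markers with `p` above this are ignored.
#' @param prune if `TRUE`, apply [prune_markers()] before scoring.
#' @param r2_threshold pruning ceiling, used when `prune = TRUE`.
#' @return tibble with `sample_id`, `raw_score`, `z_score`,
#'   `n_markers_used`, `p_threshold_used`; the number of thresholded
#'   markers missing from the matrix is attached as attribute
#'   `n_missing`.
#' @export
compute_mrs <- function(methylation, weights, p_threshold = 1,
                        prune = FALSE, r2_threshold = 0.7) {
  stopifnot(all(c("marker_id", "effect", "p") %in% names(weights)))
  assert_probability(p_threshold, "p_threshold")
  keep <- weights[weights$p <= p_threshold, , drop = FALSE]
  n_thresholded <- nrow(keep)
  available <- keep$marker_id %in% methylation$cpg_id
  n_missing <- sum(!available)
  keep <- keep[available, , drop = FALSE]
  vals <- meth_matrix(methylation)  # samples x CpGs
  vmat <- t(vals[, keep$marker_id, drop = FALSE])  # markers x samples
  if (prune && nrow(keep) > 1) {
    kept_ids <- prune_markers(keep, vmat, r2_threshold)
    keep <- keep[match(kept_ids, keep$marker_id), , drop = FALSE]
    vmat <- vmat[kept_ids, , drop = FALSE]
  }
  if (nrow(keep) == 0L) {
    abort(sprintf(paste0("no markers available for scoring at p <= %g ",
                         "(%d passed the threshold, %d missing from the ",
                         "matrix)."),
                  p_threshold, n_thresholded, n_missing),
          class = "epimediate_empty_score")
  }
  raw <- score_from_weights(vmat, keep$effect)
  out <- tibble::tibble(sample_id = rownames(vals) %||% names(raw),
                        raw_score = unname(raw),
                        z_score = unname(zscore(raw)),
                        n_markers_used = nrow(keep),
                        p_threshold_used = p_threshold)
  attr(out, "n_missing") <- n_missing
  out
}

#' Compute a polygenic risk score from a dosage matrix
#'
#' Applies the standard marker filters before scoring: multiallelic SNPs,
#' SNPs with imputation quality below `quality_min` (default 0.4), minor
#' allele frequency below `maf_min` (default 1%) and zero-effect markers are
#' excluded, and the survivors are pruned greedily at `r2_threshold`. The
#' score is the effect-weighted sum of dosages, z-scored within the cohort.
#'
#' @param genotypes tibble from [simulate_genotypes()] (or
#'   [read_genotypes()]): `snp_id`, `maf`, `imputation_quality`,
#'   `is_multiallelic` plus one dosage column per sample.
#' @param weights tibble with `marker_id`, `effect`, `p`.
#' @param maf_min,quality_min,r2_threshold filter settings.
#' @param prune apply correlation pruning (disable for hand-checked toys).
#' @return tibble as in [compute_mrs()].
#' @export
compute_prs <- function(genotypes, weights, maf_min = 0.01,
                        quality_min = 0.4, r2_threshold = 0.7,
                        prune = TRUE) {
  meta <- c("snp_id", "maf", "imputation_quality", "is_multiallelic")
  stopifnot(all(meta %in% names(genotypes)))
  ok <- !genotypes$is_multiallelic &
    genotypes$imputation_quality >= quality_min &
    genotypes$maf >= maf_min
  keep_geno <- genotypes[ok, , drop = FALSE]
  w <- weights[weights$effect != 0 &
                 weights$marker_id %in% keep_geno$snp_id, , drop = FALSE]
  samp <- setdiff(names(genotypes), meta)
  dosage <- as.matrix(keep_geno[, samp])
  rownames(dosage) <- keep_geno$snp_id
  if (prune && nrow(w) > 1) {
    kept <- prune_markers(w, dosage[w$marker_id, , drop = FALSE],
                          r2_threshold)
    w <- w[match(kept, w$marker_id), , drop = FALSE]
  }
  if (nrow(w) == 0L) {
    abort("no informative SNPs survive the filters.",
          class = "epimediate_empty_score")
  }
  raw <- score_from_weights(dosage[w$marker_id, , drop = FALSE], w$effect)
  tibble::tibble(sample_id = samp, raw_score = unname(raw),
                 z_score = zscore(raw), n_markers_used = nrow(w),
                 p_threshold_used = 1)
}

#' Area under the ROC curve via the rank-sum statistic
#'
#' @param score numeric predictor.
#' @param outcome binary 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(score, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    abort("outcome must have both classes.", class = "epimediate_data_error")
  }
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select the best methylation risk score across p-value thresholds
#'
#' Given candidate scores computed at several thresholds, returns the one
#' with the highest cross-sectional AUC against the (baseline) outcome; ties
#' are broken towards the score built from fewer markers.
#'
#' @param scores named list of score tibbles from [compute_mrs()], typically
#'   one per threshold.
#' @param outcome binary vector aligned with the score rows.
#' @return a list with `threshold` (name of the winner), `auc`, `score`
#'   (the winning tibble) and `candidates` (tibble of all AUCs).
#' @export
select_best_mrs <- function(scores, outcome) {
  if (length(scores) == 0L) {
    abort("no candidate scores supplied.", class = "epimediate_config_error")
  }
  if (length(unique(outcome)) < 2) {
    abort("outcome is constant; AUC is undefined.",
          class = "epimediate_data_error")
  }
  cand <- purrr::imap_dfr(scores, function(s, nm) {
    tibble::tibble(threshold = nm, auc = compute_auc(s$z_score, outcome),
                   n_markers_used = s$n_markers_used[1])
  })
  ord <- order(-cand$auc, cand$n_markers_used)
  best <- cand[ord[1], ]
  list(threshold = best$threshold, auc = best$auc,
       score = scores[[best$threshold]], candidates = cand)
}

#' Compute MRS candidates over a threshold grid and pick the best
#'
#' Thresholds at which no marker survives are skipped. The default grid is
#' the conventional clumping-and-thresholding ladder.
#'
#' @inheritParams compute_mrs
#' @param outcome binary vector aligned with the methylation samples.
#' @param thresholds p-value grid.
#' @return as [select_best_mrs()].
#' @export
best_mrs <- function(methylation, weights, outcome,
                     thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 1),
                     prune = FALSE, r2_threshold = 0.7) {
  cands <- list()
  for (th in thresholds) {
    s <- tryCatch(compute_mrs(methylation, weights, th, prune = prune,
                              r2_threshold = r2_threshold),
                  epimediate_empty_score = function(e) NULL)
    if (!is.null(s)) cands[[format(th, scientific = TRUE)]] <- s
  }
  if (length(cands) == 0L) {
    abort("no threshold yields any scored marker.",
          class = "epimediate_empty_score")
  }
  select_best_mrs(cands, outcome)
}
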