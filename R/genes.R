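#' Assign CpGs to their nearest gene within a window
#'
#' Each CpG is assigned to the gene with the smallest interval distance
#' (zero when the CpG lies inside the gene body); CpGs farther than `window`
#' base pairs from every gene stay unassigned. Gene intervals follow BED
#' convention (0-based, half-open); CpG positions are 1-based. Distance ties
#' are broken towards the gene with the smaller start, then the
#' lexicographically smaller gene id.
#'
#' @param cpgs tibble with `cpg_id`, `chrom`, `pos` (1-based).
#' @param genes tibble with `chrom`, `start` (0-based), `end`, `gene_id`.
#' @param window maximum assignment distance in bp (default 20,000).
#' @return tibble with one row per assigned CpG: `gene_id`, `cpg_id`,
#'   `chrom`, `pos`, `distance`.
#' @export
map_cpgs_to_genes <- function(cpgs, genes, window = 20000) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(cpgs)),
            all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  if (any(genes$end <= genes$start)) {
    abort("gene annotation has empty or inverted intervals.",
          class = "epimediate_data_error")
  }
  res <- lapply(unique(cpgs$chrom), function(ch) {
    cp <- cpgs[cpgs$chrom == ch, , drop = FALSE]
    gn <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gn) == 0L || nrow(cp) == 0L) return(NULL)
    # convert BED to 1-based inclusive: [start + 1, end]
    g1 <- gn$start + 1L
    g2 <- gn$end
    best_d <- rep(Inf, nrow(cp))
    best_i <- rep(NA_integer_, nrow(cp))
    for (i in seq_len(nrow(gn))) {
      d <- pmax(0L, g1[i] - cp$pos, cp$pos - g2[i])
      better <- d < best_d
      tie <- !better & d == best_d & !is.na(best_i)
      if (any(tie)) {
        cur <- best_i[tie]
        swap <- gn$start[i] < gn$start[cur] |
          (gn$start[i] == gn$start[cur] & gn$gene_id[i] < gn$gene_id[cur])
        idx <- which(tie)[swap]
        best_i[idx] <- i
      }
      best_d[better] <- d[better]
      best_i[better] <- i
    }
    keep <- best_d <= window
    tibble::tibble(gene_id = gn$gene_id[best_i[keep]],
                   cpg_id = cp$cpg_id[keep], chrom = ch,
                   pos = cp$pos[keep], distance = best_d[keep])
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, .data$gene_id, .data$pos)
}

# kernel principal components of one gene's scaled CpG block
gene_pcs <- function(B, kernel = c("linear", "gaussian"), threshold = 0.8) {
  kernel <- match.arg(kernel)
  if (nrow(B) < 3) abort("need at least 3 samples for kernel PCs.",
                         class = "epimediate_data_error")
  sds <- apply(B, 2, sd)
  if (all(sds == 0)) abort("constant gene block.",
                           class = "epimediate_data_error")
  B <- B[, sds > 0, drop = FALSE]
  Bs <- scale(B)
  if (kernel == "linear") {
    pc <- prcomp(Bs, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    ev <- ev[ev > 1e-12]
    k <- which(cumsum(ev) / sum(ev) >= threshold)[1]
    scores <- pc$x[, seq_len(k), drop = FALSE]
  } else {
    D <- as.matrix(stats::dist(Bs))
    h <- stats::median(D[upper.tri(D)])
    if (!is.finite(h) || h <= 0) h <- 1
    K <- exp(-D^2 / (2 * h^2))
    n <- nrow(K)
    J <- diag(n) - matrix(1 / n, n, n)
    Kc <- J %*% K %*% J
    eg <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
    ev <- eg$values[eg$values > 1e-10]
    k <- which(cumsum(ev) / sum(ev) >= threshold)[1]
    scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(k)]), k)
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, n_pcs = ncol(scores),
       explained = sum(ev[seq_len(k)]) / sum(ev))
}

# joint-significance mediation test of a PC block:
# stage 1 multivariate test of exposure -> PCs, stage 2 added-block test of
# PCs in the outcome model
pc_joint_test <- function(pcs, cohort, exposure, outcome, covariates_em,
                          covariates_mo, outcome_family) {
  df <- dplyr::bind_cols(cohort, tibble::as_tibble(pcs))
  pc_names <- colnames(pcs)
  rhs1 <- paste(c(covariates_em, exposure), collapse = " + ")
  f1 <- as.formula(paste0("cbind(", paste(pc_names, collapse = ", "),
                          ") ~ ", rhs1))
  fit1 <- lm(f1, data = df)
  a1 <- anova(fit1)  # sequential multivariate tests, exposure last
  p1 <- a1[exposure, "Pr(>F)"]

  rhs_red <- paste(c(exposure, covariates_mo), collapse = " + ")
  rhs_full <- paste(c(pc_names, exposure, covariates_mo), collapse = " + ")
  if (outcome_family == "binary") {
    full <- glm(as.formula(paste(outcome, "~", rhs_full)), data = df,
                family = binomial())
    red <- glm(as.formula(paste(outcome, "~", rhs_red)), data = df,
               family = binomial())
    p2 <- pchisq(red$deviance - full$deviance,
                 df = length(pc_names), lower.tail = FALSE)
  } else {
    full <- lm(as.formula(paste(outcome, "~", rhs_full)), data = df)
    red <- lm(as.formula(paste(outcome, "~", rhs_red)), data = df)
    p2 <- anova(red, full)[2, "Pr(>F)"]
  }
  list(p = max(p1, p2), p_stage1 = p1, p_stage2 = p2)
}

#' Gene-based mediation test on kernel principal components
#'
#' Treats a gene's CpGs as one biological unit: member CpGs are centred and
#' scaled, summarized by the fewest kernel principal components reaching the
#' explained-variance threshold (linear kernel for the linear test; Gaussian
#' kernel with median-pairwise-distance bandwidth for the nonlinear test),
#' and the joint mediation effect of the retained components is tested by a
#' joint-significance test of the multivariate exposure-to-components stage
#' and the components-in-outcome-model stage. The omnibus test combines the
#' linear and nonlinear p-values by the Cauchy combination rule.
#'
#' @param cohort phenotype tibble.
#' @param B samples-by-CpGs beta matrix of the gene's members.
#' @param exposure,outcome column names in `cohort`.
#' @param covariates_em,covariates_mo adjustment sets.
#' @param kernel_threshold explained-variance threshold for retaining
#'   components (conventionally 0.7, 0.8 or 0.9).
#' @param outcome_family `"binary"` or `"continuous"`.
#' @return one-row tibble: `p_linear`, `p_nonlinear`, `p_omnibus`,
#'   `n_pcs_linear`, `n_pcs_nonlinear`, `kernel_threshold`.
#' @export
ghma <- function(cohort, B, exposure, outcome,
                 covariates_em = character(), covariates_mo = character(),
                 kernel_threshold = 0.8, outcome_family = "binary") {
  stopifnot(is.matrix(B), nrow(B) == nrow(cohort))
  lin <- gene_pcs(B, "linear", kernel_threshold)
  nl <- gene_pcs(B, "gaussian", kernel_threshold)
  t_lin <- pc_joint_test(lin$scores, cohort, exposure, outcome,
                         covariates_em, covariates_mo, outcome_family)
  t_nl <- pc_joint_test(nl$scores, cohort, exposure, outcome,
                        covariates_em, covariates_mo, outcome_family)
  tibble::tibble(p_linear = t_lin$p, p_nonlinear = t_nl$p,
                 p_omnibus = cauchy_combine(c(t_lin$p, t_nl$p)),
                 n_pcs_linear = lin$n_pcs, n_pcs_nonlinear = nl$n_pcs,
                 kernel_threshold = kernel_threshold)
}

#' Run the gene-based test over every mapped gene
#'
#' Applies [ghma()] to each gene of a [map_cpgs_to_genes()] assignment and
#' adjusts the omnibus p-values by Benjamini-Hochberg.
#'
#' @inheritParams ghma
#' @param methylation methylation tibble.
#' @param gene_map assignment tibble from [map_cpgs_to_genes()].
#' @return tibble with one row per testable gene, including `p_adjusted`
#'   (BH-adjusted omnibus p-value).
#' @export
ghma_scan <- function(cohort, methylation, gene_map, exposure, outcome,
                      covariates_em = character(),
                      covariates_mo = character(), kernel_threshold = 0.8,
                      outcome_family = "binary") {
  used <- unique(c(exposure, outcome, covariates_em, covariates_mo))
  cc <- complete.cases(cohort[, used, drop = FALSE])
  cohort <- cohort[cc, , drop = FALSE]
  M <- meth_matrix(methylation)[cc, , drop = FALSE]
  genes <- split(gene_map$cpg_id, gene_map$gene_id)
  rows <- purrr::imap(genes, function(members, gid) {
    members <- intersect(members, colnames(M))
    if (length(members) == 0L) return(NULL)
    B <- M[, members, drop = FALSE]
    res <- tryCatch(
      ghma(cohort, B, exposure, outcome, covariates_em, covariates_mo,
           kernel_threshold, outcome_family),
      epimediate_data_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(gene_id = gid,
                                    n_cpgs = length(members)), res)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_adjusted <- adjust_fdr(out$p_omnibus)
  out
}
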