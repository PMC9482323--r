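#' Per-CpG marginal path scan
#'
#' Computes, for every CpG, the two path-specific Wald tests consumed by the
#' composite-null and joint-significance machinery. For the forward direction
#' (`"h1"`, methylation as mediator) `p_alpha` comes from regressing the CpG
#' on the exposure plus the exposure-mediator adjustment set, and `p_beta`
#' from a logistic regression of the (binary) outcome on the CpG, the
#' exposure and the mediator-outcome adjustment set. For the reverse
#' direction (`"h2"`, methylation as final outcome, sensitization as
#' mediator) `p_alpha` is the single logistic exposure-to-mediator test
#' (identical across CpGs) and `p_beta` the linear test of the mediator in
#' CpG ~ mediator + exposure + covariates.
#'
#' Constant CpGs are dropped with a warning. Rows with missing values in any
#' model variable are removed (complete-case per scan).
#'
#' @param cohort phenotype tibble.
#' @param methylation methylation tibble (`cpg_id`, `chrom`, `pos`, one
#'   column per sample).
#' @param exposure exposure column name in `cohort`.
#' @param outcome binary outcome column (`direction = "h1"`).
#' @param mediator binary mediator column (`direction = "h2"`).
#' @param covariates_em,covariates_mo adjustment sets for the two paths.
#' @param direction `"h1"` or `"h2"`.
#' @return a tibble of class `marginal_scan` with columns `marker`,
#'   `est_alpha`, `se_alpha`, `p_alpha`, `est_beta`, `se_beta`, `p_beta`,
#'   in the input CpG order.
#' @export
marginal_scan <- function(cohort, methylation, exposure, outcome = NULL,
                          mediator = NULL, covariates_em = character(),
                          covariates_mo = character(),
                          direction = c("h1", "h2")) {
  direction <- match.arg(direction)
  M <- meth_matrix(methylation)  # samples x CpGs
  stopifnot(nrow(M) == nrow(cohort))
  if (direction == "h1" && is.null(outcome)) {
    abort("`outcome` is required for direction \"h1\".",
          class = "epimediate_config_error")
  }
  if (direction == "h2" && is.null(mediator)) {
    abort("`mediator` is required for direction \"h2\".",
          class = "epimediate_config_error")
  }
  used <- unique(c(exposure, outcome, mediator, covariates_em,
                   covariates_mo))
  cc <- complete.cases(cohort[, used, drop = FALSE])
  cohort <- cohort[cc, , drop = FALSE]
  M <- M[cc, , drop = FALSE]

  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant CpG(s) from the scan.",
                 sum(sds == 0)))
    M <- M[, sds > 0, drop = FALSE]
  }

  if (direction == "h1") {
    Xa <- design_matrix(cohort, c(exposure, covariates_em))
    a <- ols_scan_multi(M, Xa, exposure)
    Xb0 <- design_matrix(cohort, c(exposure, covariates_mo))
    b <- logistic_scan(Xb0, M, cohort[[outcome]])
  } else {
    med_fit <- fit_regression(
      cohort, model_spec(mediator, exposure, covariates = covariates_em,
                         family = "binary"))
    za <- med_fit$coefficients[exposure] /
      sqrt(med_fit$vcov[exposure, exposure])
    a <- list(estimate = rep(unname(med_fit$coefficients[exposure]),
                             ncol(M)),
              se = rep(sqrt(med_fit$vcov[exposure, exposure]), ncol(M)),
              p = rep(2 * pnorm(-abs(unname(za))), ncol(M)))
    Xb <- design_matrix(cohort, c(mediator, exposure, covariates_mo))
    b <- ols_scan_multi(M, Xb, mediator)
  }
  out <- tibble::tibble(marker = colnames(M),
                        est_alpha = unname(a$estimate),
                        se_alpha = unname(a$se),
                        p_alpha = unname(a$p),
                        est_beta = unname(b$estimate),
                        se_beta = unname(b$se),
                        p_beta = unname(b$p))
  failed <- !is.finite(out$p_beta) | !is.finite(out$p_alpha)
  if (any(failed)) {
    warn(sprintf("dropping %d CpG(s) whose path model did not converge.",
                 sum(failed)))
    out <- out[!failed, , drop = FALSE]
  }
  class(out) <- c("marginal_scan", class(out))
  out
}

# conservative lambda-threshold null-proportion estimator
pi0_lambda <- function(p, lambda = 0.5) {
  min(1, mean(p > lambda) / (1 - lambda))
}

# characteristic-function (Jin-Cai style) null-proportion estimator on the
# z-scale: under the N(0,1) null, E[cos(t z)] = exp(-t^2 / 2)
pi0_jc <- function(p) {
  m <- length(p)
  z <- qnorm(pmin(pmax(p, 1e-15), 1 - 1e-15))
  t <- sqrt(0.2 * log(max(m, 10)))
  min(1, max(0, mean(cos(t * z)) * exp(t^2 / 2)))
}

# Efron-style empirical null on the z-scale: truncated-normal ML fit on the
# central peak [-2, 2], median/MAD fallback
efron_null <- function(z, interval = c(-2, 2)) {
  zc <- z[z >= interval[1] & z <= interval[2] & is.finite(z)]
  fallback <- c(mean = stats::median(zc), sd = stats::mad(zc))
  if (length(zc) < 50) return(fallback)
  negll <- function(par) {
    mu <- par[1]
    s <- exp(par[2])
    denom <- pnorm((interval[2] - mu) / s) - pnorm((interval[1] - mu) / s)
    if (denom <= 0) return(1e10)
    -sum(stats::dnorm(zc, mu, s, log = TRUE) - log(denom))
  }
  fit <- tryCatch(
    optim(c(fallback[1], log(max(fallback[2], 1e-3))), negll,
          method = "Nelder-Mead"),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(fallback)
  c(mean = unname(fit$par[1]), sd = unname(exp(fit$par[2])))
}

#' Divide-aggregate composite-null test (DACT)
#'
#' Tests the composite null of no mediation per marker by aggregating the
#' two path p-values over the three null configurations. Null proportions
#' for each path are estimated from the p-value vectors; case weights
#' w1 (alpha = 0, beta != 0), w2 (alpha != 0, beta = 0) and
#' w3 (alpha = beta = 0) are their normalized products; the combined
#' p-value is `w1 p_alpha + w2 p_beta + w3 max(p_alpha, p_beta)^2`. With
#' `calibrate = TRUE` the combined p-values are mapped to z-scores and
#' recalibrated against an empirical null fitted to the central peak, which
#' corrects the anti-conservativeness of the plain mixture when the null
#' proportions are estimated.
#'
#' @param scan a [marginal_scan()] tibble (or any tibble with `marker`,
#'   `p_alpha`, `p_beta`).
#' @param calibrate apply the empirical-null calibration (needs roughly 100
#'   or more markers; falls back with a warning below that).
#' @param pi0_method `"lambda"` (conservative threshold estimator at
#'   lambda = 0.5) or `"jc"` (characteristic-function estimator).
#' @param weights optional fixed `(w1, w2, w3)` overriding estimation (they
#'   are normalized to sum to one); mainly for analytic checks.
#' @return tibble of class `dact_result` with `marker`, `p_alpha`,
#'   `p_beta`, `p_dact`, `p_calibrated`; estimation details are stored in
#'   attributes `weights`, `pi0`, `null_mean`, `null_sd`.
#' @export
dact <- function(scan, calibrate = TRUE,
                 pi0_method = c("lambda", "jc"), weights = NULL) {
  pi0_method <- match.arg(pi0_method)
  stopifnot(all(c("marker", "p_alpha", "p_beta") %in% names(scan)))
  ok <- is.finite(scan$p_alpha) & is.finite(scan$p_beta)
  if (!all(ok)) {
    warn(sprintf("dropping %d marker(s) with unusable path p-values.",
                 sum(!ok)))
    scan <- scan[ok, , drop = FALSE]
  }
  pa <- scan$p_alpha
  pb <- scan$p_beta
  m <- length(pa)
  if (is.null(weights)) {
    est <- if (pi0_method == "lambda") pi0_lambda else pi0_jc
    pi0a <- est(pa)
    pi0b <- est(pb)
    w <- c(pi0a * (1 - pi0b), (1 - pi0a) * pi0b, pi0a * pi0b)
    if (!all(is.finite(w)) || sum(w) <= 0) w <- c(0, 0, 1)
    w <- w / sum(w)
  } else {
    stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
    w <- weights / sum(weights)
    pi0a <- pi0b <- NA_real_
  }
  p_dact <- w[1] * pa + w[2] * pb + w[3] * pmax(pa, pb)^2

  null_mean <- 0
  null_sd <- 1
  p_cal <- p_dact
  if (calibrate) {
    if (m < 100) {
      warn("fewer than 100 markers: returning uncalibrated DACT p-values.")
    } else {
      z <- qnorm(pmin(pmax(p_dact, 1e-15), 1 - 1e-15))
      nullfit <- efron_null(z)
      null_mean <- nullfit[["mean"]]
      null_sd <- max(nullfit[["sd"]], 1e-6)
      p_cal <- pnorm(z, mean = null_mean, sd = null_sd)
    }
  }
  out <- tibble::tibble(marker = scan$marker, p_alpha = pa, p_beta = pb,
                        p_dact = p_dact, p_calibrated = p_cal)
  attr(out, "weights") <- setNames(w, c("w1", "w2", "w3"))
  attr(out, "pi0") <- c(alpha = pi0a, beta = pi0b)
  attr(out, "null_mean") <- null_mean
  attr(out, "null_sd") <- null_sd
  class(out) <- c("dact_result", class(out))
  out
}

#' Sure independence screening of candidate mediators
#'
#' Ranks CpGs by the absolute standardized coefficient of the response on
#' each (standardized) CpG, adjusted for the given covariates, and keeps the
#' top `floor(multiplier * n / ln(n))`. With the default multiplier 2 this
#' reproduces the usual screening cap; the multiplier is exposed because
#' small-cohort analyses may loosen it.
#'
#' @param cohort phenotype tibble.
#' @param methylation methylation tibble.
#' @param response response column name (the outcome for forward mediation).
#' @param covariates adjustment columns (typically exposure plus the
#'   mediator-outcome set).
#' @param multiplier screening-cap multiplier.
#' @param family response family: `"binary"` (logistic scan) or
#'   `"continuous"` (least squares).
#' @return tibble of the screened markers (`marker`, `estimate`) in
#'   decreasing |estimate| order, with attributes `cap` and `n`.
#' @export
sis_screen <- function(cohort, methylation, response,
                       covariates = character(), multiplier = 2,
                       family = c("binary", "continuous")) {
  family <- match.arg(family)
  M <- meth_matrix(methylation)
  used <- unique(c(response, covariates))
  cc <- complete.cases(cohort[, used, drop = FALSE])
  cohort <- cohort[cc, , drop = FALSE]
  M <- M[cc, , drop = FALSE]
  n <- nrow(M)
  if (n < 10) abort("need at least 10 complete cases to screen.",
                    class = "epimediate_data_error")
  cap <- screening_cap(n, multiplier)
  Ms <- scale(M)
  keep <- is.finite(colSums(Ms)) & apply(M, 2, sd) > 0
  Ms <- Ms[, keep, drop = FALSE]
  X0 <- design_matrix(cohort, covariates)
  y <- cohort[[response]]
  if (family == "binary") {
    sc <- logistic_scan(X0, Ms, y)
    est <- sc$estimate
  } else {
    # Frisch-Waugh: residualize response and markers on the covariates
    q <- qr(X0)
    ry <- stats::qr.resid(q, y)
    RM <- stats::qr.resid(q, Ms)
    est <- colSums(RM * ry) / colSums(RM^2)
  }
  names(est) <- colnames(Ms)
  est <- est[is.finite(est)]
  ord <- order(-abs(est))
  top <- head(ord, cap)
  out <- tibble::tibble(marker = names(est)[top],
                        estimate = unname(est[top]))
  attr(out, "cap") <- cap
  attr(out, "n") <- n
  out
}

#' Screening cap of sure independence screening
#'
#' `floor(multiplier * n / ln(n))`, the number of markers retained at sample
#' size `n` (natural logarithm).
#'
#' @param n sample size.
#' @param multiplier cap multiplier (2 by default).
#' @return integer cap.
#' @export
screening_cap <- function(n, multiplier = 2) {
  as.integer(floor(multiplier * n / log(n)))
}

#' Minimax-concave-penalty selection of mediators
#'
#' Fits the outcome on all screened mediators (penalized) plus the exposure
#' and covariates (unpenalized) under the minimax concave penalty by
#' coordinate descent, over a descending log-spaced penalty grid with warm
#' starts, and picks the penalty by BIC. On an orthonormal design the
#' coordinate update is the firm-thresholding closed form, and at zero
#' penalty the fit coincides with unpenalized least squares.
#'
#' @param M numeric samples-by-markers matrix of screened mediators.
#' @param y response vector.
#' @param X_unpen optional matrix or data frame of unpenalized columns
#'   (exposure, covariates); an intercept is always added.
#' @param family `"continuous"` or `"binary"`.
#' @param gamma MCP concavity parameter (> 1; 3 by default).
#' @param nlambda grid size when `lambda` is not given.
#' @param lambda optional penalty grid (sorted descending internally).
#' @param lambda_min_ratio smallest grid penalty as a fraction of the
#'   data-derived maximum.
#' @param dfmax stop the path once more than this many penalized
#'   coefficients are active (defaults to `min(p, n/2)`): deeper penalties
#'   head into quasi-separation for logistic fits and are never the BIC
#'   optimum.
#' @param standardize standardize penalized columns internally (coefficients
#'   are always returned on the input scale).
#' @return list with `selected` (marker names with nonzero coefficients at
#'   the BIC-chosen penalty), `coefficients` (named, input scale),
#'   `lambda` (chosen), `path` (BIC per penalty) and `gamma`.
#' @export
mcp_select <- function(M, y, X_unpen = NULL,
                       family = c("continuous", "binary"), gamma = 3,
                       nlambda = 50, lambda = NULL,
                       lambda_min_ratio = 0.05, dfmax = NULL,
                       standardize = TRUE, tol = NULL) {
  family <- match.arg(family)
  stopifnot(is.matrix(M), nrow(M) == length(y), gamma > 1)
  if (is.null(colnames(M))) colnames(M) <- paste0("m", seq_len(ncol(M)))
  n <- nrow(M)
  Xu <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(X_unpen)) {
    Xu <- cbind(Xu, as.matrix(X_unpen))
  }
  if (standardize) {
    ctr <- colMeans(M)
    scl <- sqrt(colMeans(sweep(M, 2, ctr)^2))
    scl[scl == 0] <- 1
    Mp <- sweep(sweep(M, 2, ctr), 2, scl, `/`)
  } else {
    Mp <- M
    scl <- rep(1, ncol(M))
  }
  if (is.null(lambda)) {
    r0 <- y - mean(y)
    lmax <- max(abs(crossprod(Mp, r0)) / n) * 1.0001
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  if (is.null(dfmax)) dfmax <- min(ncol(Mp), floor(n / 2))
  fam_code <- if (family == "binary") 1L else 0L
  if (is.null(tol)) tol <- if (family == "binary") 1e-4 else 1e-8
  fit <- cpp_mcp_path(Mp, Xu, as.numeric(y), lambda, gamma, fam_code,
                      tol = tol, dfmax = as.integer(dfmax))
  lambda <- lambda[seq_len(fit$n_used)]
  coefs <- fit$coefficients[, seq_len(fit$n_used), drop = FALSE]
  fit$converged <- fit$converged[seq_len(fit$n_used)]
  p <- ncol(Mp)

  # BIC on the unpenalized refit of each active set: the penalized
  # estimates are still shrunk near the activation threshold, which would
  # bias a plugged-in deviance towards the null model
  refit_dev <- function(active) {
    X <- cbind(Xu, Mp[, active, drop = FALSE])
    if (ncol(X) >= n) return(Inf)
    if (family == "binary") {
      f <- tryCatch(
        suppressWarnings(glm.fit(X, y, family = binomial())),
        error = function(e) NULL)
      if (is.null(f)) return(Inf)
      f$deviance
    } else {
      f <- lm.fit(X, y)
      rss <- sum(f$residuals^2)
      n * log(rss / n)
    }
  }
  cache <- new.env(parent = emptyenv())
  bic <- vapply(seq_along(lambda), function(l) {
    active <- which(coefs[seq_len(p), l] != 0)
    key <- paste0("s", paste(active, collapse = ","))
    dev <- if (!is.null(cache[[key]])) {
      cache[[key]]
    } else {
      cache[[key]] <- refit_dev(active)
    }
    dev + (length(active) + ncol(Xu)) * log(n)
  }, numeric(1))
  conv <- as.logical(fit$converged)
  if (!any(conv)) {
    abort(sprintf("MCP fit did not converge at any penalty (last tried %.5g).",
                  min(lambda)),
          class = "epimediate_numerical_error")
  }
  # quasi-separated deep-path fits never converge and are excluded from
  # model selection
  bic[!conv] <- Inf
  best <- which.min(bic)
  beta_pen <- coefs[seq_len(p), best] / scl
  names(beta_pen) <- colnames(M)
  beta_unpen <- coefs[-seq_len(p), best]
  names(beta_unpen) <- colnames(Xu)
  list(selected = names(beta_pen)[beta_pen != 0],
       coefficients = c(beta_pen, beta_unpen),
       lambda = lambda[best],
       path = tibble::tibble(lambda = lambda, bic = bic,
                             converged = as.logical(fit$converged)),
       gamma = gamma)
}

#' Joint-significance test over selected mediators
#'
#' The mediation p-value of each selected marker is the maximum of its two
#' path p-values, adjusted for multiplicity over the selected set.
#'
#' @param selected character vector of selected marker ids.
#' @param scan a [marginal_scan()] tibble covering them.
#' @param method multiplicity adjustment (`"BH"` default; any
#'   [stats::p.adjust()] method).
#' @return tibble with `marker`, `p_alpha`, `p_beta`, `p_joint`,
#'   `p_adjusted` (empty if nothing was selected).
#' @export
joint_significance <- function(selected, scan, method = "BH") {
  if (length(selected) == 0L) {
    return(tibble::tibble(marker = character(), p_alpha = numeric(),
                          p_beta = numeric(), p_joint = numeric(),
                          p_adjusted = numeric()))
  }
  if (!all(selected %in% scan$marker)) {
    abort("selected markers missing from the scan.",
          class = "epimediate_data_error")
  }
  s <- scan[match(selected, scan$marker), ]
  p_joint <- pmax(s$p_alpha, s$p_beta)
  tibble::tibble(marker = s$marker, p_alpha = s$p_alpha,
                 p_beta = s$p_beta, p_joint = p_joint,
                 p_adjusted = p.adjust(p_joint, method = method))
}

#' Epigenome-wide mediator search (screen, penalize, joint-test)
#'
#' The three-step forward search for CpG mediators: sure independence
#' screening on the outcome, minimax-concave-penalty selection of the
#' screened set, and joint-significance testing with multiplicity adjustment
#' of the survivors.
#'
#' @inheritParams marginal_scan
#' @param multiplier screening-cap multiplier.
#' @param fdr significance level on adjusted joint p-values.
#' @param ... passed to [mcp_select()].
#' @return list of class `hima_result` with `screened`, `selected`,
#'   `results` (joint-significance tibble) and `significant` (markers with
#'   `p_adjusted < fdr`).
#' @export
hima <- function(cohort, methylation, exposure, outcome,
                 covariates_em = character(), covariates_mo = character(),
                 multiplier = 2, fdr = 0.05, ...) {
  used <- unique(c(exposure, outcome, covariates_em, covariates_mo))
  cc <- complete.cases(cohort[, used, drop = FALSE])
  cohort <- cohort[cc, , drop = FALSE]
  meta <- methylation[, c("cpg_id", "chrom", "pos")]
  samp <- setdiff(names(methylation), names(meta))
  methylation <- dplyr::bind_cols(meta, methylation[, samp][, cc,
                                                           drop = FALSE])
  screened <- sis_screen(cohort, methylation, response = outcome,
                         covariates = c(exposure, covariates_mo),
                         multiplier = multiplier, family = "binary")
  M <- meth_matrix(methylation)[, screened$marker, drop = FALSE]
  Xu <- design_matrix(cohort, c(exposure, covariates_mo))[, -1,
                                                          drop = FALSE]
  sel <- mcp_select(M, cohort[[outcome]], X_unpen = Xu,
                    family = "binary", ...)
  sub <- methylation[methylation$cpg_id %in% screened$marker, ,
                     drop = FALSE]
  scan <- marginal_scan(cohort, sub, exposure, outcome = outcome,
                        covariates_em = covariates_em,
                        covariates_mo = covariates_mo, direction = "h1")
  res <- joint_significance(intersect(sel$selected, scan$marker), scan)
  structure(list(screened = screened, selected = sel$selected,
                 mcp = sel, results = res,
                 significant = res$marker[res$p_adjusted < fdr]),
            class = "hima_result")
}

#' @export
print.hima_result <- function(x, ...) {
  cat(sprintf("<hima_result> screened %d, selected %d, significant %d\n",
              nrow(x$screened), length(x$selected),
              length(x$significant)))
  if (nrow(x$results)) print(x$results)
  invisible(x)
}

#' @describeIn dact p-value histogram with the calibrated values overlaid.
#' @param object a `dact_result`.
#' @param ... unused.
#' @export
autoplot.dact_result <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("p_dact", "p_calibrated")],
    cols = dplyr::everything(), names_to = "kind", values_to = "p")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p, fill = .data$kind)) +
    ggplot2::geom_histogram(boundary = 0, bins = 30, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "composite-null p-value", y = "markers") +
    ggplot2::theme_minimal()
}
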