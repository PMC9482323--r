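#' Describe a regression model for the mediation machinery
#'
#' A minimal model description: continuous responses are fit by ordinary
#' least squares, binary responses by maximum-likelihood logistic regression.
#'
#' @param response,treatment variable names in the data.
#' @param mediator mediator variable name, or `NULL` for the mediator model
#'   itself.
#' @param covariates character vector of adjustment variables.
#' @param family `"continuous"` or `"binary"`.
#' @param interaction include a treatment-by-mediator interaction term
#'   (outcome models only; off by default).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, treatment, mediator = NULL,
                       covariates = character(),
                       family = c("continuous", "binary"),
                       interaction = FALSE) {
  family <- match.arg(family)
  if (treatment %in% covariates) {
    abort("treatment must not appear in the covariate list.",
          class = "epimediate_config_error")
  }
  if (!is.null(mediator) && mediator %in% covariates) {
    abort("mediator must not appear in the covariate list.",
          class = "epimediate_config_error")
  }
  structure(list(response = response, treatment = treatment,
                 mediator = mediator, covariates = covariates,
                 family = family, interaction = interaction),
            class = "model_spec")
}

spec_vars <- function(spec) {
  unique(c(spec$response, spec$treatment, spec$mediator, spec$covariates))
}

spec_formula <- function(spec) {
  rhs <- c(spec$treatment, spec$mediator, spec$covariates)
  if (spec$interaction && !is.null(spec$mediator)) {
    rhs <- c(rhs, paste0(spec$treatment, ":", spec$mediator))
  }
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a mediator or outcome regression
#'
#' Complete-case maximum-likelihood fit of the model described by a
#' [model_spec()]: ordinary least squares for continuous responses, logistic
#' regression for binary ones. Degenerate inputs (too few complete cases,
#' rank-deficient design, constant binary response, separation) raise
#' descriptive errors rather than returning an unusable fit.
#'
#' @param data a data frame containing every variable in the spec.
#' @param spec a [model_spec()].
#' @return an object of class `epimediate_fit` carrying coefficients, their
#'   covariance, the residual scale (continuous case), and the complete-case
#'   model frame used.
#' @export
fit_regression <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- spec_vars(spec)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(sprintf("data lacks variable(s): %s",
                  paste(missing_vars, collapse = ", ")),
          class = "epimediate_config_error")
  }
  frame <- data[, vars, drop = FALSE]
  cc <- complete.cases(frame)
  frame <- frame[cc, , drop = FALSE]
  frame$.row <- which(cc)
  f <- spec_formula(spec)
  X <- model.matrix(f, data = frame)
  if (nrow(X) < ncol(X) + 2) {
    abort(sprintf("only %d complete cases for %d parameters.", nrow(X),
                  ncol(X)),
          class = "epimediate_data_error")
  }
  if (qr(X)$rank < ncol(X)) {
    abort("rank-deficient design (collinear predictors).",
          class = "epimediate_data_error")
  }
  y <- frame[[spec$response]]
  if (spec$family == "binary") {
    if (length(unique(y)) < 2) {
      abort("binary response is constant; nothing to fit.",
            class = "epimediate_data_error")
    }
    fit <- suppressWarnings(glm(f, data = frame, family = binomial()))
    # separation check on the standardized scale: a large raw coefficient
    # on a tiny-variance predictor (e.g. a beta-valued CpG) is fine
    col_sd <- apply(X[, -1, drop = FALSE], 2, sd)
    scaled <- abs(coef(fit)[-1]) * col_sd
    if (!fit$converged || any(!is.finite(scaled)) || max(scaled, 0) > 15) {
      abort("logistic fit did not converge (possible separation).",
            class = "epimediate_data_error")
    }
  } else {
    fit <- lm(f, data = frame)
  }
  structure(
    list(coefficients = coef(fit), vcov = vcov(fit),
         sigma = if (spec$family == "continuous") summary(fit)$sigma else NA,
         df_residual = fit$df.residual, family = spec$family, spec = spec,
         frame = frame, n = nrow(frame), formula = f),
    class = "epimediate_fit"
  )
}

#' @export
print.epimediate_fit <- function(x, ...) {
  cat(sprintf("<epimediate_fit> %s model: %s (n = %d)\n", x$family,
              deparse(x$formula), x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

# design matrix of a fit with treatment forced to `t` and the mediator
# column (and any interaction column) zeroed out, so that the mediator
# contribution can be added per draw
base_design <- function(fit, t_value) {
  spec <- fit$spec
  frame <- fit$frame
  frame[[spec$treatment]] <- t_value
  if (!is.null(spec$mediator)) frame[[spec$mediator]] <- 0
  model.matrix(fit$formula, data = frame)
}

#' Quasi-Bayesian counterfactual effect decomposition
#'
#' Implements the standard simulation algorithm for single-mediator causal
#' mediation: parameter vectors are drawn from the asymptotic normal
#' distribution of each fitted model; for every draw, potential mediator
#' values M(t) and potential outcomes Y(t, M(t')) are simulated over the
#' observed covariate distribution; the average causal mediation effect
#' ACME(t) is the mean of Y(t, M(1)) - Y(t, M(0)), the average direct effect
#' ADE(t) the mean of Y(1, M(t)) - Y(0, M(t)), and reported effects average
#' over t in \{0, 1\}. Within every draw the total effect equals
#' ACME(t) + ADE(1 - t), so the reported decomposition is additive to
#' machine precision. Binary outcomes are reported on the risk-difference
#' (probability) scale. Confidence intervals are percentile intervals over
#' draws and p-values are two-sided simulation p-values.
#'
#' The proportion mediated is unstable in draws whose total effect is
#' essentially zero; such draws (|TE| < 1e-12) are excluded from its summary
#' and counted. Its point estimate is the mean of per-draw ACME/TE ratios by
#' default; `prop_med = "ratio_of_means"` uses the ratio of the two point
#' estimates instead.
#'
#' @param mediator_fit,outcome_fit fits from [fit_regression()]; the
#'   mediator fit's response must be the outcome fit's mediator, and both
#'   must share the treatment and come from the same data frame.
#' @param n_draws number of quasi-Bayesian draws (at least 100).
#' @param seed integer seed for reproducibility.
#' @param control_value,treat_value treatment values contrasted (0/1 for a
#'   binary exposure; any two values for a continuous one).
#' @param prop_med `"mean_ratio"` (default) or `"ratio_of_means"`.
#' @param keep_draws retain the per-draw effect vectors in the result.
#' @return an object of class `mediation_result`.
#' @export
estimate_effects <- function(mediator_fit, outcome_fit, n_draws = 1000,
                             seed = NULL, control_value = 0,
                             treat_value = 1,
                             prop_med = c("mean_ratio", "ratio_of_means"),
                             keep_draws = FALSE) {
  prop_med <- match.arg(prop_med)
  stopifnot(inherits(mediator_fit, "epimediate_fit"),
            inherits(outcome_fit, "epimediate_fit"))
  if (n_draws < 100) {
    abort("`n_draws` must be at least 100.",
          class = "epimediate_config_error")
  }
  ms <- mediator_fit$spec
  ys <- outcome_fit$spec
  if (ms$treatment != ys$treatment) {
    abort("the two fits must share the treatment variable.",
          class = "epimediate_config_error")
  }
  if (is.null(ys$mediator) || ys$mediator != ms$response) {
    abort("the outcome fit's mediator must be the mediator fit's response.",
          class = "epimediate_config_error")
  }

  # rows complete in both models
  common <- intersect(mediator_fit$frame$.row, outcome_fit$frame$.row)
  if (length(common) < 10) {
    abort("fewer than 10 rows are complete in both models.",
          class = "epimediate_data_error")
  }
  mfit <- mediator_fit
  yfit <- outcome_fit
  mfit$frame <- mfit$frame[match(common, mfit$frame$.row), , drop = FALSE]
  yfit$frame <- yfit$frame[match(common, yfit$frame$.row), , drop = FALSE]
  tvar <- mfit$frame[[ms$treatment]]
  if (length(unique(tvar)) < 2) {
    abort("treatment does not vary on the common rows (no overlap).",
          class = "epimediate_data_error")
  }
  n <- length(common)

  if (!is.null(seed)) {
    res <- with_seed(seed, quasi_bayes_draws(mfit, yfit, n_draws,
                                             control_value, treat_value))
  } else {
    res <- quasi_bayes_draws(mfit, yfit, n_draws, control_value,
                             treat_value)
  }
  acme_d <- res$acme
  ade_d <- res$ade
  tau_d <- acme_d + ade_d

  summarize <- function(d) {
    ci <- unname(quantile(d, c(0.025, 0.975), type = 7))
    p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
    list(est = mean(d), ci = ci, p = p)
  }
  s_acme <- summarize(acme_d)
  s_ade <- summarize(ade_d)
  s_tau <- summarize(tau_d)
  usable <- abs(tau_d) >= 1e-12
  ratio <- acme_d[usable] / tau_d[usable]
  prop_est <- if (prop_med == "mean_ratio") {
    mean(ratio)
  } else {
    mean(acme_d) / mean(tau_d)
  }
  prop_ci <- if (length(ratio)) {
    unname(quantile(ratio, c(0.025, 0.975), type = 7))
  } else {
    c(NA_real_, NA_real_)
  }

  structure(
    list(acme = s_acme$est, acme_ci = s_acme$ci, p_acme = s_acme$p,
         ade = s_ade$est, ade_ci = s_ade$ci, p_ade = s_ade$p,
         total = s_tau$est, total_ci = s_tau$ci, p_total = s_tau$p,
         prop_mediated = prop_est, prop_mediated_ci = prop_ci,
         prop_med_convention = prop_med,
         n_excluded_draws = sum(!usable), n = n, n_draws = n_draws,
         seed = seed, control_value = control_value,
         treat_value = treat_value,
         mediator_family = mfit$family, outcome_family = yfit$family,
         treatment = ms$treatment, mediator = ms$response,
         outcome = ys$response,
         draws = if (keep_draws) list(acme = acme_d, ade = ade_d) else NULL),
    class = "mediation_result"
  )
}

# core simulation; assumes frames already restricted to common rows
quasi_bayes_draws <- function(mfit, yfit, n_draws, control_value,
                              treat_value) {
  n <- nrow(mfit$frame)
  theta_m <- MASS::mvrnorm(n_draws, mfit$coefficients, mfit$vcov)
  theta_y <- MASS::mvrnorm(n_draws, yfit$coefficients, yfit$vcov)

  Xm0 <- base_design(mfit, control_value)
  Xm1 <- base_design(mfit, treat_value)
  mu_m0 <- Xm0 %*% t(theta_m)   # n x n_draws
  mu_m1 <- Xm1 %*% t(theta_m)
  if (mfit$family == "continuous") {
    sigma_d <- mfit$sigma *
      sqrt(mfit$df_residual / rchisq(n_draws, mfit$df_residual))
    err <- matrix(rnorm(n * n_draws), n, n_draws) *
      matrix(sigma_d, n, n_draws, byrow = TRUE)
    M0 <- mu_m0 + err
    M1 <- mu_m1 + err
  } else {
    u <- matrix(runif(n * n_draws), n, n_draws)
    M0 <- (u < plogis(mu_m0)) * 1
    M1 <- (u < plogis(mu_m1)) * 1
  }

  ys <- yfit$spec
  cn <- colnames(model.matrix(yfit$formula, data = yfit$frame))
  med_idx <- match(ys$mediator, cn)
  int_idx <- if (ys$interaction) {
    ix <- match(paste0(ys$treatment, ":", ys$mediator), cn)
    if (is.na(ix)) ix <- match(paste0(ys$mediator, ":", ys$treatment), cn)
    ix
  } else {
    NA_integer_
  }
  Xy0 <- base_design(yfit, control_value)
  Xy1 <- base_design(yfit, treat_value)
  theta_med <- theta_y[, med_idx]
  theta_int <- if (!is.na(int_idx)) theta_y[, int_idx] else NULL
  eta_base0 <- Xy0 %*% t(theta_y)
  eta_base1 <- Xy1 %*% t(theta_y)

  linkinv <- if (yfit$family == "binary") plogis else identity
  outcome_at <- function(eta_base, t_value, M) {
    slope <- theta_med
    if (!is.null(theta_int)) slope <- slope + t_value * theta_int
    linkinv(eta_base + M * matrix(slope, nrow(M), ncol(M), byrow = TRUE))
  }
  Y00 <- outcome_at(eta_base0, control_value, M0)
  Y01 <- outcome_at(eta_base0, control_value, M1)
  Y10 <- outcome_at(eta_base1, treat_value, M0)
  Y11 <- outcome_at(eta_base1, treat_value, M1)

  delta0 <- colMeans(Y01 - Y00)
  delta1 <- colMeans(Y11 - Y10)
  zeta0 <- colMeans(Y10 - Y00)
  zeta1 <- colMeans(Y11 - Y01)
  list(acme = (delta0 + delta1) / 2, ade = (zeta0 + zeta1) / 2)
}

#' One-call causal mediation on a data frame
#'
#' Convenience wrapper fitting the mediator and outcome models from variable
#' names and decomposing effects with [estimate_effects()].
#'
#' @param data data frame with all variables.
#' @param treatment,mediator,outcome variable names.
#' @param covariates_m,covariates_y adjustment sets for the
#'   exposure-mediator and mediator-outcome models.
#' @param family_m,family_y model families.
#' @inheritParams estimate_effects
#' @return a `mediation_result`.
#' @export
mediate <- function(data, treatment, mediator, outcome,
                    covariates_m = character(), covariates_y = character(),
                    family_m = "continuous", family_y = "binary",
                    n_draws = 1000, seed = NULL, ...) {
  mfit <- fit_regression(data, model_spec(mediator, treatment,
                                          covariates = covariates_m,
                                          family = family_m))
  yfit <- fit_regression(data, model_spec(outcome, treatment,
                                          mediator = mediator,
                                          covariates = covariates_y,
                                          family = family_y))
  estimate_effects(mfit, yfit, n_draws = n_draws, seed = seed, ...)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with enforced monotonicity; the input order is
#' preserved.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted q-values in the input order.
#' @export
adjust_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].", class = "epimediate_data_error")
  }
  p.adjust(p, method = "BH")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s (n = %d, draws = %d)\n",
              x$treatment, x$mediator, x$outcome, x$n, x$n_draws))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn estimate_effects tidy method: one row per effect with
#'   estimate, percentile CI and simulation p-value.
#' @param x a `mediation_result`.
#' @param ... unused.
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total", "prop_mediated"),
    estimate = c(x$acme, x$ade, x$total, x$prop_mediated),
    conf.low = c(x$acme_ci[1], x$ade_ci[1], x$total_ci[1],
                 x$prop_mediated_ci[1]),
    conf.high = c(x$acme_ci[2], x$ade_ci[2], x$total_ci[2],
                  x$prop_mediated_ci[2]),
    p.value = c(x$p_acme, x$p_ade, x$p_total, NA_real_)
  )
}

#' @describeIn estimate_effects glance method: one-row model summary.
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_draws = x$n_draws,
                 mediator_family = x$mediator_family,
                 outcome_family = x$outcome_family,
                 n_excluded_draws = x$n_excluded_draws)
}

#' @describeIn estimate_effects forest plot of the effect decomposition.
#' @param object a `mediation_result`.
#' @export
autoplot.mediation_result <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "prop_mediated", ]
  d$term <- factor(d$term, levels = rev(c("acme", "ade", "total")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "effect (risk difference / response scale)",
                  y = NULL,
                  title = sprintf("%s → %s → %s", object$treatment,
                                  object$mediator, object$outcome)) +
    ggplot2::theme_minimal()
}
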