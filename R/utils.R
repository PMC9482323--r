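# internal helpers shared across modules

# Named substreams expanded from one global seed, so that e.g. adding CpGs to
# a simulation does not perturb the phenotype draws.
.stream_offsets <- c(
  cohort = 1L, planted = 2L, meth_baseline = 3L, meth_followup = 4L,
  genotypes = 5L, weights = 6L, positions = 7L, genes = 8L,
  mediation = 9L, pipeline = 10L
)

substream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.stream_offsets))
  offset <- .stream_offsets[[stream]]
  as.integer((as.numeric(seed) * 31L + offset * 97919) %% 2147483629)
}

# run code under a temporary RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "epimediate_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != round(x)) {
    abort(sprintf("`%s` must be a positive integer.", name),
          class = "epimediate_config_error")
  }
  invisible(as.integer(x))
}

# z-score with the sample (n - 1) standard deviation
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot z-score a constant vector", class = "epimediate_data_error")
  }
  (x - mean(x)) / s
}

# column-wise OLS of many responses against one shared design matrix,
# returning the Wald estimate/SE/p for a single coefficient. Used for every
# scan in which the design is shared and only the response varies.
ols_scan_multi <- function(Y, X, coef_name) {
  stopifnot(is.matrix(Y), is.matrix(X), nrow(Y) == nrow(X))
  j <- match(coef_name, colnames(X))
  if (is.na(j)) abort(sprintf("coefficient `%s` not in design", coef_name))
  n <- nrow(X)
  k <- qr(X)$rank
  if (k < ncol(X)) abort("rank-deficient scan design",
                         class = "epimediate_data_error")
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXinv[j, j])
  est <- B[j, ]
  tval <- est / se
  p <- 2 * pt(-abs(tval), df)
  list(estimate = est, se = se, p = p, df = df)
}

# per-column logistic Wald scan (shared design + one varying column)
logistic_scan <- function(X0, M, y) {
  stopifnot(is.matrix(X0), is.matrix(M), nrow(X0) == nrow(M))
  out <- cpp_logistic_scan(X0, M, as.numeric(y))
  est <- as.numeric(out$estimate)
  se <- as.numeric(out$se)
  z <- est / se
  list(estimate = est, se = se, p = 2 * pnorm(-abs(z)))
}

# build a design matrix with intercept from a data frame and variable names
design_matrix <- function(data, vars) {
  if (length(vars) == 0L) {
    return(matrix(1, nrow = nrow(data), dimnames = list(NULL, "(Intercept)")))
  }
  f <- as.formula(paste("~", paste(vars, collapse = " + ")))
  model.matrix(f, data = data)
}

# methylation tibble (cpg_id, chrom, pos, <samples>) -> samples x CpG matrix
meth_matrix <- function(methylation) {
  meta <- c("cpg_id", "chrom", "pos")
  stopifnot(all(meta %in% names(methylation)))
  samp <- setdiff(names(methylation), meta)
  m <- t(as.matrix(methylation[, samp]))
  colnames(m) <- methylation$cpg_id
  m
}

cauchy_combine <- function(p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stat <- mean(tan((0.5 - p) * pi))
  0.5 - atan(stat) / pi
}
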