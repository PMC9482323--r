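test_that("linear fits are exact least squares", {
  d <- tibble::tibble(x = c(0, 1, 2, 3), y = 2 * c(0, 1, 2, 3) + 1)
  f <- fit_regression(d, model_spec("y", "x", family = "continuous"))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-12)

  # 6-point toy against the closed-form normal equations
  set.seed(2)
  d2 <- tibble::tibble(x = rnorm(6), z = rnorm(6),
                       y = 1.5 - 0.7 * rnorm(6))
  f2 <- fit_regression(d2, model_spec("y", "x", covariates = "z",
                                      family = "continuous"))
  X <- cbind(1, d2$x, d2$z)
  beta <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(unname(f2$coefficients), as.numeric(beta),
               tolerance = 1e-10)
})

test_that("degenerate regressions raise descriptive errors", {
  d <- tibble::tibble(x = rnorm(30), y = rep(1, 30))
  expect_error(fit_regression(d, model_spec("y", "x", family = "binary")),
               class = "epimediate_data_error")
  d2 <- tibble::tibble(x = rnorm(30), x2 = NA_real_, y = rnorm(30))
  d2$x2 <- 2 * d2$x  # collinear
  expect_error(
    fit_regression(d2, model_spec("y", "x", covariates = "x2",
                                  family = "continuous")),
    class = "epimediate_data_error")
  d3 <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                       y = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_regression(d3, model_spec("y", "x", family = "binary")),
               class = "epimediate_data_error")
  expect_error(model_spec("y", "x", covariates = "x"),
               class = "epimediate_config_error")
})

test_that("effect decomposition is additive to machine precision", {
  set.seed(11)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  m <- 0.5 * x + rnorm(n)
  d <- tibble::tibble(
    x = x, m = m,
    y_cont = 0.4 * m + 0.2 * x + rnorm(n),
    y_bin = rbinom(n, 1, plogis(0.8 * m + 0.3 * x)))
  for (spec in list(c("y_cont", "continuous"), c("y_bin", "binary"))) {
    r <- mediate(d, "x", "m", spec[1], family_m = "continuous",
                 family_y = spec[2], n_draws = 200, seed = 1)
    expect_lt(abs(r$total - (r$acme + r$ade)), 1e-9)
    expect_lte(r$acme_ci[1], r$acme)
    expect_gte(r$acme_ci[2], r$acme)
  }
})

test_that("ACME matches the product-of-coefficients oracle (no interaction)", {
  set.seed(12)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  m <- 0.5 * x + rnorm(n)
  y <- 0.4 * m + 0.3 * x + rnorm(n)
  d <- tibble::tibble(x = x, m = m, y = y)
  ahat <- coef(lm(m ~ x, d))[["x"]]
  bhat <- coef(lm(y ~ m + x, d))[["m"]]
  r <- mediate(d, "x", "m", "y", family_m = "continuous",
               family_y = "continuous", n_draws = 10000, seed = 2,
               keep_draws = TRUE)
  mc_se <- sd(r$draws$acme) / sqrt(r$n_draws)
  expect_lt(abs(r$acme - ahat * bhat), 3 * mc_se)
})

test_that("a null mediator path yields a near-zero ACME with covering CI", {
  set.seed(13)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  m <- 0.5 * x + rnorm(n)
  y <- 0 * m + 0.3 * x + rnorm(n)   # b = 0 in the generating process
  r <- mediate(tibble::tibble(x = x, m = m, y = y), "x", "m", "y",
               family_m = "continuous", family_y = "continuous",
               n_draws = 500, seed = 3)
  expect_lte(r$acme_ci[1], 0)
  expect_gte(r$acme_ci[2], 0)
  expect_lt(abs(r$acme), 0.05)
})

test_that("mediation results are reproducible under a fixed seed", {
  set.seed(14)
  n <- 200
  d <- tibble::tibble(x = rbinom(n, 1, 0.5))
  d$m <- 0.4 * d$x + rnorm(n)
  d$y <- rbinom(n, 1, plogis(0.6 * d$m))
  r1 <- mediate(d, "x", "m", "y", n_draws = 300, seed = 7)
  r2 <- mediate(d, "x", "m", "y", n_draws = 300, seed = 7)
  expect_identical(tidy(r1), tidy(r2))
  expect_error(
    mediate(dplyr::mutate(d, x = 1), "x", "m", "y", n_draws = 300),
    class = "epimediate_data_error")
})

test_that("tidy/glance/autoplot expose the decomposition", {
  set.seed(15)
  d <- tibble::tibble(x = rbinom(150, 1, 0.5))
  d$m <- 0.5 * d$x + rnorm(150)
  d$y <- 0.5 * d$m + rnorm(150)
  r <- mediate(d, "x", "m", "y", family_y = "continuous", n_draws = 200,
               seed = 1)
  td <- tidy(r)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high",
                     "p.value"))
  expect_equal(td$term, c("acme", "ade", "total", "prop_mediated"))
  expect_s3_class(glance(r), "tbl_df")
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("BH adjustment matches hand-worked cases and preserves order", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(0, 5)), rep(0, 5))
  p <- c(0.9, 0.001, 0.5, 0.02)
  q <- adjust_fdr(p)
  expect_equal(order(q), order(p))
  expect_error(adjust_fdr(c(0.5, 1.2)), class = "epimediate_data_error")
  expect_error(adjust_fdr(c(0.5, -0.1)), class = "epimediate_data_error")
})
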