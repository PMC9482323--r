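test_that("marginal scan preserves CpG order and finds planted paths", {
  st <- small_study(seed = 21)
  sc <- marginal_scan(st$cohort, st$methylation_baseline, "prs",
                      outcome = "sensitized_followup",
                      covariates_em = "sex",
                      covariates_mo = c("sex", "bmi"))
  expect_identical(sc$marker, st$methylation_baseline$cpg_id)
  expect_lt(sc$p_alpha[3], 1e-10)   # planted a = 0.6 on cg000003
  expect_lt(sc$p_beta[3], 0.05)
})

test_that("reverse-direction scan shares p_alpha and varies p_beta", {
  st <- small_study(seed = 22)
  sc <- marginal_scan(st$cohort, st$methylation_followup,
                      "family_history", mediator = "sensitized_baseline",
                      covariates_em = c("ses", "no2"),
                      covariates_mo = c("sex", "bmi"), direction = "h2")
  expect_equal(length(unique(sc$p_alpha)), 1L)
  expect_gt(length(unique(sc$p_beta)), 1L)
  expect_lt(sc$p_beta[7], 1e-4)  # planted d = 0.6 on cg000007
})

test_that("DACT reduces exactly to each pure composite-null case", {
  set.seed(23)
  scan <- tibble::tibble(marker = sprintf("m%d", 1:5),
                         p_alpha = runif(5), p_beta = runif(5))
  expect_equal(dact(scan, calibrate = FALSE,
                    weights = c(1, 0, 0))$p_dact, scan$p_alpha)
  expect_equal(dact(scan, calibrate = FALSE,
                    weights = c(0, 1, 0))$p_dact, scan$p_beta)
  expect_equal(dact(scan, calibrate = FALSE,
                    weights = c(0, 0, 1))$p_dact,
               pmax(scan$p_alpha, scan$p_beta)^2)
  # mixed weights: hand-computed aggregation
  w <- c(0.2, 0.3, 0.5)
  expect_equal(dact(scan, calibrate = FALSE, weights = w)$p_dact,
               0.2 * scan$p_alpha + 0.3 * scan$p_beta +
                 0.5 * pmax(scan$p_alpha, scan$p_beta)^2)
})

test_that("DACT warns and skips calibration below 100 markers", {
  set.seed(24)
  scan <- tibble::tibble(marker = sprintf("m%d", 1:20),
                         p_alpha = runif(20), p_beta = runif(20))
  expect_warning(d <- dact(scan, calibrate = TRUE), "100 markers")
  expect_equal(d$p_calibrated, d$p_dact)
})

test_that("empirical-null calibration recovers a shifted null", {
  set.seed(25)
  # z-scores drawn from N(0.3, 1.2): the empirical null should absorb both
  z <- rnorm(5000, 0.3, 1.2)
  fitted <- epimediate:::efron_null(z)
  expect_lt(abs(fitted[["mean"]] - 0.3), 0.1)
  expect_lt(abs(fitted[["sd"]] - 1.2), 0.1)
})

test_that("screening cap follows the 2n/ln(n) law", {
  expect_equal(screening_cap(215), 80L)
  expect_equal(screening_cap(154), 61L)
  expect_equal(screening_cap(100, multiplier = 3), 65L)
  st <- small_study(seed = 26, n = 300, cpgs = 30)
  sc <- sis_screen(st$cohort, st$methylation_baseline,
                   "sensitized_followup", c("prs", "sex"))
  expect_equal(nrow(sc), 30L)  # cap (105) not binding
})

test_that("screening ranking equals the brute-force coefficient sort", {
  st <- small_study(seed = 27, n = 250, cpgs = 50)
  co <- st$cohort
  me <- st$methylation_baseline
  sc <- sis_screen(co, me, "sensitized_followup", c("prs", "sex"),
                   family = "binary")
  M <- scale(epimediate:::meth_matrix(me))
  ests <- vapply(seq_len(ncol(M)), function(j) {
    coef(glm(co$sensitized_followup ~ M[, j] + co$prs + co$sex,
             family = binomial()))[2]
  }, numeric(1))
  names(ests) <- colnames(M)
  oracle <- names(sort(-abs(ests)))[seq_len(nrow(sc))]
  expect_identical(sc$marker, oracle)
})

test_that("MCP at zero penalty equals unpenalized least squares", {
  set.seed(28)
  n <- 100
  M <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("m", 1:5)))
  y <- M %*% c(1, -0.5, 0, 0.3, 0) + rnorm(n)
  sel <- mcp_select(M, as.numeric(y), family = "continuous", lambda = 0)
  ols <- coef(lm(y ~ M))
  expect_equal(unname(sel$coefficients[paste0("m", 1:5)]),
               unname(ols[-1]), tolerance = 1e-6)
})

test_that("a large enough penalty shrinks every mediator to zero", {
  set.seed(29)
  M <- matrix(rnorm(300), 60, dimnames = list(NULL, paste0("m", 1:5)))
  y <- rnorm(60)
  sel <- mcp_select(M, y, family = "continuous", lambda = 10)
  expect_length(sel$selected, 0)
})

test_that("orthonormal-design MCP equals the firm-threshold closed form", {
  set.seed(30)
  n <- 64
  # orthonormal columns, also orthogonal to the (unpenalized) intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 8), n))))[, -1] * sqrt(n)
  colnames(Q) <- paste0("m", 1:8)
  beta0 <- c(2, -1.5, 0.8, 0.4, 0.2, 0, 0, 0)
  y <- as.numeric(Q %*% beta0 + rnorm(n, sd = 0.5))
  gamma <- 3
  for (lam in c(0.1, 0.3, 0.6)) {
    sel <- mcp_select(Q, y, family = "continuous", gamma = gamma,
                      lambda = lam, standardize = FALSE)
    z <- as.numeric(crossprod(Q, y - mean(y)) / n)
    # closed form on the centred response (intercept is unpenalized)
    firm <- ifelse(abs(z) <= lam, 0,
                   ifelse(abs(z) <= gamma * lam,
                          sign(z) * (abs(z) - lam) / (1 - 1 / gamma), z))
    expect_equal(unname(sel$coefficients[paste0("m", 1:8)]), firm,
                 tolerance = 1e-4)
  }
})

test_that("joint significance takes the maximum path p-value with BH", {
  scan <- tibble::tibble(marker = c("a", "b", "c"),
                         p_alpha = c(0.001, 0.5, 0.2),
                         p_beta = c(0.04, 0.001, 0.01))
  js <- joint_significance(c("a", "b", "c"), scan)
  expect_equal(js$p_joint, c(0.04, 0.5, 0.2))
  expect_true(all(js$p_joint[2] >= 0.5))
  expect_equal(js$p_adjusted, bh_oracle(js$p_joint))
  empty <- joint_significance(character(0), scan)
  expect_equal(nrow(empty), 0L)
  expect_error(joint_significance("zzz", scan),
               class = "epimediate_data_error")
})

test_that("the three-step search recovers a strongly planted mediator", {
  st <- small_study(seed = 31, n = 400, cpgs = 200,
                    h1 = plant_h1(5, a = 0.6, b = 1.5, exposure = "prs"),
                    h2 = plant_h2())
  h <- hima(st$cohort, st$methylation_baseline, "prs",
            "sensitized_followup", covariates_em = "sex",
            covariates_mo = c("sex", "bmi"))
  expect_true("cg000005" %in% h$selected)
  expect_true("cg000005" %in% h$significant)
  expect_true(all(h$selected %in% h$screened$marker))
  expect_lte(nrow(h$screened), screening_cap(400))
})
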