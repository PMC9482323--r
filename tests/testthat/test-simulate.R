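test_that("cohort marginals match the configured prevalences", {
  cfg <- sim_config(n_samples = 10000, n_cpgs = 5, seed = 1)
  co <- simulate_cohort(cfg)
  expect_gte(mean(co$maternal_smoking), 0.065)
  expect_lte(mean(co$maternal_smoking), 0.085)
  expect_lt(abs(mean(co$family_history) - 0.645), 0.02)
  expect_lt(abs(mean(co$sex) - 0.577), 0.02)
  expect_lt(abs(mean(co$sensitized_baseline) - 0.316), 0.02)
  # follow-up prevalence exceeds baseline, as in the cohort being emulated
  expect_gt(mean(co$sensitized_followup), mean(co$sensitized_baseline))
})

test_that("cohort invariants hold: simplex cells, increasing ages, ids", {
  co <- simulate_cohort(sim_config(n_samples = 500, n_cpgs = 5, seed = 2))
  cells <- as.matrix(co[, grep("^cell_", names(co))])
  expect_true(all(abs(rowSums(cells) - 1) < 1e-9))
  expect_true(all(cells >= 0))
  expect_true(all(co$age_followup > co$age_baseline))
  expect_false(anyDuplicated(co$sample_id) > 0)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 150, n_cpgs = 40, n_snps = 30, seed = 9,
                    planted_h1 = plant_h1(1, 0.4, 0.5))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$methylation_baseline, s2$methylation_baseline)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$weight_tables, s2$weight_tables)
})

test_that("phenotype draws do not depend on the number of CpGs", {
  a <- simulate_cohort(sim_config(n_samples = 100, n_cpgs = 10, seed = 4))
  b <- simulate_cohort(sim_config(n_samples = 100, n_cpgs = 500, seed = 4))
  expect_identical(a, b)
})

test_that("betas lie strictly in (0,1) and planted slopes are recovered", {
  cfg <- sim_config(n_samples = 2000, n_cpgs = 50, seed = 5,
                    noise_sd = 0.1,
                    planted_h1 = plant_h1(2, a = 0.5, b = 0))
  co <- simulate_cohort(cfg)
  me <- simulate_methylation(co, cfg, "baseline")
  beta <- as.matrix(me[, grep("^S", names(me))])
  expect_true(all(beta > 0 & beta < 1))
  m_planted <- qlogis(as.numeric(beta[2, ]))
  fit <- summary(lm(m_planted ~ co$maternal_smoking))
  est <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(est - 0.5), 3 * se)
})

test_that("zero planted effects give a null methylome: uniform scan p-values", {
  cfg <- sim_config(n_samples = 200, n_cpgs = 5000, seed = 6)
  co <- simulate_cohort(cfg)
  me <- simulate_methylation(co, cfg, "baseline")
  sc <- marginal_scan(co, me, "maternal_smoking",
                      outcome = "sensitized_followup")
  ks <- suppressWarnings(ks.test(sc$p_alpha, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("null confounder config leaves exposure and covariates independent", {
  cfg <- sim_config(n_samples = 5000, n_cpgs = 5, seed = 7)
  co <- simulate_cohort(cfg)
  for (v in c("bmi", "no2", "ses", "sex")) {
    expect_lt(abs(cor(co$maternal_smoking, co[[v]])), 0.04)
    expect_lt(abs(cor(co$sensitized_followup, co[[v]])), 0.04)
  }
})

test_that("configured confounders correlate with mediator and outcome", {
  cfg <- sim_config(
    n_samples = 3000, n_cpgs = 10, seed = 8,
    confounder_effects = list(ses = c(mediator = 0.5, outcome = 0.8)))
  co <- simulate_cohort(cfg)
  me <- simulate_methylation(co, cfg, "baseline")
  m1 <- qlogis(as.numeric(as.matrix(me[1, grep("^S", names(me))])))
  expect_gt(cor(m1, co$ses), 0.2)
  expect_gt(cor(co$sensitized_baseline, co$ses), 0.1)
})

test_that("genotype generator honours MAF, flags and determinism", {
  cfg <- sim_config(n_samples = 800, n_cpgs = 5, n_snps = 200, seed = 10)
  g <- simulate_genotypes(cfg)
  expect_identical(g, simulate_genotypes(cfg))
  dose <- as.matrix(g$genotypes[, grep("^S", names(g$genotypes))])
  expect_true(all(dose >= 0 & dose <= 2))
  # binomial mean 2*maf per SNP
  err <- abs(rowMeans(dose) - 2 * g$genotypes$maf)
  expect_lt(max(err / sqrt(2 * g$genotypes$maf * (1 - g$genotypes$maf) /
                             800) - 4), Inf)
  expect_lt(mean(err), 0.05)
  expect_equal(sum(g$genotypes$imputation_quality < 0.4), round(0.1 * 200))
  expect_equal(sum(g$genotypes$is_multiallelic), round(0.05 * 200))
  expect_equal(sum(g$genotypes$maf < 0.01), round(0.05 * 200))
})

test_that("configuration errors are raised for invalid settings", {
  expect_error(sim_config(n_samples = 0), class = "epimediate_config_error")
  expect_error(sim_config(baseline_rate = 1.2),
               class = "epimediate_config_error")
  expect_error(sim_config(noise_sd = -1),
               class = "epimediate_config_error")
  expect_error(sim_config(n_cpgs = 10, planted_h1 = plant_h1(11, 1, 1)),
               class = "epimediate_config_error")
  expect_error(
    sim_config(n_cpgs = 10, planted_h1 = plant_h1(c(2, 2), c(1, 1),
                                                  c(1, 1))),
    class = "epimediate_config_error")
})

test_that("truth record lists each planted CpG once with the a*b product", {
  cfg <- sim_config(n_cpgs = 20, seed = 3,
                    planted_h1 = plant_h1(c(1, 2), c(0.5, -0.2),
                                          c(0.4, 0.3)),
                    planted_h2 = plant_h2(5, 0.8, 0.6))
  tr <- simulate_truth(cfg)
  expect_equal(nrow(tr), 3)
  expect_false(anyDuplicated(tr$cpg_id) > 0)
  expect_equal(tr$true_indirect, tr$true_a * tr$true_b)
  expect_setequal(attr(tr, "null_indices"), setdiff(1:20, c(1, 2, 5)))
})
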