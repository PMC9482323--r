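test_that("CpGs map to genes by containment, window and tie rules", {
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(1000L, 5000L, 40000L),
                          end = c(2000L, 6000L, 41000L),
                          gene_id = c("G1", "G2", "G3"))
  cpgs <- tibble::tibble(
    cpg_id = c("in_body", "too_far", "near_g2"),
    chrom = "chr1",
    pos = c(1500L, 66001L, 7000L))
  m <- map_cpgs_to_genes(cpgs, genes, window = 20000)
  expect_equal(m$gene_id[m$cpg_id == "in_body"], "G1")
  expect_equal(m$distance[m$cpg_id == "in_body"], 0)
  expect_false("too_far" %in% m$cpg_id)  # 25,001 bp from G3
  expect_equal(m$gene_id[m$cpg_id == "near_g2"], "G2")
})

test_that("mapping equals the exhaustive all-pairs distance oracle", {
  set.seed(41)
  genes <- tibble::tibble(chrom = "chr1",
                          start = sort(sample.int(50000, 3)),
                          end = 0L, gene_id = c("GA", "GB", "GC"))
  genes$end <- genes$start + sample(2000:8000, 3)
  cpgs <- tibble::tibble(cpg_id = sprintf("c%02d", 1:10), chrom = "chr1",
                         pos = sample.int(60000, 10))
  m <- map_cpgs_to_genes(cpgs, genes, window = 20000)
  # oracle: scan every pair
  for (i in seq_len(nrow(cpgs))) {
    d <- pmax(0, genes$start + 1 - cpgs$pos[i], cpgs$pos[i] - genes$end)
    best <- min(d)
    row <- m[m$cpg_id == cpgs$cpg_id[i], ]
    if (best > 20000) {
      expect_equal(nrow(row), 0L)
    } else {
      cand <- which(d == best)
      pick <- cand[order(genes$start[cand], genes$gene_id[cand])][1]
      expect_equal(row$gene_id, genes$gene_id[pick])
      expect_equal(row$distance, best)
    }
  }
})

test_that("BED round trip preserves the annotation and flags bad lines", {
  genes <- simulate_gene_annotation(sim_config(n_cpgs = 200, seed = 42))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(genes, path)
  back <- read_bed(path)
  expect_equal(back, genes[, c("chrom", "start", "end", "gene_id")])
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tG1", "chr1\toops\t30\tG2"), bad)
  expect_error(read_bed(bad), "line 2", class = "epimediate_data_error")
})

test_that("a single-CpG gene reduces to the single-mediator joint test", {
  st <- small_study(seed = 43, n = 250, cpgs = 40)
  co <- st$cohort
  M <- epimediate:::meth_matrix(st$methylation_baseline)
  one <- M[, "cg000009", drop = FALSE]
  r <- ghma(co, one, "maternal_smoking", "sensitized_followup",
            covariates_em = "ses", covariates_mo = c("sex", "bmi"),
            kernel_threshold = 0.8)
  expect_equal(r$n_pcs_linear, 1L)
  df <- dplyr::mutate(co, m = as.numeric(scale(one)))
  p1 <- anova(lm(cbind(m) ~ ses + maternal_smoking,
                 data = df))["maternal_smoking", "Pr(>F)"]
  full <- glm(sensitized_followup ~ m + maternal_smoking + sex + bmi,
              binomial(), df)
  red <- glm(sensitized_followup ~ maternal_smoking + sex + bmi,
             binomial(), df)
  p2 <- pchisq(red$deviance - full$deviance, 1, lower.tail = FALSE)
  expect_lt(abs(r$p_linear - max(p1, p2)), 1e-9)
})

test_that("higher variance thresholds retain at least as many components", {
  st <- small_study(seed = 44, n = 200, cpgs = 60)
  M <- epimediate:::meth_matrix(st$methylation_baseline)
  B <- M[, 1:12]
  lo <- ghma(st$cohort, B, "prs", "sensitized_followup", "sex",
             c("sex", "bmi"), kernel_threshold = 0.7)
  hi <- ghma(st$cohort, B, "prs", "sensitized_followup", "sex",
             c("sex", "bmi"), kernel_threshold = 0.9)
  expect_gte(hi$n_pcs_linear, lo$n_pcs_linear)
  expect_gte(hi$n_pcs_nonlinear, lo$n_pcs_nonlinear)
  expect_true(all(c(lo$p_omnibus, hi$p_omnibus) >= 0 &
                    c(lo$p_omnibus, hi$p_omnibus) <= 1))
})

test_that("degenerate gene blocks raise errors", {
  st <- small_study(seed = 45, n = 50, cpgs = 10)
  B <- matrix(0.5, nrow = 50, ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_error(
    ghma(st$cohort, B, "prs", "sensitized_followup"),
    class = "epimediate_data_error")
})

test_that("gene-level scan adjusts omnibus p-values across genes", {
  st <- small_study(seed = 46, n = 250, cpgs = 150)
  gm <- map_cpgs_to_genes(
    st$methylation_baseline[, c("cpg_id", "chrom", "pos")],
    st$annotation)
  g <- ghma_scan(st$cohort, st$methylation_baseline, gm, "prs",
                 "sensitized_followup", covariates_em = "sex",
                 covariates_mo = c("sex", "bmi"))
  expect_true(all(c("gene_id", "p_linear", "p_nonlinear", "p_omnibus",
                    "p_adjusted") %in% names(g)))
  expect_equal(g$p_adjusted, bh_oracle(g$p_omnibus))
})
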