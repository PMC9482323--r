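test_that("pruning keeps the better-powered of two identical markers", {
  v <- matrix(rnorm(40), nrow = 2, byrow = TRUE)
  v[2, ] <- v[1, ]  # perfectly correlated pair
  rownames(v) <- c("a", "b")
  w <- tibble::tibble(marker_id = c("a", "b"), effect = c(1, 1),
                      p = c(0.001, 0.01))
  expect_identical(prune_markers(w, v, 0.7), "a")
})

test_that("uncorrelated markers all survive pruning, which is idempotent", {
  set.seed(1)
  v <- matrix(rnorm(20 * 200), nrow = 20)
  rownames(v) <- sprintf("m%02d", 1:20)
  w <- tibble::tibble(marker_id = rownames(v), effect = 1,
                      p = runif(20))
  kept <- prune_markers(w, v, 0.7)
  expect_setequal(kept, rownames(v))
  again <- prune_markers(w[match(kept, w$marker_id), ],
                         v[kept, , drop = FALSE], 0.7)
  expect_identical(again, kept)
})

test_that("pruning equals the exhaustive greedy oracle on block designs", {
  for (seed in 1:5) {
    set.seed(seed)
    base <- matrix(rnorm(4 * 60), nrow = 4)
    # 20 markers in 4 correlated blocks plus noise
    v <- base[rep(1:4, each = 5), ] + matrix(rnorm(20 * 60, sd = 0.4),
                                             nrow = 20)
    rownames(v) <- sprintf("m%02d", 1:20)
    w <- tibble::tibble(marker_id = rownames(v), effect = 1,
                        p = runif(20))
    expect_identical(prune_markers(w, v, 0.7), prune_oracle(w, v, 0.7))
  }
})

test_that("zero-variance markers are excluded with a warning", {
  v <- rbind(a = rnorm(30), b = rep(1, 30))
  w <- tibble::tibble(marker_id = c("a", "b"), effect = 1,
                      p = c(0.5, 0.001))
  expect_warning(kept <- prune_markers(w, v, 0.7), "zero-variance")
  expect_identical(kept, "a")
})

test_that("single-CpG score is the forced affine map of its betas", {
  me <- toy_methylation(matrix(c(0.2, 0.4, 0.6), nrow = 1))
  w <- tibble::tibble(marker_id = "cg01", effect = 1, p = 0.001)
  s <- compute_mrs(me, w)
  expect_equal(s$raw_score, c(0.2, 0.4, 0.6))
  expect_equal(s$z_score, c(-1, 0, 1))
  # negating the weights exactly negates the z-scores
  w2 <- dplyr::mutate(w, effect = -effect)
  expect_equal(compute_mrs(me, w2)$z_score, -s$z_score)
})

test_that("scores equal hand-computed dot products and are linear in weights", {
  set.seed(3)
  beta <- matrix(runif(12, 0.1, 0.9), nrow = 3)
  me <- toy_methylation(beta)
  w1 <- tibble::tibble(marker_id = sprintf("cg%02d", 1:3),
                       effect = c(0.5, -1, 2), p = c(0.01, 0.02, 0.03))
  w2 <- dplyr::mutate(w1, effect = c(1, 0.3, -0.7))
  s1 <- compute_mrs(me, w1)
  expect_equal(s1$raw_score, as.numeric(crossprod(beta, w1$effect)))
  s2 <- compute_mrs(me, w2)
  s12 <- compute_mrs(me, dplyr::mutate(w1, effect = w1$effect + w2$effect))
  expect_equal(s12$raw_score, s1$raw_score + s2$raw_score)
  # z-normalization invariant
  expect_lt(abs(mean(s1$z_score)), 1e-9)
  expect_lt(abs(sd(s1$z_score) - 1), 1e-9)
})

test_that("thresholding is monotone and missing markers are skipped", {
  set.seed(4)
  beta <- matrix(runif(40, 0.2, 0.8), nrow = 5)
  me <- toy_methylation(beta)
  w <- tibble::tibble(marker_id = c(sprintf("cg%02d", 1:5), "cg99"),
                      effect = rnorm(6), p = c(1e-6, 1e-4, 0.005, 0.04,
                                               0.5, 1e-9))
  used <- vapply(c(1e-5, 1e-3, 0.01, 0.05, 1),
                 function(th) compute_mrs(me, w, th)$n_markers_used[1],
                 numeric(1))
  expect_true(all(diff(used) >= 0))
  # cg99 is never scored (absent from the matrix), lowest p notwithstanding
  expect_equal(max(used), 5)
  expect_equal(attr(compute_mrs(me, w, 1), "n_missing"), 1L)
  expect_error(compute_mrs(me, w, 1e-12),
               class = "epimediate_empty_score")
})

test_that("PRS filters exclude rare, low-quality and multiallelic SNPs", {
  dose <- rbind(c(0, 1, 2, 1, 0, 2), c(2, 1, 0, 1, 2, 0),
                c(1, 1, 1, 2, 0, 1), c(0, 0, 1, 1, 2, 2))
  geno <- dplyr::bind_cols(
    tibble::tibble(snp_id = sprintf("rs%d", 1:4),
                   maf = c(0.3, 0.2, 0.005, 0.4),
                   imputation_quality = c(0.9, 0.95, 0.99, 0.2),
                   is_multiallelic = c(FALSE, FALSE, FALSE, FALSE)),
    tibble::as_tibble(matrix(dose, nrow = 4,
                             dimnames = list(NULL,
                                             sprintf("S%02d", 1:6)))))
  w <- tibble::tibble(marker_id = sprintf("rs%d", 1:4),
                      effect = c(0.1, -0.2, 5, 5), p = rep(0.01, 4))
  s <- compute_prs(geno, w, prune = FALSE)
  # rs3 fails MAF < 1%, rs4 fails quality < 0.4 however large the effects
  expect_equal(s$n_markers_used[1], 2)
  expect_equal(s$raw_score[1:3], c(0 * 0.1 + 2 * -0.2,
                                   1 * 0.1 + 1 * -0.2,
                                   2 * 0.1 + 0 * -0.2))
  expect_error(compute_prs(geno, dplyr::mutate(w, effect = 0)),
               class = "epimediate_empty_score")
})

test_that("AUC equals the rank-sum oracle and drives MRS selection", {
  set.seed(5)
  score <- rnorm(8)
  outcome <- c(1, 0, 1, 1, 0, 0, 1, 0)
  u <- wilcox.test(score[outcome == 1], score[outcome == 0],
                   exact = TRUE)$statistic
  expect_equal(compute_auc(score, outcome), unname(u) / (4 * 4))

  perfect <- tibble::tibble(sample_id = sprintf("S%d", 1:8),
                            raw_score = outcome, z_score = zscore_(outcome),
                            n_markers_used = 3, p_threshold_used = 0.05)
  noise <- dplyr::mutate(perfect, z_score = rnorm(8), n_markers_used = 9)
  sel <- select_best_mrs(list(good = perfect, bad = noise), outcome)
  expect_identical(sel$threshold, "good")
  expect_equal(sel$auc, 1)
  # singleton candidate is returned as-is
  one <- select_best_mrs(list(only = noise), outcome)
  expect_identical(one$threshold, "only")
  expect_error(select_best_mrs(list(a = perfect), rep(1, 8)),
               class = "epimediate_data_error")
})

test_that("AUC ties break towards the sparser score", {
  s <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                      raw_score = 1:6, z_score = zscore_(1:6),
                      n_markers_used = 10, p_threshold_used = 1)
  sparse <- dplyr::mutate(s, n_markers_used = 2)
  sel <- select_best_mrs(list(dense = s, sparse = sparse),
                         c(0, 0, 0, 1, 1, 1))
  expect_identical(sel$threshold, "sparse")
})
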