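# shared fixture builders; everything is generated in code at test time

small_study <- function(seed = 42, n = 300, cpgs = 120,
                        h1 = plant_h1(3, a = 0.6, b = 1.2,
                                      exposure = "prs"),
                        h2 = plant_h2(7, c = 1.0, d = 0.6,
                                      exposure = "family_history")) {
  cfg <- sim_config(n_samples = n, n_cpgs = cpgs, n_snps = 60,
                    planted_h1 = h1, planted_h2 = h2, seed = seed)
  simulate_study(cfg)
}

# tiny methylation tibble built by hand: markers x samples
toy_methylation <- function(beta, ids = sprintf("cg%02d", seq_len(nrow(beta))),
                            pos = seq_len(nrow(beta)) * 100L) {
  samples <- sprintf("S%02d", seq_len(ncol(beta)))
  colnames(beta) <- samples
  dplyr::bind_cols(
    tibble::tibble(cpg_id = ids, chrom = "chr1", pos = pos),
    tibble::as_tibble(beta)
  )
}

zscore_ <- function(x) (x - mean(x)) / sd(x)

# brute-force step-up BH, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# brute-force greedy pruning over the full correlation matrix
prune_oracle <- function(weights, values, r2) {
  ord <- weights$marker_id[order(weights$p)]
  kept <- character(0)
  for (m in ord) {
    ok <- TRUE
    for (k in kept) {
      if (cor(values[m, ], values[k, ])^2 > r2) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, m)
  }
  kept
}
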