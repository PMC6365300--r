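# Small in-code fixtures shared across test files.

# deterministic 3 x 4 genotype set with one NA
tiny_geno <- function() {
  genotype_data(
    codes = rbind(c(0, 1, 2, 0),
                  c(2, NA, 0, 2),
                  c(1, 1, 1, 2)),
    map = data.frame(marker_id = c("m1", "m2", "m3"),
                     chromosome = c("1", "1", "2"),
                     position = c(100L, 2000L, 500L)),
    individual_ids = c("A", "B", "C", "D"))
}

# seeded random genotype set without missing data
rand_geno <- function(n = 50, m = 30, seed = 42, maf = c(0.1, 0.5)) {
  simulate_genotypes(n_individuals = n, n_markers = m, n_chromosomes = 3L,
                     chrom_length_bp = 1e6, maf_range = maf, seed = seed)
}

# independent per-marker OLS oracle: lm() refit of
# y ~ covariates + pseudo-QTNs + marker, dropping the marker's own pseudo-QTN
oracle_scan <- function(geno, y, covariates = NULL, pseudo_qtns = integer(0)) {
  G <- blinkr::impute_missing(geno, "mean")
  n <- length(y)
  if (is.null(covariates)) covariates <- matrix(0, n, 0L)
  out <- data.frame(effect = rep(NA_real_, nrow(G)), p = NA_real_)
  for (j in seq_len(nrow(G))) {
    keep <- pseudo_qtns
    for (q in pseudo_qtns) {
      r <- suppressWarnings(stats::cor(G[j, ], G[q, ]))
      if (!is.na(r) && abs(r) >= 1 - 1e-12) keep <- setdiff(keep, q)
    }
    if (stats::sd(G[j, ]) == 0) next
    X <- cbind(covariates, t(G[keep, , drop = FALSE]), g = G[j, ])
    df <- as.data.frame(X)
    names(df)[ncol(df)] <- "g"
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    if (!"g" %in% rownames(sm)) next
    out$effect[j] <- sm["g", 1]
    out$p[j] <- sm["g", 4]
  }
  out
}

# independent greedy LD pruning written as a literal translation of the rule
oracle_prune <- function(candidates, geno, beta) {
  G <- blinkr::impute_missing(geno, "mean")
  remaining <- candidates
  kept <- integer(0)
  while (length(remaining) > 0L) {
    head_idx <- remaining[1L]
    kept <- c(kept, head_idx)
    remaining <- remaining[-1L]
    if (length(remaining)) {
      drop <- vapply(remaining, function(j) {
        r <- suppressWarnings(stats::cor(G[head_idx, ], G[j, ]))
        !is.na(r) && abs(r) > beta
      }, logical(1))
      remaining <- remaining[!drop]
    }
  }
  kept
}
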