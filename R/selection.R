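# Pseudo-QTN selection: P-value sort + Bonferroni threshold, greedy LD
# pruning on |Pearson r|, then nested-model information-criterion search
# over the first k candidates.

#' Bonferroni candidate filter
#'
#' Markers with a defined P value at or below `alpha / M` are returned,
#' sorted ascending by P value (ties broken by chromosome, position,
#' marker id). An empty result is valid: it means no candidates.
#'
#' @param scan a `blink_scan` data.frame from [scan_markers()].
#' @param alpha genome-wide significance level (default 0.01).
#' @param M number of tests for the Bonferroni correction; defaults to the
#'   number of scanned markers.
#' @return integer vector of marker row indices into the scan, most
#'   significant first.
#' @export
candidate_filter <- function(scan, alpha = 0.01, M = nrow(scan)) {
  stopifnot(nrow(scan) > 0L, alpha > 0, alpha < 1)
  cutoff <- alpha / M
  idx <- which(!is.na(scan$p) & scan$p <= cutoff)
  if (!length(idx)) return(integer(0))
  idx[order(scan$p[idx], scan$chromosome[idx], scan$position[idx],
            scan$marker_id[idx])]
}

#' Pearson correlation between two genotype vectors
#'
#' @param x,y equal-length numeric vectors (mean-imputed genotype codes).
#' @return sample Pearson correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Greedy linkage-disequilibrium pruning
#'
#' Keeps the most significant candidate, removes every later candidate
#' whose absolute Pearson correlation with it exceeds `beta`, then repeats
#' on the remainder. The output preserves significance order and contains
#' no pair with |r| > beta.
#'
#' @param candidates integer marker indices sorted most significant first.
#' @param geno [genotype_data] (LD computed on mean-imputed codes over the
#'   full analyzed sample).
#' @param beta LD threshold on |r|, in (0, 1\]; default 0.7.
#' @return pruned integer vector, significance order preserved.
#' @export
ld_prune <- function(candidates, geno, beta = 0.7) {
  stopifnot(beta > 0, beta <= 1)
  candidates <- as.integer(candidates)
  if (length(candidates) <= 1L) return(candidates)
  G <- .impute_rows(geno$codes[candidates, , drop = FALSE])  # candidate order
  keep <- logical(length(candidates))
  alive <- rep(TRUE, length(candidates))
  sds <- apply(G, 1L, stats::sd)
  for (i in seq_along(candidates)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    later <- which(alive & seq_along(candidates) > i)
    for (j in later) {
      r <- if (sds[i] == 0 || sds[j] == 0) 0 else stats::cor(G[i, ], G[j, ])
      if (abs(r) > beta) alive[j] <- FALSE
    }
  }
  candidates[keep]
}

#' Information criterion for a fitted covariates-only model
#'
#' The default criterion is the package's Bayesian information criterion
#' with penalty `bic_penalty_factor * k * ln(n)` where k counts pseudo-QTNs
#' only (never the intercept or common covariates); the default penalty
#' factor is 2. `bic_penalty_factor = 1` gives the textbook BIC penalty.
#' AIC is -2LL + 2k; eBIC adds `2 * gamma * ln(choose(M, k))` to the BIC
#' for a predictor space of M markers.
#'
#' @param fit a `fem_fit` from [fit_fem()] (its `k` is the pseudo-QTN count).
#' @param criterion `"BIC"`, `"AIC"` or `"eBIC"`.
#' @param M total scanned markers (predictor-space size, eBIC only).
#' @param gamma eBIC weight in \[0, 1\], default 0.5.
#' @param bic_penalty_factor multiplier on k*ln(n) in the BIC penalty.
#' @return criterion value (smaller is better).
#' @export
information_criterion <- function(fit, criterion = c("BIC", "AIC", "eBIC"),
                                  M = NULL, gamma = 0.5,
                                  bic_penalty_factor = 2) {
  criterion <- match.arg(criterion)
  k <- fit$k; n <- fit$n; n2ll <- fit$neg2_log_likelihood
  bic <- n2ll + bic_penalty_factor * k * log(n)
  switch(criterion,
         BIC = bic,
         AIC = n2ll + 2 * k,
         eBIC = {
           if (is.null(M)) stop("eBIC needs M, the predictor-space size")
           if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
           if (k > M) stop("k (", k, ") exceeds M (", M, ") under eBIC")
           bic + 2 * gamma * lchoose(M, k)
         })
}

#' Choose the pseudo-QTN set size by nested model selection
#'
#' Fits the covariates-only model with the first k candidates for
#' k = 0..t (k = 0 is the intercept+covariates baseline, so a spurious set
#' can be discarded entirely), records the (k, -2LL, criterion) trace, and
#' returns the k minimizing the criterion; ties go to the smaller k.
#' Candidates are capped at `n - c - 2` so every fit keeps positive
#' residual degrees of freedom.
#'
#' @param candidates integer marker indices, LD-pruned, most significant
#'   first.
#' @param y numeric phenotype vector.
#' @param covariates numeric matrix (0 columns for none).
#' @param geno [genotype_data].
#' @param criterion,M,gamma,bic_penalty_factor see [information_criterion()];
#'   `M` defaults to the number of markers in `geno`.
#' @param source_p optional P values of the candidates (stored for
#'   provenance).
#' @return list of class `pseudo_qtn_set`: `marker_indices` (the chosen
#'   first k), `chosen_k`, `criterion`, `criterion_trace` (data.frame k,
#'   neg2LL, criterion), `source_p_values`, `candidates` (post-cap).
#' @export
select_pseudo_qtns <- function(candidates, y, covariates = NULL, geno,
                               criterion = "BIC", M = n_markers(geno),
                               gamma = 0.5, bic_penalty_factor = 2,
                               source_p = NULL) {
  n <- length(y)
  if (is.null(covariates)) covariates <- matrix(0, n, 0L)
  covariates <- as.matrix(covariates)
  cap <- n - ncol(covariates) - 2L
  if (length(candidates) > cap) {
    warning("capping pseudo-QTN candidates at ", cap,
            " (was ", length(candidates), ") to keep residual df positive")
    candidates <- candidates[seq_len(cap)]
    if (!is.null(source_p)) source_p <- source_p[seq_len(cap)]
  }
  t_n <- length(candidates)
  Gc <- if (t_n) {
    .impute_rows(geno$codes[candidates, , drop = FALSE])
  } else matrix(0, 0L, n)
  W0 <- cbind(1, covariates)
  ks <- integer(0); n2lls <- numeric(0); crits <- numeric(0); skipped <- integer(0)
  for (k in 0:t_n) {
    X <- if (k == 0L) W0 else cbind(W0, t(Gc[seq_len(k), , drop = FALSE]))
    fit <- tryCatch(fit_fem(y, X, n_pseudo_qtns = k), error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, k); next }
    ks <- c(ks, k)
    n2lls <- c(n2lls, fit$neg2_log_likelihood)
    crits <- c(crits, information_criterion(fit, criterion, M = M,
                                            gamma = gamma,
                                            bic_penalty_factor = bic_penalty_factor))
  }
  if (length(skipped))
    warning("skipped degenerate model size(s) k = ",
            paste(skipped, collapse = ", "))
  best <- ks[which.min(crits)]   # which.min takes the first (smallest k) tie
  structure(list(marker_indices = candidates[seq_len(best)],
                 chosen_k = best,
                 criterion = criterion,
                 criterion_trace = data.frame(k = ks, neg2LL = n2lls,
                                              criterion = crits),
                 source_p_values = source_p,
                 candidates = candidates),
            class = "pseudo_qtn_set")
}

#' @export
print.pseudo_qtn_set <- function(x, ...) {
  cat("pseudo-QTN set:", x$chosen_k, "of", length(x$candidates),
      "candidates chosen by", x$criterion, "\n")
  if (x$chosen_k > 0)
    cat("  marker rows:", paste(x$marker_indices, collapse = ", "), "\n")
  invisible(x)
}
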