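# The iterative engine: scan -> Bonferroni filter -> LD prune -> BIC size
# selection, repeated until the pseudo-QTN set is stable (or a cycle /
# iteration cap is hit). Iteration 1 always runs with an empty pseudo-QTN
# set, i.e. a plain covariates-only GLM scan.

#' Configuration for a BLINK run
#'
#' All tunables live here; no other function hard-codes a default.
#'
#' @param maf_threshold markers with MAF at or below this are removed
#'   before scanning (default 0.05).
#' @param alpha genome-wide significance level for the Bonferroni candidate
#'   cut and the final significance call (default 0.01).
#' @param ld_threshold LD pruning cut on |Pearson r|, in (0, 1\]
#'   (default 0.7).
#' @param criterion model-size criterion: `"BIC"`, `"AIC"` or `"eBIC"`.
#' @param bic_penalty_factor multiplier on k*ln(n) in the BIC penalty
#'   (default 2; 1 gives the textbook penalty).
#' @param ebic_gamma eBIC weight (default 0.5).
#' @param max_iterations iteration cap (default 10).
#' @param bin_sizes_bp bin widths used by the evaluation helpers.
#' @param seed optional integer seed echoed into outputs.
#' @return list of class `blink_config`.
#' @export
blink_config <- function(maf_threshold = 0.05, alpha = 0.01,
                         ld_threshold = 0.7, criterion = c("BIC", "AIC", "eBIC"),
                         bic_penalty_factor = 2, ebic_gamma = 0.5,
                         max_iterations = 10L,
                         bin_sizes_bp = c(1L, 1000L, 10000L, 100000L),
                         seed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(maf_threshold >= 0, maf_threshold <= 0.5,
            alpha > 0, alpha < 1,
            ld_threshold > 0, ld_threshold <= 1,
            bic_penalty_factor > 0,
            ebic_gamma >= 0, ebic_gamma <= 1,
            max_iterations >= 1)
  structure(list(maf_threshold = maf_threshold, alpha = alpha,
                 ld_threshold = ld_threshold, criterion = criterion,
                 bic_penalty_factor = bic_penalty_factor,
                 ebic_gamma = ebic_gamma,
                 max_iterations = as.integer(max_iterations),
                 bin_sizes_bp = as.integer(bin_sizes_bp),
                 seed = seed),
            class = "blink_config")
}

#' Run the iterative pseudo-QTN scan on aligned inputs
#'
#' Lower-level engine behind [blink()]: inputs must already be aligned
#' (same individuals, no missing phenotype) and MAF-filtered. Each
#' iteration scans all markers with the current pseudo-QTN covariates,
#' filters candidates at the Bonferroni cut alpha/M, LD-prunes them, and
#' re-sizes the set by the information criterion. The run stops when two
#' consecutive sets are identical (converged), when a previously seen set
#' reappears (cycle; the best-criterion set seen is kept), or at the
#' iteration cap. The reported scan is recomputed under the final set, so
#' P values always correspond to the final model; pseudo-QTNs themselves
#' carry the P value of their own exclusion test.
#'
#' @param geno aligned, MAF-filtered [genotype_data].
#' @param y numeric phenotype vector (no NA), one value per individual.
#' @param covariates numeric matrix (0 columns for none).
#' @param config a [blink_config()].
#' @return list of class `blink_run`: `final_scan`, `pseudo_qtns` (final
#'   marker row indices), `iteration_history` (one record per iteration:
#'   `iteration`, `set` (a `pseudo_qtn_set`), `n_candidates`, `n_pruned`,
#'   `chosen_k`, `criterion_value`), `converged`, `stop_reason`
#'   (`"stable_set"`, `"max_iterations"` or `"cycle_detected"`),
#'   `n_iterations`, `config`.
#' @export
run_blink <- function(geno, y, covariates = NULL, config = blink_config()) {
  m <- n_markers(geno)
  n <- n_individuals(geno)
  if (is.null(covariates)) covariates <- matrix(0, n, 0L)
  covariates <- as.matrix(covariates)
  current <- integer(0)                      # iteration 1: empty set
  seen <- list("")                            # signatures of visited sets
  history <- list()
  stop_reason <- "max_iterations"
  converged <- FALSE
  best_sig <- ""; best_crit <- Inf; best_set <- integer(0)

  for (it in seq_len(config$max_iterations)) {
    scan <- withCallingHandlers(
      scan_markers(geno, y, covariates, pseudo_qtns = current),
      error = function(e) stop("iteration ", it, ": ", conditionMessage(e),
                               call. = FALSE))
    cand <- candidate_filter(scan, alpha = config$alpha, M = m)
    pruned <- ld_prune(cand, geno, beta = config$ld_threshold)
    sel <- select_pseudo_qtns(pruned, y, covariates, geno,
                              criterion = config$criterion, M = m,
                              gamma = config$ebic_gamma,
                              bic_penalty_factor = config$bic_penalty_factor,
                              source_p = scan$p[pruned])
    crit_val <- min(sel$criterion_trace$criterion)
    history[[it]] <- list(iteration = it, set = sel,
                          n_candidates = length(cand),
                          n_pruned = length(pruned),
                          chosen_k = sel$chosen_k,
                          criterion_value = crit_val)
    new <- sel$marker_indices
    if (crit_val < best_crit) { best_crit <- crit_val; best_set <- new }
    if (identical(as.integer(new), as.integer(current))) {
      converged <- TRUE; stop_reason <- "stable_set"; break
    }
    sig <- paste(new, collapse = ",")
    if (sig %in% seen) {                      # revisit => cycle
      stop_reason <- "cycle_detected"
      current <- best_set                     # keep best-criterion set seen
      break
    }
    seen <- c(seen, sig)
    current <- new
  }

  final_scan <- scan_markers(geno, y, covariates, pseudo_qtns = current)
  structure(list(final_scan = final_scan, pseudo_qtns = current,
                 iteration_history = history, converged = converged,
                 stop_reason = stop_reason, n_iterations = length(history),
                 config = config),
            class = "blink_run")
}

#' Declare genome-wide significant markers
#'
#' Markers whose defined P value is at or below the Bonferroni cut
#' `alpha / M` (a P value exactly at the cut is declared significant).
#'
#' @param scan a `blink_scan` data.frame.
#' @param alpha significance level (default 0.01).
#' @param M number of tests (defaults to scanned markers).
#' @return the significant rows of the scan, sorted by P value.
#' @export
declare_significant <- function(scan, alpha = 0.01, M = nrow(scan)) {
  if (nrow(scan) == 0L) return(scan)
  hit <- !is.na(scan$p) & scan$p <= alpha / M
  out <- scan[hit, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Principal components of the genotype matrix
#'
#' SVD of the individual-by-marker mean-imputed, column-centered matrix;
#' scores use a deterministic sign convention (the largest-magnitude
#' marker loading of each component is positive).
#'
#' @param geno [genotype_data].
#' @param q number of components, `0 <= q < min(markers, individuals)`.
#' @return [covariate_data] with columns PC1..PCq.
#' @export
compute_pcs <- function(geno, q) {
  m <- n_markers(geno); n <- n_individuals(geno)
  if (q < 0 || q >= min(m, n))
    stop("q must satisfy 0 <= q < min(markers, individuals) = ", min(m, n))
  if (q == 0L)
    return(covariate_data(geno$individual_ids, matrix(0, n, 0L)))
  A <- t(impute_missing(geno, "mean"))       # n x m
  A <- sweep(A, 2L, colMeans(A))
  sv <- svd(A, nu = q, nv = q)
  flip <- vapply(seq_len(q), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(q), drop = FALSE] %*%
                    diag(sv$d[seq_len(q)], q, q), 2L, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(q))
  covariate_data(geno$individual_ids, scores)
}
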