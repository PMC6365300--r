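#' Fit a multi-locus association model by iterative pseudo-QTN selection
#'
#' The main entry point. Aligns genotypes, phenotype and covariates on
#' shared individuals, filters markers by minor allele frequency, then runs
#' the iterative scan-select cycle: every marker is tested in a fixed
#' effect model containing the current pseudo-QTN covariates; candidate
#' pseudo-QTNs are the markers passing the Bonferroni cut, sorted by P
#' value and pruned so no pair has |Pearson r| above the LD threshold; the
#' retained set size is chosen by information-criterion model selection;
#' and the cycle repeats until the set is stable. The fitted object carries
#' the final genome scan and the final pseudo-QTN model.
#'
#' @param geno [genotype_data].
#' @param pheno [phenotype_data] (or a plain named numeric vector).
#' @param covar optional [covariate_data]; alternatively `n_pcs > 0`
#'   computes genotype principal components and uses them as covariates.
#' @param n_pcs number of genotype PCs to use when `covar` is NULL.
#' @param config a [blink_config()]; individual tunables can also be
#'   passed through `...` (e.g. `alpha`, `ld_threshold`).
#' @param ... overrides forwarded to [blink_config()] when `config` is not
#'   supplied.
#' @return object of class `blink`: the `blink_run` fields plus `y`,
#'   `covariates`, `ids`, `geno_dim`, `maf_removed`, and `qtn_model` (the
#'   final covariates + pseudo-QTN [fit_fem()] fit).
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(n_individuals = 120, n_markers = 300, seed = 7)
#' tr <- simulate_phenotype(g, qtn_indices = c(10, 200), h2 = 0.6, seed = 8)
#' fit <- blink(g, phenotype_data(g$individual_ids, tr$phenotype))
#' fit
#' @export
blink <- function(geno, pheno, covar = NULL, n_pcs = 0L, config = NULL, ...) {
  if (is.numeric(pheno) && !inherits(pheno, "phenotype_data")) {
    ids <- names(pheno)
    if (is.null(ids)) ids <- geno$individual_ids
    pheno <- phenotype_data(ids, pheno)
  }
  if (is.null(config)) config <- blink_config(...)
  if (is.null(covar) && n_pcs > 0L) covar <- compute_pcs(geno, n_pcs)
  al <- align_samples(geno, pheno, covar)
  m0 <- n_markers(al$geno)
  g <- filter_maf(al$geno, config$maf_threshold)
  if (n_markers(g) == 0L)
    stop("no markers left after MAF filtering at threshold ",
         config$maf_threshold)
  run <- run_blink(g, al$y, al$covariates, config)
  W <- cbind(`(intercept)` = 1, al$covariates)
  if (length(run$pseudo_qtns)) {
    Gq <- .impute_rows(g$codes[run$pseudo_qtns, , drop = FALSE])
    rownames(Gq) <- g$map$marker_id[run$pseudo_qtns]
    W <- cbind(W, t(Gq))
  }
  qtn_model <- fit_fem(al$y, W, n_pseudo_qtns = length(run$pseudo_qtns))
  out <- run
  out$y <- al$y
  out$covariates <- al$covariates
  out$ids <- al$ids
  out$geno <- g
  out$geno_dim <- c(markers = n_markers(g), individuals = n_individuals(g))
  out$maf_removed <- m0 - n_markers(g)
  out$qtn_model <- qtn_model
  class(out) <- c("blink", "blink_run")
  out
}

#' @export
print.blink <- function(x, ...) {
  cat("Multi-locus association fit (iterative pseudo-QTN selection)\n")
  cat(sprintf("  %d markers x %d individuals (%d removed by MAF filter)\n",
              x$geno_dim[["markers"]], x$geno_dim[["individuals"]],
              x$maf_removed))
  cat(sprintf("  %d iteration(s); stop: %s%s\n", x$n_iterations,
              x$stop_reason, if (x$converged) " (converged)" else ""))
  k <- length(x$pseudo_qtns)
  cat(sprintf("  final pseudo-QTNs: %d selected by %s\n", k,
              x$config$criterion))
  if (k > 0) {
    ids <- x$final_scan$marker_id[x$pseudo_qtns]
    cat("   ", paste(utils::head(ids, 8L), collapse = ", "),
        if (k > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.blink <- function(object, ...) {
  m <- nrow(object$final_scan)
  sig <- declare_significant(object$final_scan, object$config$alpha, m)
  structure(list(fit = object, significant = sig,
                 bonferroni = object$config$alpha / m),
            class = "summary.blink")
}

#' @export
print.summary.blink <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Bonferroni cut: %.3g; significant markers: %d\n",
              x$bonferroni, nrow(x$significant)))
  if (nrow(x$significant) > 0)
    print.data.frame(utils::head(x$significant, 10L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.blink <- function(object, ...) {
  object$qtn_model$coefficients
}

#' @export
fitted.blink <- function(object, ...) {
  stats::setNames(object$qtn_model$fitted, object$ids)
}

#' @export
residuals.blink <- function(object, ...) {
  stats::setNames(object$qtn_model$residuals, object$ids)
}

#' Predict phenotypes from the final pseudo-QTN model
#'
#' Uses the intercept, covariate and pseudo-QTN effects of the final
#' model. With `newdata` (a [genotype_data] carrying the pseudo-QTN
#' markers), genotypes are looked up by marker id; new covariates must be
#' supplied if the fit used any.
#'
#' @param object a fitted `blink` object.
#' @param newdata optional [genotype_data] for new individuals.
#' @param newcovar optional covariate matrix for the new individuals.
#' @param ... ignored.
#' @return numeric vector of predicted trait values.
#' @export
predict.blink <- function(object, newdata = NULL, newcovar = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  qtn_ids <- object$final_scan$marker_id[object$pseudo_qtns]
  idx <- match(qtn_ids, newdata$map$marker_id)
  if (anyNA(idx))
    stop("newdata is missing pseudo-QTN marker(s): ",
         paste(qtn_ids[is.na(idx)], collapse = ", "))
  n_new <- n_individuals(newdata)
  c_cols <- ncol(object$covariates)
  if (c_cols > 0L) {
    if (is.null(newcovar)) stop("fit used covariates; supply newcovar")
    newcovar <- as.matrix(newcovar)
  } else newcovar <- matrix(0, n_new, 0L)
  W <- cbind(1, newcovar)
  if (length(idx))
    W <- cbind(W, t(.impute_rows(newdata$codes[idx, , drop = FALSE])))
  beta <- object$qtn_model$coefficients
  beta[is.na(beta)] <- 0
  as.numeric(W %*% beta)
}
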