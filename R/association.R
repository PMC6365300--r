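# Fixed-effect-model machinery.
#
# The genome scan tests one marker at a time in
#   y = intercept + covariates + pseudo-QTNs + marker,
# and the covariates-only model (used for pseudo-QTN model selection) is
#   y = intercept + covariates + first-k pseudo-QTNs.
# An intercept is always included (phenotypes are not centered by contract)
# and is never counted in information-criterion penalties.

.RSS_FLOOR <- 1e-300

#' Ordinary least squares fit with a Gaussian -2 log-likelihood
#'
#' Fits `y ~ X` by OLS (no implicit intercept: include a column of ones in
#' `X` if wanted). The -2LL is the maximum-likelihood Gaussian profile,
#' using the biased residual-variance estimate RSS/n. Rank-deficient
#' trailing columns are dropped deterministically (first occurrence kept)
#' and reported in `dropped`.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix with `length(y)` rows.
#' @param n_pseudo_qtns how many columns of `X` are pseudo-QTNs (stored as
#'   `k` for information-criterion penalties; intercept and common
#'   covariates are not counted).
#' @return list of class `fem_fit`: `coefficients`, `neg2_log_likelihood`,
#'   `k`, `n`, `residual_variance` (RSS/n), `rss`, `rank`, `dropped`
#'   (indices of aliased columns), `perfect_fit` flag, `fitted`, `residuals`.
#' @export
fit_fem <- function(y, X, n_pseudo_qtns = 0L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("rows of X (", nrow(X), ") do not match y (", n, ")")
  fit <- stats::lm.fit(X, y)
  rank <- fit$rank
  if (n <= rank)
    stop("degenerate model: n (", n, ") must exceed fitted rank (", rank, ")")
  dropped <- which(is.na(fit$coefficients))
  rss <- sum(fit$residuals^2)
  perfect <- rss <= max(.RSS_FLOOR, 1e-12 * sum(y^2))
  sigma2 <- max(rss, .RSS_FLOOR) / n
  neg2ll <- n * (log(2 * pi * sigma2) + 1)
  structure(list(coefficients = fit$coefficients,
                 neg2_log_likelihood = neg2ll,
                 k = as.integer(n_pseudo_qtns), n = n,
                 residual_variance = rss / n, rss = rss,
                 rank = rank, dropped = dropped, perfect_fit = perfect,
                 fitted = fit$fitted.values, residuals = fit$residuals),
            class = "fem_fit")
}

#' Two-sided P value from a Student-t statistic
#'
#' @param t_stat numeric t statistic (vectorized).
#' @param df residual degrees of freedom, >= 1.
#' @return two-sided tail probability in (0, 1].
#' @export
pvalue_from_t <- function(t_stat, df) {
  if (any(df < 1)) stop("degrees of freedom must be >= 1")
  2 * stats::pt(-abs(t_stat), df)
}

# Residualize the columns of A against the column span of qr_W.
.resid_on <- function(qr_W, A) {
  if (is.null(qr_W)) return(A)
  A - qr.fitted(qr_W, A)
}

#' Genome scan: test every marker in a fixed effect model
#'
#' For each marker j the model contains intercept + common covariates +
#' the current pseudo-QTN markers + marker j, and the reported P value is
#' the two-sided t test (1-df partial F) on the marker effect. When the
#' scanned marker is itself a pseudo-QTN, or exactly collinear with one,
#' that pseudo-QTN is removed from the covariate block for its own test so
#' the design stays non-singular. Markers that are constant, or exactly
#' collinear with the common covariates, get an undefined (NA) P value.
#'
#' Implementation: the covariate block is QR-decomposed once and both the
#' phenotype and all markers are residualized against it
#' (Frisch-Waugh-Lovell), which is algebraically identical to a full
#' per-marker refit.
#'
#' @param geno [genotype_data], aligned to `y`.
#' @param y numeric phenotype vector (no NA).
#' @param covariates numeric matrix (individuals x c), 0 columns for none.
#' @param pseudo_qtns integer vector of marker row indices used as
#'   covariates (may be empty).
#' @return data.frame of class `blink_scan` with columns marker_id,
#'   chromosome, position, effect, se, t, p, n_used.
#' @export
scan_markers <- function(geno, y, covariates = NULL, pseudo_qtns = integer(0)) {
  n <- n_individuals(geno)
  m <- n_markers(geno)
  y <- as.numeric(y)
  if (length(y) != n) stop("phenotype length (", length(y),
                           ") does not match individuals (", n, ")")
  if (is.null(covariates)) covariates <- matrix(0, n, 0L)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stop("covariate rows do not match individuals")
  pseudo_qtns <- as.integer(pseudo_qtns)
  if (length(pseudo_qtns) &&
      (min(pseudo_qtns) < 1L || max(pseudo_qtns) > m))
    stop("pseudo-QTN indices out of range")

  G <- impute_missing(geno, "mean")          # m x n
  W <- cbind(`(intercept)` = 1, covariates)
  if (length(pseudo_qtns))
    W <- cbind(W, t(G[pseudo_qtns, , drop = FALSE]))
  qr_W <- qr(W)
  p_cols <- qr_W$rank
  df <- n - p_cols - 1L
  if (df < 1L)
    stop("not enough residual degrees of freedom: n = ", n,
         ", covariate rank = ", p_cols)

  y_res <- as.numeric(.resid_on(qr_W, y))
  G_res <- t(.resid_on(qr_W, t(G)))          # m x n
  syy <- sum(y_res^2)
  sgg <- rowSums(G_res^2)
  sgy <- as.numeric(G_res %*% y_res)

  raw_ss <- rowSums((G - rowMeans(G))^2)
  defined <- sgg > pmax(1e-10 * pmax(raw_ss, 1), 1e-12)

  effect <- se <- tval <- pval <- rep(NA_real_, m)
  b <- sgy[defined] / sgg[defined]
  rss <- pmax(syy - b^2 * sgg[defined], .RSS_FLOOR)
  s <- sqrt(rss / df / sgg[defined])
  effect[defined] <- b
  se[defined] <- s
  tval[defined] <- b / s
  pval[defined] <- pvalue_from_t(b / s, df)

  # self-test: pseudo-QTNs (and markers exactly collinear with one) were
  # annihilated by the residualization; refit each without the offender
  special <- which(!defined & raw_ss > 1e-12)
  for (j in special) {
    off <- .collinear_pseudo(G, j, pseudo_qtns)
    if (is.na(off)) next                      # collinear with common covariates
    keep <- setdiff(pseudo_qtns, off)
    Wj <- cbind(1, covariates)
    if (length(keep)) Wj <- cbind(Wj, t(G[keep, , drop = FALSE]))
    res <- .single_marker_test(y, Wj, G[j, ])
    effect[j] <- res[1L]; se[j] <- res[2L]; tval[j] <- res[3L]; pval[j] <- res[4L]
  }

  out <- data.frame(marker_id = geno$map$marker_id,
                    chromosome = geno$map$chromosome,
                    position = geno$map$position,
                    effect = effect, se = se, t = tval, p = pval,
                    n_used = n, stringsAsFactors = FALSE)
  class(out) <- c("blink_scan", "data.frame")
  out
}

# Which pseudo-QTN (if any) is marker j exactly collinear with?
.collinear_pseudo <- function(G, j, pseudo_qtns) {
  if (j %in% pseudo_qtns) return(j)
  if (!length(pseudo_qtns)) return(NA_integer_)
  gj <- G[j, ]
  for (q in pseudo_qtns) {
    r <- suppressWarnings(stats::cor(gj, G[q, ]))
    if (!is.na(r) && abs(r) >= 1 - 1e-12) return(q)
  }
  NA_integer_
}

# Full refit of one marker against an explicit covariate block.
.single_marker_test <- function(y, W, g) {
  X <- cbind(W, marker = g)
  fit <- stats::lm.fit(X, y)
  if (is.na(fit$coefficients[["marker"]])) return(rep(NA_real_, 4L))
  df <- length(y) - fit$rank
  if (df < 1L) return(rep(NA_real_, 4L))
  rss <- max(sum(fit$residuals^2), .RSS_FLOOR)
  R <- qr.R(fit$qr)
  XtXinv_diag <- diag(chol2inv(R[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]))
  pos <- which(fit$qr$pivot[seq_len(fit$rank)] == ncol(X))  # lm.fit pivots
  if (!length(pos)) return(rep(NA_real_, 4L))
  v <- XtXinv_diag[pos]
  b <- fit$coefficients[["marker"]]
  s <- sqrt(rss / df * v)
  c(b, s, b / s, pvalue_from_t(b / s, df))
}

#' @export
print.blink_scan <- function(x, ...) {
  cat("genome scan:", nrow(x), "markers,", x$n_used[1L], "individuals;",
      sum(is.na(x$p)), "undefined P value(s)\n")
  print.data.frame(utils::head(x[order(x$p), ], 5L), row.names = FALSE)
  invisible(x)
}

#' Write a scan result as tab-separated text
#'
#' Columns marker_id, chromosome, position, effect, se, t, p, n_used;
#' undefined values printed as NA.
#'
#' @param scan a `blink_scan` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
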