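# Bin-based scoring of simulated scans. The genome is divided into
# fixed-width bins; a bin is a QTN bin if it contains at least one true
# QTN; a bin's P value is its most significant marker. Power, FDR and
# type I error are counted over bins at every distinct P-value threshold,
# and ROC curves are closed to cost 0 and 1 before trapezoid AUC.

#' Assign markers to genomic bins
#'
#' Bin id is `(chromosome, floor((position - 1) / bin_size_bp))`;
#' positions are 1-based.
#'
#' @param map data.frame with chromosome and position columns (e.g. a
#'   [genotype_data] map or a scan result).
#' @param qtn_indices integer row indices of the true QTNs in `map`.
#' @param bin_size_bp bin width in base pairs, >= 1.
#' @return data.frame, one row per bin: `bin_id`, `chromosome`, `bin`,
#'   `is_qtn_bin`, `n_markers`; attribute `"assignment"` holds the per-row
#'   bin id of `map`.
#' @export
bin_markers <- function(map, qtn_indices, bin_size_bp) {
  stopifnot(bin_size_bp >= 1)
  bin <- (map$position - 1L) %/% as.integer(bin_size_bp)
  bin_id <- paste(map$chromosome, bin, sep = ":")
  is_qtn <- tabulate_bins(bin_id, qtn_indices)
  out <- data.frame(bin_id = names(is_qtn),
                    is_qtn_bin = as.logical(is_qtn),
                    n_markers = as.integer(table(bin_id)[names(is_qtn)]),
                    stringsAsFactors = FALSE)
  attr(out, "assignment") <- bin_id
  out
}

tabulate_bins <- function(bin_id, qtn_indices) {
  u <- unique(bin_id)
  hit <- stats::setNames(rep(FALSE, length(u)), u)
  hit[unique(bin_id[qtn_indices])] <- TRUE
  hit
}

#' Per-bin P values (minimum over member markers)
#'
#' Bins whose members all have undefined P values are excluded.
#'
#' @param scan a `blink_scan` (or any data.frame with a `p` column,
#'   row-aligned with the map used for `bins`).
#' @param bins result of [bin_markers()] on the same map.
#' @return data.frame `bin_id`, `is_qtn_bin`, `p`.
#' @export
bin_pvalues <- function(scan, bins) {
  bin_id <- attr(bins, "assignment")
  if (is.null(bin_id) || length(bin_id) != nrow(scan))
    stop("bins were not computed from this scan's map")
  ok <- !is.na(scan$p)
  pmin_by <- tapply(scan$p[ok], bin_id[ok], min)
  idx <- match(bins$bin_id, names(pmin_by))
  out <- data.frame(bin_id = bins$bin_id, is_qtn_bin = bins$is_qtn_bin,
                    p = as.numeric(pmin_by[idx]), stringsAsFactors = FALSE)
  out[!is.na(out$p), , drop = FALSE]
}

# shared threshold sweep: returns power plus raw positive counts
.sweep_thresholds <- function(p, is_qtn) {
  thr <- sort(unique(p))
  n_qtn <- sum(is_qtn); n_null <- sum(!is_qtn)
  tp <- vapply(thr, function(t) sum(is_qtn & p <= t), integer(1))
  fp <- vapply(thr, function(t) sum(!is_qtn & p <= t), integer(1))
  list(thr = thr, tp = tp, fp = fp, n_qtn = n_qtn, n_null = n_null)
}

.close_curve <- function(cost, power) {
  o <- order(cost, power)
  cost <- cost[o]; power <- power[o]
  cost <- c(0, cost, 1)
  power <- c(0, power, power[length(power)])
  # collapse duplicate costs keeping the best power at each, then make
  # power non-decreasing in cost (the achievable-power staircase)
  keep <- !duplicated(cost, fromLast = TRUE)
  list(cost = cost[keep], power = cummax(power[keep]))
}

.trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

.make_curve <- function(cost, power, thr, axis, bin_size_bp) {
  cl <- .close_curve(cost, power)
  structure(list(axis = axis,
                 points = data.frame(cost = cl$cost, power = cl$power),
                 sweep = data.frame(threshold = thr, cost = cost,
                                    power = power),
                 auc = .trapezoid(cl$cost, cl$power),
                 bin_size_bp = bin_size_bp),
            class = "eval_curve")
}

#' Power versus FDR curve over bins
#'
#' At each distinct bin P value taken as the threshold, power is the
#' proportion of QTN bins detected and FDR the proportion of non-QTN bins
#' among positive bins (0 when there are no positives). The curve is
#' anchored at (0, 0), extended horizontally to FDR 1, and the AUC is the
#' trapezoid area over the full \[0, 1\] cost domain.
#'
#' @param bin_p result of [bin_pvalues()], or a data.frame with columns
#'   `p` and `is_qtn_bin`.
#' @param bin_size_bp recorded on the curve for provenance (optional).
#' @return object of class `eval_curve` with fields `axis`, `points`
#'   (the closed cost/power staircase), `sweep` (the raw per-threshold
#'   cost/power table), `auc`, `bin_size_bp`.
#' @export
power_fdr_curve <- function(bin_p, bin_size_bp = NA_integer_) {
  if (!any(bin_p$is_qtn_bin)) stop("no QTN bins: cannot compute power")
  if (all(bin_p$is_qtn_bin)) stop("no non-QTN bins: cannot compute FDR")
  sw <- .sweep_thresholds(bin_p$p, bin_p$is_qtn_bin)
  pos <- sw$tp + sw$fp
  fdr <- ifelse(pos == 0, 0, sw$fp / pos)
  .make_curve(fdr, sw$tp / sw$n_qtn, sw$thr, "FDR", bin_size_bp)
}

#' Power versus type-I-error curve over bins
#'
#' Type I error at a threshold is the proportion of non-QTN bins at or
#' below it (the empirical null distribution of the non-QTN bins).
#'
#' @inheritParams power_fdr_curve
#' @return object of class `eval_curve`.
#' @export
power_type1_curve <- function(bin_p, bin_size_bp = NA_integer_) {
  if (!any(bin_p$is_qtn_bin)) stop("no QTN bins: cannot compute power")
  if (all(bin_p$is_qtn_bin)) stop("no non-QTN bins: cannot compute type I error")
  sw <- .sweep_thresholds(bin_p$p, bin_p$is_qtn_bin)
  .make_curve(sw$fp / sw$n_null, sw$tp / sw$n_qtn, sw$thr, "type_I_error",
              bin_size_bp)
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("power vs %s curve: %d points, AUC = %.4f",
              x$axis, nrow(x$points), x$auc))
  if (!is.na(x$bin_size_bp)) cat(sprintf(" (bins of %d bp)", x$bin_size_bp))
  cat("\n")
  invisible(x)
}

#' @export
plot.eval_curve <- function(x, ...) {
  graphics::plot(x$points$cost, x$points$power, type = "s",
                 xlab = x$axis, ylab = "power", xlim = c(0, 1),
                 ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Score a scan against known QTNs at several bin sizes
#'
#' Convenience wrapper producing both curves per bin size.
#'
#' @param scan a `blink_scan`.
#' @param qtn_indices true QTN row indices into the scan.
#' @param bin_sizes_bp integer vector of bin widths.
#' @return data.frame: bin_size_bp, axis, auc; attribute `"curves"` holds
#'   the `eval_curve` objects.
#' @export
evaluate_scan <- function(scan, qtn_indices,
                          bin_sizes_bp = c(1L, 1000L, 10000L, 100000L)) {
  curves <- list()
  rows <- list()
  for (b in bin_sizes_bp) {
    bins <- bin_markers(scan, qtn_indices, b)
    bp <- bin_pvalues(scan, bins)
    cf <- power_fdr_curve(bp, b)
    ct <- power_type1_curve(bp, b)
    curves[[as.character(b)]] <- list(fdr = cf, type1 = ct)
    rows[[as.character(b)]] <- data.frame(
      bin_size_bp = b, axis = c("FDR", "type_I_error"),
      auc = c(cf$auc, ct$auc))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}

#' Null probability of candidate-region overlaps
#'
#' Probability, under random placement, that at least `n_overlap_min` of
#' `n_loci` sampled loci fall into candidate regions covering
#' `region_fraction` of the genome. The closed form is the binomial upper
#' tail P(X >= n_overlap_min), X ~ Binomial(n_loci, region_fraction); the
#' Monte-Carlo mode samples loci against a region mask and estimates the
#' same tail (the two agree within Monte-Carlo error).
#'
#' @param n_loci number of sampled loci.
#' @param region_fraction fraction of the genome covered by regions,
#'   in (0, 1).
#' @param n_overlap_min observed overlap count.
#' @param mode `"binomial"` (default) or `"monte_carlo"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed integer seed for Monte-Carlo.
#' @return upper-tail probability.
#' @export
enrichment_null <- function(n_loci, region_fraction, n_overlap_min,
                            mode = c("binomial", "monte_carlo"),
                            n_samples = 100000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(region_fraction > 0, region_fraction < 1,
            n_overlap_min <= n_loci)
  if (mode == "binomial")
    return(stats::pbinom(n_overlap_min - 1, n_loci, region_fraction,
                         lower.tail = FALSE))
  .with_seed(seed, {
    # genome discretized to a mask with the requested covered fraction
    mask_n <- 100000L
    covered <- seq_len(round(region_fraction * mask_n))
    hits <- vapply(seq_len(n_samples), function(i) {
      sum(sample.int(mask_n, n_loci) %in% covered)
    }, integer(1))
    mean(hits >= n_overlap_min)
  })
}

#' Count loci overlapping gene regions
#'
#' A locus overlaps when it lies within `window_bp` of a gene position on
#' the same chromosome (inclusive bounds: exactly `window_bp` away counts).
#'
#' @param loci data.frame with `chromosome`, `position`.
#' @param genes data.frame with `chromosome`, `position`.
#' @param window_bp window half-width in base pairs (default 50000).
#' @return number of loci within a window of any gene.
#' @export
overlap_count <- function(loci, genes, window_bp = 50000) {
  sum(vapply(seq_len(nrow(loci)), function(i) {
    same <- genes$chromosome == loci$chromosome[i]
    any(same & abs(genes$position - loci$position[i]) <= window_bp)
  }, logical(1)))
}
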