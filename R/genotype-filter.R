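#' Minor allele frequency of one marker
#'
#' Computed over non-missing calls only; the returned frequency is that of
#' the rarer allele, so it lies in \[0, 0.5\].
#'
#' @param geno a [genotype_data] object.
#' @param marker_index integer row index.
#' @return MAF in \[0, 0.5\].
#' @examples
#' g <- genotype_data(matrix(c(0, 0, 1, 2), 1),
#'                    data.frame(marker_id = "m", chromosome = "1", position = 1L),
#'                    letters[1:4])
#' compute_maf(g, 1)  # 3/8
#' @export
compute_maf <- function(geno, marker_index) {
  v <- geno$codes[marker_index, ]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("MAF undefined: marker ", geno$map$marker_id[marker_index],
         " has no non-missing calls")
  f <- sum(v) / (2 * length(v))
  min(f, 1 - f)
}

.maf_all <- function(geno) {
  nn <- rowSums(!is.na(geno$codes))
  if (any(nn == 0L))
    stop("MAF undefined for all-missing marker(s): ",
         paste(utils::head(geno$map$marker_id[nn == 0L], 3), collapse = ", "))
  f <- rowSums(geno$codes, na.rm = TRUE) / (2 * nn)
  pmin(f, 1 - f)
}

#' Filter markers by minor allele frequency
#'
#' Default semantics follow the usual GWAS preprocessing rule that markers
#' with MAF at or below the threshold are removed, i.e. only markers with
#' MAF strictly greater than `threshold` are retained.
#'
#' @param geno a [genotype_data] object.
#' @param threshold frequency in \[0, 0.5\]; default 0.05.
#' @param keep_strictly_greater if TRUE (default) retain MAF > threshold;
#'   if FALSE retain MAF >= threshold.
#' @return filtered [genotype_data].
#' @export
filter_maf <- function(geno, threshold = 0.05, keep_strictly_greater = TRUE) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  maf <- .maf_all(geno)
  keep <- if (keep_strictly_greater) maf > threshold else maf >= threshold
  geno[keep, ]
}

#' Impute missing genotype calls
#'
#' Returns a dense numeric matrix for use inside the numerics; the original
#' coded container is left untouched. `mean` (default) replaces missing
#' calls with the marker mean, which preserves Pearson correlations and
#' keeps least-squares well behaved; `major_allele` replaces them with the
#' modal code, preserving integer coding.
#'
#' @param geno a [genotype_data] object.
#' @param policy `"mean"` or `"major_allele"`.
#' @return numeric matrix, markers x individuals, no NA.
#' @export
impute_missing <- function(geno, policy = c("mean", "major_allele")) {
  policy <- match.arg(policy)
  nn <- rowSums(!is.na(geno$codes))
  if (any(nn == 0L))
    stop("cannot impute all-missing marker(s); filter them out first: ",
         paste(utils::head(geno$map$marker_id[nn == 0L], 3), collapse = ", "))
  .impute_rows(geno$codes, policy)
}

# row-wise imputation on a raw code matrix (rows = markers)
.impute_rows <- function(X, policy = "mean") {
  miss <- which(is.na(X), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(X)
  fill <- if (policy == "mean") {
    rowMeans(X, na.rm = TRUE)
  } else {
    apply(X, 1L, function(v) {
      tab <- table(v[!is.na(v)])
      as.numeric(names(tab)[which.max(tab)])
    })
  }
  X[miss] <- fill[miss[, 1L]]
  X
}

#' Align genotypes, phenotype and covariates on shared individuals
#'
#' Restricts all three inputs to the intersection of individual ids, in
#' sorted-id order (deterministic regardless of input order), and drops
#' individuals with a missing phenotype.
#'
#' @param geno [genotype_data].
#' @param pheno [phenotype_data].
#' @param covar optional [covariate_data] (NULL for none).
#' @return list with aligned `geno`, `y` (numeric phenotype vector named by
#'   id), `covariates` (numeric matrix, 0 columns if none), `ids`.
#' @export
align_samples <- function(geno, pheno, covar = NULL) {
  ids <- intersect(geno$individual_ids, pheno$individual_ids)
  if (!is.null(covar) && ncol(covar$X) > 0L)
    ids <- intersect(ids, covar$individual_ids)
  ids <- sort(ids)
  keep <- !is.na(pheno$values[match(ids, pheno$individual_ids)])
  ids <- ids[keep]
  if (length(ids) == 0L)
    stop("no analyzable individuals shared between genotype and phenotype inputs")
  y <- pheno$values[match(ids, pheno$individual_ids)]
  names(y) <- ids
  if (sum(!is.na(y)) < 2L)
    stop("fewer than 2 non-missing phenotype values after alignment")
  X <- if (is.null(covar) || ncol(covar$X) == 0L) {
    matrix(0, length(ids), 0L)
  } else {
    covar$X[match(ids, covar$individual_ids), , drop = FALSE]
  }
  if (ncol(X) > 0L) {
    const <- apply(X, 2L, function(col) max(col) - min(col) == 0)
    if (any(const))
      stop("constant covariate column(s) after alignment: ",
           paste(which(const), collapse = ", "))
  }
  list(geno = geno[NULL, match(ids, geno$individual_ids)],
       y = y, covariates = X, ids = ids)
}
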