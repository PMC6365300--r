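# Synthetic genotypes and phenotypes for power/FDR studies.
#
# Genotypes are independent biallelic SNPs in Hardy-Weinberg proportions:
# per-marker allele frequency drawn uniform over maf_range, codes
# Binomial(2, freq). Optional discrete subpopulations with
# frequency divergence induce detectable structure. Phenotypes are
# additive: QTN effects are normal draws, genetic values are the genotype
# x effect sums, and the residual variance is set from the realized
# genetic variance so the assigned additive proportion equals the target
# heritability.

# derive a bounded child seed from a parent seed, reproducibly
.child_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + tag)
  sample.int(.Machine$integer.max - 1L, 1L)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Simulate independent biallelic SNP genotypes
#'
#' @param n_individuals sample size.
#' @param n_markers number of markers.
#' @param n_chromosomes chromosomes; markers are split evenly across them
#'   with positions uniform over `chrom_length_bp` and sorted.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param maf_range allele-frequency range, a sub-interval of (0, 0.5\].
#' @param k_subpops optional number of subpopulations (> 1 induces
#'   structure).
#' @param divergence Fst-like spread of subpopulation allele frequencies
#'   around the global frequency (standard deviation on the frequency
#'   scale), used only when `k_subpops > 1`.
#' @param seed integer seed; identical seeds give identical data.
#' @return [genotype_data]; when `k_subpops > 1` the subpopulation labels
#'   are attached as attribute `"subpop"`.
#' @export
simulate_genotypes <- function(n_individuals, n_markers, n_chromosomes = 5L,
                               chrom_length_bp = 1e8, maf_range = c(0.05, 0.5),
                               k_subpops = 1L, divergence = 0.1, seed = NULL) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], n_chromosomes >= 1)
  .with_seed(seed, {
    freq <- stats::runif(n_markers, maf_range[1], maf_range[2])
    chrom <- sort(rep_len(seq_len(n_chromosomes), n_markers))
    pos <- as.integer(ceiling(stats::runif(n_markers, 0, chrom_length_bp)))
    subpop <- NULL
    if (k_subpops > 1L) {
      subpop <- rep_len(seq_len(k_subpops), n_individuals)
      pf <- matrix(stats::rnorm(n_markers * k_subpops, freq, divergence),
                   n_markers, k_subpops)
      pf <- pmin(pmax(pf, 0.01), 0.99)
      codes <- matrix(stats::rbinom(n_markers * n_individuals, 2L,
                                    pf[, subpop]), n_markers, n_individuals)
    } else {
      codes <- matrix(stats::rbinom(n_markers * n_individuals, 2L, freq),
                      n_markers, n_individuals)
    }
    g <- genotype_data(codes,
                       data.frame(marker_id = sprintf("snp%06d", seq_len(n_markers)),
                                  chromosome = as.character(chrom),
                                  position = pos, stringsAsFactors = FALSE),
                       sprintf("ind%05d", seq_len(n_individuals)))
    if (!is.null(subpop)) attr(g, "subpop") <- subpop
    g
  })
}

#' Sample QTN positions, optionally in clustered pairs
#'
#' Unclustered: a simple random sample of markers without replacement.
#' Clustered: `n_qtn/2` anchor markers are sampled, and each anchor is
#' paired with a distinct marker on the same chromosome within
#' `cluster_distance_bp`; anchors with no eligible partner are resampled
#' (bounded retries).
#'
#' @param geno [genotype_data].
#' @param n_qtn number of QTNs (even when `clustered`).
#' @param clustered logical.
#' @param cluster_distance_bp pairing distance in base pairs
#'   (default 300000).
#' @param seed integer seed.
#' @param max_retries resampling attempts per anchor before giving up.
#' @return integer vector of marker row indices.
#' @export
sample_qtns <- function(geno, n_qtn, clustered = FALSE,
                        cluster_distance_bp = 300000, seed = NULL,
                        max_retries = 100L) {
  m <- n_markers(geno)
  stopifnot(n_qtn <= m)
  .with_seed(seed, {
    if (!clustered) return(sort(sample.int(m, n_qtn)))
    if (n_qtn %% 2L != 0L) stop("clustered sampling needs an even n_qtn")
    chrom <- geno$map$chromosome
    pos <- geno$map$position
    picked <- integer(0)
    for (pair in seq_len(n_qtn / 2L)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        anchor <- sample(setdiff(seq_len(m), picked), 1L)
        partners <- which(chrom == chrom[anchor] &
                            abs(pos - pos[anchor]) <= cluster_distance_bp)
        partners <- setdiff(partners, c(anchor, picked))
        if (length(partners)) {
          partner <- if (length(partners) == 1L) partners
                     else sample(partners, 1L)
          picked <- c(picked, anchor, partner)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("no eligible QTN partner within ", cluster_distance_bp,
             " bp after ", max_retries, " anchor draws")
    }
    sort(picked)
  })
}

#' Simulate an additive phenotype with controlled heritability
#'
#' QTN effects are drawn Normal(0, `effect_sd`^2); genetic values are the
#' additive genotype-weighted sums; residuals are Normal with variance
#' `var(genetic) * (1 - h2) / h2`, computed from the realized
#' (sample) genetic variance so the assigned additive-variance proportion
#' equals `h2`. The realized heritability `var(genetic) / var(phenotype)`
#' still fluctuates around `h2` through the residual draw.
#'
#' @param geno [genotype_data].
#' @param qtn_indices integer marker row indices of the causal markers.
#' @param h2 target heritability in (0, 1\].
#' @param effect_sd standard deviation of QTN effects (default 1).
#' @param seed integer seed.
#' @return list of class `simulated_trait`: `phenotype`, `qtn_indices`,
#'   `qtn_ids`, `qtn_effects`, `genetic_values`, `target_h2`,
#'   `realized_h2`, `seed`.
#' @export
simulate_phenotype <- function(geno, qtn_indices, h2, effect_sd = 1,
                               seed = NULL) {
  stopifnot(h2 > 0, h2 <= 1)
  qtn_indices <- as.integer(qtn_indices)
  .with_seed(seed, {
    effects <- stats::rnorm(length(qtn_indices), 0, effect_sd)
    Gq <- .impute_rows(geno$codes[qtn_indices, , drop = FALSE])
    gvals <- as.numeric(crossprod(Gq, effects))
    vg <- stats::var(gvals)
    if (!is.finite(vg) || vg <= 0)
      stop("zero additive genetic variance (monomorphic QTNs?)")
    resid <- if (h2 == 1) rep(0, length(gvals))
             else stats::rnorm(length(gvals), 0, sqrt(vg * (1 - h2) / h2))
    y <- gvals + resid
    structure(list(phenotype = stats::setNames(y, geno$individual_ids),
                   qtn_indices = qtn_indices,
                   qtn_ids = geno$map$marker_id[qtn_indices],
                   qtn_effects = effects,
                   genetic_values = gvals,
                   target_h2 = h2,
                   realized_h2 = vg / stats::var(y),
                   seed = seed),
              class = "simulated_trait")
  })
}

#' @export
print.simulated_trait <- function(x, ...) {
  cat(sprintf("simulated trait: %d individuals, %d QTNs, target h2 = %.2f, realized h2 = %.3f\n",
              length(x$phenotype), length(x$qtn_indices), x$target_h2,
              x$realized_h2))
  invisible(x)
}

#' Write the ground truth of a simulated trait
#'
#' @param trait a `simulated_trait`.
#' @param geno the [genotype_data] it was simulated from.
#' @param path output path (tab-separated: marker_id, chromosome,
#'   position, effect).
#' @return `path`, invisibly.
#' @export
write_truth <- function(trait, geno, path) {
  utils::write.table(
    data.frame(marker_id = trait$qtn_ids,
               chromosome = geno$map$chromosome[trait$qtn_indices],
               position = geno$map$position[trait$qtn_indices],
               effect = trait$qtn_effects),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
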