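---
title: "Iterative pseudo-QTN association: model, tuning and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative pseudo-QTN association: model, tuning and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

blinkr fits multi-locus genome-wide association models without a mixed
model. Polygenic background is absorbed not by a kinship random effect but
by *pseudo-QTNs*: markers selected from the data and fitted as fixed-effect
covariates. Two fixed effect models (FEMs) alternate.

The **testing model** evaluates one marker at a time,

$$y_i = \beta_0 + \sum_{l} c_{il}\gamma_l + \sum_{u=1}^{k} S^*_{iu} b_u + S_{ij} d_j + e_i,$$

where $y_i$ is the trait of individual $i$, $c_{il}$ are common covariates
(e.g. principal components), $S^*_{iu}$ are the genotypes of the current
$k$ pseudo-QTNs, $S_{ij}$ the additive genotype code (0/1/2) of the tested
marker $j$, and $e_i \sim (0, \sigma^2_e)$. The reported P value is the
two-sided $t$ test on $d_j$. The **selection model** drops the testing term
and varies how many of the top candidates are kept:

$$y_i = \beta_0 + \sum_l c_{il}\gamma_l + \sum_{u=1}^{k} S^*_{iu} b_u + e_i,
\qquad k = 0, 1, \dots, t.$$

Candidates for the pseudo-QTN set are chosen from the scan in three steps:

1. **Bonferroni filter.** Markers with $P \le \alpha/M$ survive and are
   sorted most significant first ($\alpha = 0.01$ by default, $M$ = number
   of scanned markers).
2. **LD pruning.** A greedy sweep keeps the head of the list and removes
   every later candidate whose absolute Pearson correlation with it exceeds
   the threshold $\beta$ (0.7 by default), recursing on the remainder. LD
   here is plain correlation of genotype codes, computed on the
   mean-imputed matrix over all analyzed individuals — no subsampling, so
   pruning is exact at the scale this package targets.
3. **Model-size selection.** The selection model is fitted for every nested
   prefix $k = 0..t$ and the information criterion decides $k$.

The scan and the selection steps alternate, starting from an empty
pseudo-QTN set (iteration 1 is therefore a plain covariates-only scan),
until two consecutive pseudo-QTN sets are identical.

## The information criterion

The package's default criterion is

$$\mathrm{BIC}_k = -2\mathrm{LL}_k + 2\,k\ln(n),$$

with $-2\mathrm{LL}$ the Gaussian profile likelihood at the ML variance
estimate $\mathrm{RSS}/n$, $n$ the number of individuals, and $k$ counting
pseudo-QTNs only — the intercept and common covariates are free. Note the
penalty coefficient: the default is $2k\ln(n)$, twice the textbook BIC
penalty. This heavier penalty is deliberately conservative about adding
pseudo-QTNs; `bic_penalty_factor = 1` restores the textbook form, and AIC
($-2\mathrm{LL} + 2k$) and an extended BIC
($\mathrm{BIC} + 2\gamma\ln\binom{M}{k}$, $\gamma = 0.5$, with $M$ the
predictor-space size) are available through `criterion=`. For the extended
BIC the combinatorial term uses the total number of scanned markers as the
predictor space; that is this package's definition, chosen so the penalty
reflects the true search space of the candidate filter.

Two design choices here were genuinely open and are worth recording:

* **$k = 0$ is always evaluated**, although the selection step could start
  at $k = 1$. Without the empty model in the search, a spurious pseudo-QTN
  picked in an early iteration could never be discarded on a null trait;
  with it, pure-noise phenotypes converge to an empty set.
* **Ties go to the smaller $k$** (parsimony), and the candidate list is
  capped at $n - c - 2$ so every nested fit retains positive residual
  degrees of freedom; the capped-off candidates are the least significant.

## Numerical strategy

The per-iteration scan residualizes the phenotype and all marker columns
against a single QR decomposition of the covariate block (intercept +
covariates + pseudo-QTNs) — the Frisch–Waugh–Lovell identity — so each
marker test costs one dot product yet is algebraically identical to a full
refit. The test suite verifies equality against per-marker `lm()` refits at
1e-10.

Degenerate cases are handled explicitly:

* a marker that is **constant** or exactly collinear with the common
  covariates has an undefined (NA) P value, never a fabricated one;
* a marker that **is a pseudo-QTN** (or exactly collinear with one) is
  tested by removing that pseudo-QTN from the covariate block for its own
  test, so the final report never contains an undefined pseudo-QTN P value.
  Only exact collinearity (|r| at 1 within 1e-12) triggers the exclusion;
  merely high LD does not, because the pruning step already guarantees the
  set itself is not internally correlated above $\beta$;
* an exact zero-residual fit is flagged `perfect_fit` and the likelihood is
  floored rather than returning infinity;
* rank-deficient designs drop trailing aliased columns deterministically
  (first occurrence kept), mirroring `lm()`.

Missing genotype calls are mean-imputed per marker inside the numerics
(the stored codes are never modified); mean imputation keeps Pearson
correlations and least squares well behaved. A modal-code policy is
available where integer codes must be preserved. Missing phenotypes are
dropped during alignment, which intersects individual ids and orders them
deterministically (sorted) regardless of input order.

Termination is not guaranteed by the iteration rule itself, so the engine
adds two guards: an iteration cap (default 10) and cycle detection on the
ordered pseudo-QTN index tuples; on a cycle the set with the best criterion
value seen so far is kept. Every run reports `stop_reason` as one of
`stable_set`, `max_iterations`, `cycle_detected`.

## Tunables

| parameter | default | meaning |
|---|---|---|
| `maf_threshold` | 0.05 | markers with minor allele frequency *at or below* this are removed (strictly-greater retained) |
| `alpha` | 0.01 | genome-wide level; candidate cut and significance cut are both `alpha/M` (inclusive boundary) |
| `ld_threshold` | 0.7 | greedy pruning cut on absolute Pearson r |
| `criterion` | BIC | model-size criterion (BIC / AIC / eBIC) |
| `bic_penalty_factor` | 2 | multiplier on k·ln(n) |
| `max_iterations` | 10 | engine cap |
| `bin_sizes_bp` | 1, 1e3, 1e4, 1e5 | evaluation bin widths |

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws independent biallelic SNPs in
Hardy–Weinberg proportions: each marker's allele frequency is uniform over
`maf_range` (default 0.05–0.5) and codes are Binomial(2, freq). Optional
discrete subpopulations with frequency divergence produce detectable
structure (the PC helper separates them). Positions are uniform over a
configurable number of chromosomes, so genomic-bin logic is exercised.

`simulate_phenotype()` implements the additive construction used in GWAS
power studies: QTN effects drawn Normal(0, 1), genetic values
$g_i = \sum_q S_{iq}\beta_q$, and residuals Normal with variance
$\mathrm{var}(g)\,(1-h^2)/h^2$ computed from the *realized* sample genetic
variance, so the assigned additive proportion equals the target
heritability (default target 0.75). The realized
$h^2 = \mathrm{var}(g)/\mathrm{var}(y)$ still fluctuates through the
residual draw; its mean over replicates recovers the target, which is what
the acceptance script measures. `sample_qtns()` supports the clustered
scenario — QTNs drawn in pairs within a fixed distance on a chromosome,
default 300 kb, the distance being a parameter because both 10 kb and
300 kb variants are plausible designs — alongside simple random placement.

What the simulator deliberately does **not** model: linkage
disequilibrium between non-causal neighbours (markers are independent given
the subpopulation), dominance and epistasis, case-control liability, and
kinship beyond discrete subpopulations. Consequently, passing tests show
that the estimator does what its own model claims under clean additive
genetics; they do not certify behaviour under the LD structure, relatedness
and confounding of real panels.

## Scoring scans

Evaluation is bin-based: the genome is divided into fixed-width bins
(1 bp, 1 kb, 100 kb emitted; 10 kb used as the headline width), a bin is a
QTN bin if it contains at least one true QTN, and a bin's P value is its
most significant marker. Sweeping thresholds over the observed bin P
values yields power (detected QTN bins / QTN bins) against FDR (non-QTN
bins among positives; defined as 0 when there are no positives) or against
type I error (the empirical null proportion of non-QTN bins passing). The
curve is anchored at (0, 0), extended horizontally to cost 1, collapsed to
the achievable-power staircase, and integrated by trapezoid — AUC over the
full [0, 1] cost domain. Interpolation is not defined by the counting
rules themselves; the trapezoid on the staircase is this package's choice.

The enrichment helper answers the candidate-gene question — is an observed
overlap between associated loci and gene regions covering a fraction $f$
of the genome surprising? — with the closed-form binomial upper tail
$P(X \ge x),\ X \sim \mathrm{Bin}(n_{\mathrm{loci}}, f)$ by default, and a
Monte-Carlo mode (sampling loci against a region mask) for the sampling
view of the same null; the two agree within Monte-Carlo error.

## Problem sizes used in the tests

The suite exercises the full pipeline at desk scale: oracle equivalence on
a 50 × 30 fixture, null calibration on 100 replicates of 10,000 markers ×
100 individuals, the clustered-QTN power comparison on 50 replicates of
5,000 markers × 500 individuals (20 QTNs in 300 kb pairs, $h^2 = 0.75$),
and the heritability construction on 200 replicates of 10,000 markers ×
1,000 individuals. These sizes keep every property statistically sharp
while the whole suite remains runnable on a laptop core.

## Known limitations

* Binary traits are analysed as numeric 0/1 in the linear FEM; there is no
  logistic scan.
* No mixed-model fallback: confounding that a kinship matrix would absorb
  is only addressed through PCs and pseudo-QTNs.
* The LD pruner is quadratic in the candidate count; candidates are
  Bonferroni-filtered first, so this is immaterial in practice.
* VCF, dosage and multi-allelic inputs are out of scope; genotype input is
  the numeric table or PLINK bed/bim/fam.
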