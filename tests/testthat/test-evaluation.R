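make_scan <- function(chrom, pos, p) {
  data.frame(marker_id = sprintf("m%03d", seq_along(pos)),
             chromosome = as.character(chrom), position = pos, p = p,
             stringsAsFactors = FALSE)
}

test_that("bin assignment follows the (chromosome, floor) rule", {
  scan <- make_scan(c(1, 1, 1, 2), c(100, 900, 1500, 100), c(0.5, 0.1, 0.9, 0.2))
  # 1 bp bins: every marker its own bin; QTN bins are exactly the QTNs
  b1 <- bin_markers(scan, qtn_indices = c(2L, 4L), bin_size_bp = 1)
  expect_identical(nrow(b1), 4L)
  expect_identical(sum(b1$is_qtn_bin), 2L)
  # 1 KB bins: positions 100 and 900 co-bin
  b2 <- bin_markers(scan, qtn_indices = c(1L, 2L), bin_size_bp = 1000)
  expect_identical(nrow(b2), 3L)
  expect_identical(sum(b2$is_qtn_bin), 1L)
})

test_that("bin membership and bin P values match a brute-force recount", {
  set.seed(50)
  m <- 300
  scan <- make_scan(sample(1:3, m, TRUE), sample.int(5e5, m), runif(m))
  scan$p[sample.int(m, 8)] <- NA
  qtns <- sample.int(m, 12)
  for (bs in c(1, 1000, 100000)) {
    bins <- bin_markers(scan, qtns, bs)
    bp <- bin_pvalues(scan, bins)
    key <- paste(scan$chromosome, (scan$position - 1) %/% bs, sep = ":")
    for (row in sample.int(nrow(bp), min(nrow(bp), 25))) {
      members <- which(key == bp$bin_id[row])
      expect_identical(bp$is_qtn_bin[row], any(members %in% qtns))
      expect_equal(bp$p[row], min(scan$p[members], na.rm = TRUE))
    }
    # bins with only undefined members are excluded
    expect_false(any(is.na(bp$p)))
  }
})

test_that("single-marker bins reproduce the scan and the min rule holds", {
  scan <- make_scan(1, c(10, 20), c(0.3, 1e-9))
  bins <- bin_markers(scan, integer(0), 1000)  # both in one bin
  bp <- bin_pvalues(scan, bins)
  expect_equal(bp$p, 1e-9)
  bins1 <- bin_markers(scan, integer(0), 1)
  expect_equal(sort(bin_pvalues(scan, bins1)$p), c(1e-9, 0.3))
})

test_that("power/FDR counting matches hand counts on engineered scans", {
  # 3 QTN bins, 1 non-QTN bin positive at the loosest threshold
  scan <- make_scan(1, c(1, 2, 3, 4), c(1e-8, 1e-7, 1e-6, 1e-5))
  bins <- bin_markers(scan, qtn_indices = 1:3, bin_size_bp = 1)
  bp <- bin_pvalues(scan, bins)
  cur <- power_fdr_curve(bp)
  # at the loosest threshold: 3 TP + 1 FP -> FDR 1/4, power 1
  expect_true(any(abs(cur$sweep$cost - 0.25) < 1e-12 & cur$sweep$power == 1))
  # 2 QTN bins, 1 detected: power 0.5
  scan2 <- make_scan(1, c(1, 2, 3), c(1e-8, 0.5, 0.9))
  bins2 <- bin_markers(scan2, qtn_indices = 1:2, bin_size_bp = 1)
  cur2 <- power_fdr_curve(bin_pvalues(scan2, bins2))
  expect_true(any(abs(cur2$sweep$power - 0.5) < 1e-12))
})

test_that("perfect separation gives AUC 1; curves are closed to [0,1]", {
  set.seed(55)
  scan <- make_scan(1, 1:10, c(sort(runif(5, 0, 1e-6)), sort(runif(5, 0.1, 1))))
  bins <- bin_markers(scan, qtn_indices = 1:5, bin_size_bp = 1)
  bp <- bin_pvalues(scan, bins)
  cf <- power_fdr_curve(bp)
  expect_equal(cf$auc, 1)
  expect_equal(cf$points$cost[1], 0)
  expect_equal(cf$points$cost[nrow(cf$points)], 1)
  ct <- power_type1_curve(bp)
  expect_equal(ct$auc, 1)
  # type I error reaches 1 at the loosest threshold
  expect_equal(max(ct$points$cost), 1)
})

test_that("curves are invariant to strictly monotone P transforms", {
  set.seed(60)
  scan <- make_scan(1, 1:200, runif(200))
  bins <- bin_markers(scan, qtn_indices = sample.int(200, 20), bin_size_bp = 1)
  bp <- bin_pvalues(scan, bins)
  bp2 <- bp; bp2$p <- sqrt(bp$p)        # strictly monotone
  expect_equal(power_fdr_curve(bp)$points, power_fdr_curve(bp2)$points)
  expect_equal(power_type1_curve(bp)$auc, power_type1_curve(bp2)$auc)
})

test_that("random P values give a near-diagonal power/type-I curve", {
  aucs <- vapply(1:20, function(r) {
    set.seed(4000 + r)
    scan <- make_scan(1, 1:500, runif(500))
    bins <- bin_markers(scan, sample.int(500, 50), 1)
    power_type1_curve(bin_pvalues(scan, bins))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # monotone: power and cost non-decreasing along each curve
  set.seed(4100)
  scan <- make_scan(1, 1:300, runif(300))
  bins <- bin_markers(scan, sample.int(300, 30), 1)
  ct <- power_type1_curve(bin_pvalues(scan, bins))
  expect_true(all(diff(ct$points$cost) >= 0))
  expect_true(all(diff(ct$points$power) >= 0))
})

test_that("enrichment null: closed-form binomial tail and its bounds", {
  expect_equal(enrichment_null(9, 0.03, 0), 1)
  # exact four-term complement for P(X >= 4), X ~ Bin(9, 0.03)
  exact <- 1 - sum(choose(9, 0:3) * 0.03^(0:3) * 0.97^(9:6))
  expect_equal(enrichment_null(9, 0.03, 4), exact, tolerance = 1e-9)
  expect_lt(enrichment_null(9, 0.03, 4), 0.01)
  expect_lt(enrichment_null(40, 0.03, 8), 0.05)
})

test_that("Monte-Carlo enrichment null agrees with the closed form", {
  p_mc <- enrichment_null(9, 0.03, 2, mode = "monte_carlo",
                          n_samples = 100000L, seed = 99)
  p_cf <- enrichment_null(9, 0.03, 2)
  se <- sqrt(p_cf * (1 - p_cf) / 100000)
  expect_lt(abs(p_mc - p_cf), 3 * se)
})

test_that("locus/gene overlap counting uses inclusive 50 kb windows", {
  genes <- data.frame(chromosome = c("1", "2"), position = c(1e6, 5e6))
  loci <- data.frame(chromosome = c("1", "1", "2", "2"),
                     position = c(1e6 + 50000, 1e6 + 50001, 5e6, 4e6))
  expect_identical(overlap_count(loci, genes), 2L)
  # brute-force double loop on a random fixture
  set.seed(70)
  genes2 <- data.frame(chromosome = sample(1:3, 40, TRUE),
                       position = sample.int(1e7, 40))
  loci2 <- data.frame(chromosome = sample(1:3, 25, TRUE),
                      position = sample.int(1e7, 25))
  brute <- 0L
  for (i in 1:25) {
    hit <- FALSE
    for (j in 1:40)
      if (loci2$chromosome[i] == genes2$chromosome[j] &&
          abs(loci2$position[i] - genes2$position[j]) <= 50000) hit <- TRUE
    brute <- brute + hit
  }
  expect_identical(overlap_count(loci2, genes2), brute)
})

test_that("evaluate_scan summarises AUC per bin size and axis", {
  g <- rand_geno(n = 100, m = 200, seed = 81)
  q <- sample_qtns(g, 6, seed = 82)
  tr <- simulate_phenotype(g, q, h2 = 0.8, seed = 83)
  scan <- scan_markers(g, tr$phenotype)
  tab <- evaluate_scan(scan, tr$qtn_indices, c(1L, 10000L))
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_identical(sort(unique(tab$axis)), c("FDR", "type_I_error"))
})
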