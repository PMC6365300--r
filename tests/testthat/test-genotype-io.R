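test_that("numeric-table write/read round-trips codes and map exactly", {
  g <- tiny_geno()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "numeric_table")
  expect_identical(g2$codes, g$codes)
  expect_identical(g2$map, g$map)
  expect_identical(g2$individual_ids, g$individual_ids)

  g <- rand_geno(n = 7, m = 20, seed = 5)
  g$codes[2, 3] <- NA
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "numeric_table")
  expect_identical(g2$codes, g$codes)
  expect_identical(g2$map, g$map)
})

test_that("missing tokens and unknown characters map to NA; bad lines are named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker_id,chromosome,position,A,B",
               "m1,1,10,0,NA",
               "m2,1,20,.,2",
               "m3,2,5,?,1"), path)
  g <- read_genotypes(path, "numeric_table")
  expect_true(is.na(g$codes[g$map$marker_id == "m1", 2]))
  expect_true(is.na(g$codes[g$map$marker_id == "m2", 1]))
  expect_true(is.na(g$codes[g$map$marker_id == "m3", 1]))

  writeLines(c("marker_id,chromosome,position,A,B",
               "m1,1,10,0"), path)
  expect_error(read_genotypes(path, "numeric_table"), "line 2")

  writeLines(c("marker_id,chromosome,position,A,B",
               "m1,1,10,0,1",
               "m1,2,99,2,2"), path)
  expect_error(read_genotypes(path, "numeric_table"), "duplicate")

  writeLines(c("marker_id,chromosome,position,A,B",
               "m1,1,10,3,1"), path)
  expect_error(read_genotypes(path, "numeric_table"), "not in \\{0,1,2\\}")
})

test_that("map is sorted by (chromosome, position) on load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("marker_id", "chromosome", "position", "A", "B", sep = "\t"),
               paste("m1", "2", "50", 0, 1, sep = "\t"),
               paste("m2", "1", "900", 1, 1, sep = "\t"),
               paste("m3", "1", "100", 2, 0, sep = "\t")), path)
  g <- read_genotypes(path, "numeric_table")
  expect_identical(g$map$marker_id, c("m3", "m2", "m1"))
  expect_identical(g$codes[1, ], c(2, 0))
})

test_that("PLINK bed round-trip matches the numeric-table codes", {
  g <- rand_geno(n = 13, m = 25, seed = 9)   # 13 forces byte padding
  g$codes[c(3, 40, 100)] <- NA
  stem <- withr::local_tempfile()
  write_genotypes(g, paste0(stem, ".bed"), format = "plink_bed")
  gb <- read_genotypes(paste0(stem, ".bed"), "plink_bed")
  expect_identical(gb$codes, g$codes)
  expect_identical(gb$map$marker_id, g$map$marker_id)
  expect_identical(gb$map$position, g$map$position)
  expect_identical(gb$individual_ids, g$individual_ids)
})

test_that("bed reader rejects wrong magic and truncation", {
  stem <- withr::local_tempfile()
  g <- rand_geno(n = 4, m = 3, seed = 2)
  write_genotypes(g, paste0(stem, ".bed"), format = "plink_bed")
  raw <- readBin(paste0(stem, ".bed"), "raw", 100)
  raw[1] <- as.raw(0)
  writeBin(raw, paste0(stem, ".bed"))
  expect_error(read_genotypes(paste0(stem, ".bed"), "plink_bed"), "magic")
})

test_that("MAF is counted over non-missing calls and is allele-label symmetric", {
  g <- tiny_geno()
  expect_equal(compute_maf(g, which(g$map$marker_id == "m1")), 3 / 8)
  expect_equal(compute_maf(g, which(g$map$marker_id == "m2")), 2 / 6)  # alt freq 4/6
  gm <- genotype_data(matrix(0, 1, 4),
                      data.frame(marker_id = "x", chromosome = "1", position = 1L),
                      letters[1:4])
  expect_equal(compute_maf(gm, 1), 0)

  g2 <- rand_geno(n = 20, m = 15, seed = 77)
  swapped <- genotype_data(2 - g2$codes, g2$map, g2$individual_ids)
  for (j in seq_len(15))
    expect_equal(compute_maf(g2, j), compute_maf(swapped, j))

  gall <- tiny_geno()
  gall$codes[1, ] <- NA
  expect_error(compute_maf(gall, 1), "no non-missing")
})

test_that("filter_maf removes 'at or below' and matches a brute-force recount", {
  # three markers engineered to MAF 0.04, 0.05, 0.10 over 50 individuals
  n <- 50
  mk <- function(count1) c(rep(1, count1), rep(0, n - count1))
  g <- genotype_data(rbind(mk(4), mk(5), mk(10)),
                     data.frame(marker_id = c("a", "b", "c"),
                                chromosome = "1", position = 1:3),
                     sprintf("i%02d", 1:n))
  kept <- filter_maf(g, 0.05)
  expect_identical(kept$map$marker_id, "c")

  g2 <- rand_geno(n = 30, m = 200, seed = 11, maf = c(0.01, 0.5))
  f <- filter_maf(g2, 0.05)
  maf_each <- vapply(seq_len(200), function(j) compute_maf(g2, j), numeric(1))
  expect_identical(f$map$marker_id, g2$map$marker_id[maf_each > 0.05])
  # idempotence
  expect_identical(filter_maf(f, 0.05)$map, f$map)
  # threshold 0 removes exactly the monomorphic markers
  g3 <- g2
  g3$codes[5, ] <- 2
  expect_false(g3$map$marker_id[5] %in% filter_maf(g3, 0)$map$marker_id)
})

test_that("imputation follows the policy and leaves observed calls alone", {
  g <- genotype_data(rbind(c(0, 2, NA), c(0, 0, NA), c(1, 2, 0)),
                     data.frame(marker_id = c("a", "b", "c"),
                                chromosome = "1", position = 1:3),
                     c("x", "y", "z"))
  mean_imp <- impute_missing(g, "mean")
  expect_equal(mean_imp[1, ], c(0, 2, 1))
  maj_imp <- impute_missing(g, "major_allele")
  expect_equal(maj_imp[2, ], c(0, 0, 0))
  expect_identical(impute_missing(g, "mean")[3, ], g$codes[3, ])
  g_nomiss <- tiny_geno()
  g_nomiss$codes[2, 2] <- 1
  expect_identical(impute_missing(g_nomiss, "mean"), g_nomiss$codes)
})

test_that("sample alignment intersects ids, drops missing phenotypes, deterministically", {
  g <- tiny_geno()
  ph <- phenotype_data(c("B", "C", "D", "E"), c(1.5, NA, 2.5, 9))
  al <- align_samples(g, ph)
  expect_identical(al$ids, c("B", "D"))
  expect_equal(unname(al$y), c(1.5, 2.5))
  expect_identical(al$geno$individual_ids, c("B", "D"))

  # shuffled input order gives the same alignment
  ph2 <- phenotype_data(c("E", "D", "C", "B"), c(9, 2.5, NA, 1.5))
  al2 <- align_samples(g, ph2)
  expect_identical(al2$ids, al$ids)
  expect_equal(al2$y, al$y)

  expect_error(align_samples(g, phenotype_data("Z", 1)), "no analyzable")
  cv <- covariate_data(c("B", "D"), matrix(5, 2, 1))
  expect_error(align_samples(g, ph, cv), "constant covariate")
})
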