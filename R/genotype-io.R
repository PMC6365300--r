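# Readers and writers for the tool's tabular dialects and PLINK bed/bim/fam.
#
# numeric_table dialect: tab- or comma-separated, header row of individual
# ids; first three columns marker_id, chromosome, position; remaining cells
# in {0,1,2} or a missing token ("NA", "N", "-9", ".").
#
# PLINK .bed: variant-major binary (magic 0x6c 0x1b 0x01), two bits per
# call; codes here count copies of the .bim A1 allele (het -> 1,
# homozygous A1 -> 2, missing -> NA).

.missing_tokens <- c("NA", "N", "-9", ".", "")

#' Read genotypes from a numeric table or a PLINK .bed fileset
#'
#' @param path for `numeric_table`, the table file; for `plink_bed`, the
#'   `.bed` file (the `.bim`/`.fam` companions are found by extension swap).
#' @param format `"numeric_table"` or `"plink_bed"`.
#' @return A [genotype_data] object (map sorted by chromosome, position).
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("numeric_table", "plink_bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         numeric_table = .read_numeric_table(path),
         plink_bed = .read_plink_bed(path))
}

.read_numeric_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("parse error at line 1: empty genotype table")
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  if (length(header) < 4L)
    stop("parse error at line 1: expected marker_id, chromosome, position + individuals")
  ids <- header[-(1:3)]
  n <- length(ids)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  m <- length(body)
  codes <- matrix(NA_real_, m, n)
  marker_id <- character(m); chrom <- character(m); pos <- integer(m)
  for (k in seq_len(m)) {
    f <- strsplit(body[[k]], sep, fixed = TRUE)[[1L]]
    if (length(f) != n + 3L)
      stop("parse error at line ", k + 1L, ": expected ", n + 3L,
           " fields, found ", length(f))
    marker_id[k] <- f[[1L]]; chrom[k] <- f[[2L]]
    p <- suppressWarnings(as.integer(f[[3L]]))
    if (is.na(p)) stop("parse error at line ", k + 1L, ": bad position '", f[[3L]], "'")
    pos[k] <- p
    cells <- trimws(f[-(1:3)])
    v <- suppressWarnings(as.numeric(cells))
    v[cells %in% .missing_tokens] <- NA_real_
    bad <- !is.na(v) & !(v %in% c(0, 1, 2))
    v[is.na(v)] <- NA_real_  # unknown characters become missing
    if (any(bad))
      stop("parse error at line ", k + 1L, ": genotype code '",
           cells[which(bad)[1L]], "' not in {0,1,2}")
    codes[k, ] <- v
  }
  genotype_data(codes,
                data.frame(marker_id = marker_id, chromosome = chrom,
                           position = pos, stringsAsFactors = FALSE),
                ids)
}

#' Write genotypes
#'
#' Round-trips with [read_genotypes()]: write then read reproduces codes
#' and map exactly (up to the map sort applied on load).
#'
#' @param geno a [genotype_data] object.
#' @param path output path (`.bed` path for `plink_bed`).
#' @param format output dialect.
#' @param sep field separator for the numeric table.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("numeric_table", "plink_bed"),
                            sep = "\t") {
  format <- match.arg(format)
  if (format == "numeric_table") {
    header <- paste(c("marker_id", "chromosome", "position", geno$individual_ids),
                    collapse = sep)
    body <- vapply(seq_len(n_markers(geno)), function(k) {
      v <- geno$codes[k, ]
      cells <- ifelse(is.na(v), "NA", format(v, trim = TRUE, scientific = FALSE))
      paste(c(geno$map$marker_id[k], geno$map$chromosome[k],
              geno$map$position[k], cells), collapse = sep)
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    .write_plink_bed(geno, path)
  }
  invisible(path)
}

# --- PLINK bed/bim/fam -------------------------------------------------------

.plink_companions <- function(bed_path) {
  stem <- sub("\\.bed$", "", bed_path)
  list(bed = bed_path, bim = paste0(stem, ".bim"), fam = paste0(stem, ".fam"))
}

.read_plink_bed <- function(bed_path) {
  p <- .plink_companions(bed_path)
  for (f in unlist(p))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- utils::read.table(p$bim, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(p$fam, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(bim); n <- nrow(fam)
  ids <- as.character(fam[[2L]])
  raw <- readBin(p$bed, "raw", n = 3L + ceiling(n / 4) * m)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed_path)
  if (raw[3L] != as.raw(0x01))
    stop("only variant-major .bed files are supported: ", bed_path)
  body <- raw[-(1:3)]
  bpv <- ceiling(n / 4)  # bytes per variant
  if (length(body) < bpv * m)
    stop("truncated .bed file: expected ", bpv * m, " data bytes, found ",
         length(body))
  # decode the 4 two-bit calls of every byte: 00 hom A1 (2), 01 missing,
  # 10 het (1), 11 hom A2 (0)
  lut <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  ints <- as.integer(body[seq_len(bpv * m)])
  two_bits <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                    (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  calls <- matrix(lut[as.character(as.vector(two_bits))], nrow = 4L * bpv)
  codes <- matrix(t(calls)[, seq_len(n), drop = FALSE], m, n)  # drop pad calls
  genotype_data(codes,
                data.frame(marker_id = bim[[2L]], chromosome = bim[[1L]],
                           position = as.integer(bim[[4L]]),
                           stringsAsFactors = FALSE),
                ids)
}

.write_plink_bed <- function(geno, bed_path) {
  p <- .plink_companions(bed_path)
  m <- n_markers(geno); n <- n_individuals(geno)
  # bim: chrom, id, cM (0), bp, A1, A2
  utils::write.table(
    data.frame(geno$map$chromosome, geno$map$marker_id, 0,
               geno$map$position, "A", "G"),
    p$bim, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(geno$individual_ids, geno$individual_ids, 0, 0, 0, -9),
    p$fam, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  enc <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # inverse of the read LUT
  bpv <- ceiling(n / 4)
  out <- raw(3L + bpv * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (k in seq_len(m)) {
    v <- geno$codes[k, ]
    b2 <- ifelse(is.na(v), 1L, enc[as.character(v)])
    b2 <- c(b2, integer(4L * bpv - n))     # pad tail with 0b00
    byte <- b2[c(TRUE, FALSE, FALSE, FALSE)] +
      4L * b2[c(FALSE, TRUE, FALSE, FALSE)] +
      16L * b2[c(FALSE, FALSE, TRUE, FALSE)] +
      64L * b2[c(FALSE, FALSE, FALSE, TRUE)]
    out[3L + (k - 1L) * bpv + seq_len(bpv)] <- as.raw(byte)
  }
  writeBin(out, p$bed)
  invisible(bed_path)
}

# --- phenotype / covariate tables -------------------------------------------

#' Read a phenotype table
#'
#' Header row; first column individual id; one numeric trait column is
#' analyzed per run (`trait` selects it by name or position).
#'
#' @param path file path (tab- or comma-separated, sniffed from the header).
#' @param trait column name or index (after the id column); default first.
#' @return list with `individual_ids` and numeric `values` (NA allowed),
#'   class `phenotype_data`.
#' @export
read_phenotypes <- function(path, trait = 1L) {
  tab <- .read_id_table(path)
  if (ncol(tab) < 2L) stop("phenotype table needs an id column plus a trait")
  vals <- if (is.character(trait)) tab[[trait]] else tab[[trait + 1L]]
  phenotype_data(as.character(tab[[1L]]), as.numeric(vals))
}

#' Phenotype container
#' @param individual_ids character vector.
#' @param values numeric vector, same length, NA allowed.
#' @return `phenotype_data` object.
#' @export
phenotype_data <- function(individual_ids, values) {
  individual_ids <- as.character(individual_ids)
  values <- as.numeric(values)
  if (length(values) != length(individual_ids))
    stop("phenotype length does not match ids")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  structure(list(individual_ids = individual_ids, values = values),
            class = "phenotype_data")
}

#' Read a covariate table (no intercept column)
#' @param path file path; header row, first column individual id, remaining
#'   columns numeric.
#' @return `covariate_data` object: `individual_ids` plus numeric matrix `X`.
#' @export
read_covariates <- function(path) {
  tab <- .read_id_table(path)
  X <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  covariate_data(as.character(tab[[1L]]), X)
}

#' Covariate container
#' @param individual_ids character vector.
#' @param X numeric matrix (individuals x covariates), zero columns allowed.
#' @return `covariate_data` object.
#' @export
covariate_data <- function(individual_ids, X) {
  individual_ids <- as.character(individual_ids)
  X <- as.matrix(X)
  if (length(individual_ids) != nrow(X) && ncol(X) > 0L)
    stop("covariate rows do not match ids")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  structure(list(individual_ids = individual_ids, X = X),
            class = "covariate_data")
}

.read_id_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
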