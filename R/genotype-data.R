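#' Genotype container: additive codes plus a marker map
#'
#' Constructs the package's genotype container. Genotypes are stored
#' marker-by-individual (markers as rows) because every downstream
#' computation streams over markers. Codes are additive allele counts
#' 0/1/2 with `NA` for missing calls. The map is sorted by
#' (chromosome, position) on construction and the code rows are
#' reordered with it.
#'
#' @param codes numeric matrix, markers x individuals, entries in
#'   \{0, 1, 2, NA\}.
#' @param map data.frame with columns `marker_id` (character, unique),
#'   `chromosome` (character) and `position` (positive integer base pairs,
#'   1-based as in the PLINK .bim convention).
#' @param individual_ids character vector, unique, one per column of `codes`.
#' @return An object of class `genotype_data`: a list with elements
#'   `codes`, `map`, `individual_ids`.
#' @examples
#' g <- genotype_data(
#'   codes = rbind(c(0, 1, 2), c(2, 2, 0)),
#'   map = data.frame(marker_id = c("m1", "m2"), chromosome = "1",
#'                    position = c(100L, 50L)),
#'   individual_ids = c("a", "b", "c"))
#' g$map$marker_id  # sorted by position: m2 first
#' @export
genotype_data <- function(codes, map, individual_ids) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (!is.data.frame(map)) stop("`map` must be a data.frame")
  req <- c("marker_id", "chromosome", "position")
  if (!all(req %in% names(map)))
    stop("`map` needs columns marker_id, chromosome, position")
  map <- data.frame(marker_id = as.character(map$marker_id),
                    chromosome = as.character(map$chromosome),
                    position = as.integer(map$position),
                    stringsAsFactors = FALSE)
  if (nrow(map) != nrow(codes))
    stop("map has ", nrow(map), " rows but codes has ", nrow(codes))
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != ncol(codes))
    stop("individual_ids length does not match number of genotype columns")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids")
  if (any(map$position < 0, na.rm = TRUE))
    stop("positions must be non-negative")
  bad <- !(codes %in% c(0, 1, 2) | is.na(codes))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(utils::head(unique(codes[bad]), 3), collapse = ", "))
  ord <- order(map$chromosome, map$position, map$marker_id)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  structure(list(codes = codes[ord, , drop = FALSE],
                 map = map,
                 individual_ids = individual_ids),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$codes), "markers x",
      ncol(x$codes), "individuals on",
      length(unique(x$map$chromosome)), "chromosome(s)\n")
  nmiss <- sum(is.na(x$codes))
  if (nmiss > 0)
    cat("  missing calls:", nmiss,
        sprintf("(%.2f%%)", 100 * nmiss / length(x$codes)), "\n")
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$codes)

#' Number of markers / individuals
#' @param geno a `genotype_data` object.
#' @return integer count.
#' @export
n_markers <- function(geno) nrow(geno$codes)

#' @rdname n_markers
#' @export
n_individuals <- function(geno) ncol(geno$codes)

#' Subset a genotype container by marker and/or individual
#'
#' @param x `genotype_data`.
#' @param i marker index (integer/logical) or NULL for all.
#' @param j individual index or NULL for all.
#' @param ... ignored.
#' @return `genotype_data` restricted to the selection.
#' @export
`[.genotype_data` <- function(x, i = NULL, j = NULL, ...) {
  if (is.null(i)) i <- seq_len(nrow(x$codes))
  if (is.null(j)) j <- seq_len(ncol(x$codes))
  genotype_data(x$codes[i, j, drop = FALSE], x$map[i, , drop = FALSE],
                x$individual_ids[j])
}
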