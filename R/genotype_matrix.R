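#' Construct a line-panel genotype matrix
#'
#' The central genotype container: biallelic SNP calls for a panel of inbred
#' lines.  Calls are coded per (line, SNP) as `0` (homozygous reference), `2`
#' (homozygous alternate), `1` (heterozygous, i.e. still segregating within
#' the line) and `NA` (missing).
#'
#' @param calls integer matrix, lines in rows, SNPs in columns, values in
#'   `{0, 1, 2, NA}`.
#' @param snps data frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`; one row per SNP, positions strictly increasing within chromosome.
#' @param line_ids character vector of line identifiers (row names).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `snps` (with a `maf` column added, see [snp_maf()]) and
#'   `line_ids`.
#' @export
genotype_matrix <- function(calls, snps, line_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps <- as.data.frame(snps)
  stopifnot(is.character(line_ids) || is.factor(line_ids))
  line_ids <- as.character(line_ids)
  if (nrow(calls) != length(line_ids))
    stop("call matrix has ", nrow(calls), " rows but ", length(line_ids), " line ids")
  if (ncol(calls) != nrow(snps))
    stop("call matrix has ", ncol(calls), " columns but ", nrow(snps), " SNP records")
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(snps))
  if (length(miss)) stop("snps table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(line_ids)) stop("duplicate line ids")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  key <- paste(snps$chrom, snps$pos)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos): ", key[duplicated(key)][1])
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  rownames(calls) <- line_ids
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  rownames(snps) <- NULL
  g <- structure(list(calls = calls, snps = snps, line_ids = line_ids),
                 class = "genotype_matrix")
  g$snps$maf <- snp_maf(g)
  g
}

#' Minor-allele frequencies of a genotype matrix
#'
#' Computed from homozygous calls only: heterozygous and missing calls are
#' excluded, so the frequency reflects the between-line allele frequency of
#' the fixed portion of the panel.  Always folded to `[0, 0.5]`.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector, one value per SNP (`NA` where no homozygous call).
#' @export
snp_maf <- function(g) {
  calls <- g$calls
  hom <- calls == 0L | calls == 2L
  n_alt <- colSums(calls == 2L & hom, na.rm = TRUE)
  n_hom <- colSums(hom, na.rm = TRUE)
  f <- ifelse(n_hom > 0, n_alt / n_hom, NA_real_)
  pmin(f, 1 - f)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i line index (logical, integer or character).
#' @param j SNP index (logical or integer).
#' @param ... ignored.
#' @return a [genotype_matrix()] restricted to the selected lines and SNPs.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$line_ids)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(i)) i <- match(i, x$line_ids)
  genotype_matrix(x$calls[i, j, drop = FALSE], x$snps[j, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                  x$line_ids[i])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$line_ids), "lines x", nrow(x$snps), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  nhet <- sum(x$calls == 1L, na.rm = TRUE)
  nmis <- sum(is.na(x$calls))
  cat(sprintf("  heterozygous calls: %d (%.2f%%), missing: %d (%.2f%%)\n",
              nhet, 100 * nhet / length(x$calls), nmis, 100 * nmis / length(x$calls)))
  invisible(x)
}

#' Per-line residual heterozygosity
#'
#' Fraction of non-missing calls per line that are heterozygous, the standard
#' summary of residual within-line segregation after inbreeding.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector, one fraction per line.
#' @export
residual_heterozygosity <- function(g) {
  het <- rowSums(g$calls == 1L, na.rm = TRUE)
  tot <- rowSums(!is.na(g$calls))
  setNames(ifelse(tot > 0, het / tot, NA_real_), g$line_ids)
}
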