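#' Read a genotype matrix from VCF
#'
#' Reads a VCF with one sample column per inbred line.  Only biallelic SNP
#' records are kept; multi-allelic records and records whose alleles are not
#' single nucleotides are dropped and counted.  Half-calls (`./1`) and empty
#' genotype fields become missing; haploid calls (`0`, `1`) are accepted and
#' coded as the corresponding homozygote.
#'
#' @param vcf_source path to a VCF 4.x file (plain or gzipped).
#' @return a [genotype_matrix()] with attribute `"dropped"` giving the number
#'   of non-biallelic records removed.
#' @export
read_genotype_matrix <- function(vcf_source) {
  if (!file.exists(vcf_source)) stop("no such VCF file: ", vcf_source)
  v <- tryCatch(vcfR::read.vcfR(vcf_source, verbose = FALSE),
                error = function(e) stop("malformed VCF '", vcf_source, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ok <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  dropped <- sum(!ok)
  if (!any(ok)) stop("no biallelic SNP records in ", vcf_source)
  key <- paste(chrom[ok], pos[ok])
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) record: ", key[duplicated(key)][1])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(chrom))
  gt <- gt[ok, , drop = FALSE]
  calls <- apply(gt, 2, gt_to_code)
  if (is.null(dim(calls))) calls <- matrix(calls, ncol = ncol(gt))
  g <- genotype_matrix(t(calls),
                       data.frame(chrom = chrom[ok], pos = pos[ok],
                                  ref = ref[ok], alt = alt[ok],
                                  stringsAsFactors = FALSE),
                       colnames(gt))
  attr(g, "dropped") <- dropped
  g
}

gt_to_code <- function(gt) {
  gt <- sub(":.*", "", gt)
  code <- rep(NA_integer_, length(gt))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code[gt %in% c("0/0", "0")] <- 0L
  code[gt %in% c("1/1", "1")] <- 2L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCF 4.2 file (GT field only) that [read_genotype_matrix()]
#' reads back to an identical call matrix.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(g, path) {
  gt_str <- matrix("./.", nrow(g$snps), length(g$line_ids))
  codes <- t(g$calls)
  gt_str[codes == 0L] <- "0/0"
  gt_str[codes == 1L] <- "0/1"
  gt_str[codes == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=linepanel",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$line_ids), collapse = "\t"))
  body <- paste(g$snps$chrom, g$snps$pos,
                paste0(g$snps$chrom, "_", g$snps$pos),
                g$snps$ref, g$snps$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a brood-level phenotype table
#'
#' Expects a CSV with header columns `line_id`, `female_id`, `n_males`,
#' `n_females`.  Zero-clutch rows (no offspring of either sex) are dropped
#' and counted.
#'
#' @param csv_source path to the CSV file, or a data frame with the same
#'   columns.
#' @return data frame of class `brood_table` with added columns
#'   `clutch_size` and `sex_ratio` (proportion male); attribute
#'   `"dropped_zero_clutch"` counts removed rows.
#' @export
read_brood_table <- function(csv_source) {
  d <- if (is.data.frame(csv_source)) csv_source else read.csv(csv_source, stringsAsFactors = FALSE)
  req <- c("line_id", "female_id", "n_males", "n_females")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("brood table missing columns: ", paste(miss, collapse = ", "))
  if (any(d$n_males < 0 | d$n_females < 0, na.rm = TRUE))
    stop("negative offspring counts in brood table")
  if (any(is.na(d$n_males) | is.na(d$n_females)))
    stop("missing offspring counts in brood table")
  keep <- (d$n_males + d$n_females) > 0
  dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  d$line_id <- as.character(d$line_id)
  d$clutch_size <- d$n_males + d$n_females
  d$sex_ratio <- d$n_males / d$clutch_size
  rownames(d) <- NULL
  class(d) <- c("brood_table", "data.frame")
  attr(d, "dropped_zero_clutch") <- dropped
  d
}

#' Read line metadata
#'
#' @param csv_source path to a CSV with columns `line_id`,
#'   `wolbachia_positive` (logical), `excluded` (logical) and optionally
#'   `reason`; or a data frame with those columns.
#' @return data frame with those columns, `reason` filled with `""`.
#' @export
read_line_metadata <- function(csv_source) {
  d <- if (is.data.frame(csv_source)) csv_source else read.csv(csv_source, stringsAsFactors = FALSE)
  req <- c("line_id", "wolbachia_positive", "excluded")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  d$line_id <- as.character(d$line_id)
  d$wolbachia_positive <- as.logical(d$wolbachia_positive)
  d$excluded <- as.logical(d$excluded)
  if (is.null(d$reason)) d$reason <- ""
  d
}

#' Apply the line-panel GWAS filters
#'
#' Reproduces the standard filtering cascade for iso-female line association
#' panels, in this order:
#' 1. drop lines flagged `excluded` or not `wolbachia_positive`;
#' 2. set heterozygous (within-line segregating) calls to missing;
#' 3. drop SNPs fixed for one allele across the retained lines;
#' 4. drop SNPs with fewer than `min_called_lines` non-missing calls;
#' 5. drop SNPs with minor-allele frequency below `maf_min`.
#'
#' @param g a [genotype_matrix()].
#' @param meta line metadata as from [read_line_metadata()]; `NULL` keeps all
#'   lines.
#' @param min_called_lines minimum number of lines with a non-missing call
#'   per retained SNP (default 18).
#' @param maf_min minor-allele frequency threshold (default 0.04).
#' @return filtered [genotype_matrix()] with attribute `"filter_log"`: a data
#'   frame (step, removed, remaining) auditing each step.  SNP counts refer
#'   to SNPs, the first step's to lines.
#' @export
apply_gwas_filters <- function(g, meta = NULL, min_called_lines = 18, maf_min = 0.04) {
  log <- data.frame(step = character(), removed = integer(), remaining = integer(),
                    stringsAsFactors = FALSE)
  add <- function(step, removed, remaining)
    rbind(log, data.frame(step = step, removed = removed, remaining = remaining))

  keep_lines <- rep(TRUE, length(g$line_ids))
  if (!is.null(meta)) {
    m <- meta[match(g$line_ids, meta$line_id), ]
    keep_lines <- !is.na(m$line_id) & m$wolbachia_positive & !m$excluded
  }
  if (!any(keep_lines)) stop("no lines retained after metadata exclusion")
  if (min_called_lines > sum(keep_lines))
    stop("min_called_lines (", min_called_lines, ") exceeds retained line count (",
         sum(keep_lines), ")")
  calls <- g$calls[keep_lines, , drop = FALSE]
  log <- add("exclude_lines", sum(!keep_lines), sum(keep_lines))

  n_het <- sum(calls == 1L, na.rm = TRUE)
  calls[calls == 1L] <- NA_integer_
  log <- add("mask_heterozygotes", n_het, ncol(calls))

  n_call <- colSums(!is.na(calls))
  n_alt <- colSums(calls == 2L, na.rm = TRUE)
  fixed <- n_call == 0L | n_alt == 0L | n_alt == n_call
  calls <- calls[, !fixed, drop = FALSE]
  log <- add("remove_fixed", sum(fixed), ncol(calls))

  n_call <- colSums(!is.na(calls))
  low_call <- n_call < min_called_lines
  calls <- calls[, !low_call, drop = FALSE]
  log <- add("min_called_lines", sum(low_call), ncol(calls))

  n_call <- colSums(!is.na(calls))
  n_alt <- colSums(calls == 2L, na.rm = TRUE)
  maf <- pmin(n_alt / n_call, 1 - n_alt / n_call)
  low_maf <- maf < maf_min
  calls <- calls[, !low_maf, drop = FALSE]
  log <- add("min_maf", sum(low_maf), ncol(calls))

  if (ncol(calls) == 0L) stop("no SNPs survive the GWAS filters")
  keep_snps <- which(!fixed)[!low_call][!low_maf]
  out <- genotype_matrix(calls, g$snps[keep_snps, c("chrom", "pos", "ref", "alt")],
                         g$line_ids[keep_lines])
  attr(out, "filter_log") <- log
  out
}

#' Write a filter log as TSV
#'
#' @param g a filtered [genotype_matrix()] carrying a `"filter_log"` attribute.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(g, path) {
  log <- attr(g, "filter_log")
  if (is.null(log)) stop("object carries no filter log")
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
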