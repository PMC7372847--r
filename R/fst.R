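#' Pairwise line F_ST matrix
#'
#' Hudson-style estimator between every pair of lines, treating each line as
#' a population of two chromosomes: a homozygous call is allele frequency 0
#' or 1, a heterozygous (still segregating) call frequency 0.5.  Per site,
#' with frequencies p1 and p2 and n1 = n2 = 2 sampled chromosomes,
#' \deqn{N = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1),}
#' \deqn{D = p_1(1-p_2) + p_2(1-p_1),}
#' and the pair's F_ST is the ratio of averages `sum(N)/sum(D)` over sites
#' variable within the pair.  Negative ratios are clamped to 0 for
#' reporting; pairs with no variable site get `NA` and are counted.
#'
#' @param g a [genotype_matrix()].
#' @return object of class `fst_matrix`: list with `fst` (symmetric matrix,
#'   zero diagonal), `n_sites` (variable sites per pair) and `n_na_pairs`.
#' @export
pairwise_fst <- function(g) {
  nl <- length(g$line_ids)
  if (nl < 2) stop("need at least two lines")
  freq <- g$calls / 2                      # 0, 0.5, 1 or NA
  fst <- matrix(0, nl, nl, dimnames = list(g$line_ids, g$line_ids))
  nsites <- matrix(0L, nl, nl, dimnames = dimnames(fst))
  for (i in seq_len(nl - 1)) {
    for (j in (i + 1):nl) {
      p1 <- freq[i, ]; p2 <- freq[j, ]
      ok <- !is.na(p1) & !is.na(p2)
      variable <- ok & !(p1 == p2 & (p1 == 0 | p1 == 1))
      p1 <- p1[variable]; p2 <- p2[variable]
      nsites[i, j] <- nsites[j, i] <- length(p1)
      if (!length(p1)) {
        fst[i, j] <- fst[j, i] <- NA_real_
        next
      }
      num <- (p1 - p2)^2 - p1 * (1 - p1) - p2 * (1 - p2)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      fst[i, j] <- fst[j, i] <- max(0, sum(num) / sum(den))
    }
  }
  structure(list(fst = fst, n_sites = nsites,
                 n_na_pairs = sum(is.na(fst[upper.tri(fst)]))),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  v <- x$fst[upper.tri(x$fst)]
  cat("fst_matrix:", nrow(x$fst), "lines;",
      sprintf("mean pairwise F_ST = %.3f (sd %.3f, range %.3f-%.3f)\n",
              mean(v, na.rm = TRUE), sd(v, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  if (x$n_na_pairs) cat("  pairs with no variable site:", x$n_na_pairs, "\n")
  invisible(x)
}

#' Complete-linkage clustering of lines by F_ST
#'
#' @param f a [pairwise_fst()] result (no missing entries allowed).
#' @return an [stats::hclust] dendrogram.
#' @export
cluster_lines <- function(f) {
  if (any(is.na(f$fst))) stop("F_ST matrix has missing entries; cannot cluster")
  hclust(as.dist(f$fst), method = "complete")
}

#' Population-structure check: F_ST versus phenotype distance
#'
#' Spearman rank correlation between off-diagonal pairwise F_ST and the
#' pairwise absolute difference in line phenotype means.  A material
#' positive correlation indicates that genetic structure is confounded with
#' the phenotype and a GWAS would need a relatedness correction; a null
#' result justifies the uncorrected single-marker scan.
#'
#' @param f a [pairwise_fst()] result.
#' @param line_means named numeric vector of per-line phenotype means
#'   (names matching the F_ST matrix lines).
#' @return list of class `structure_check`: `rho`, `p_value`, `n_pairs`,
#'   `tied` (TRUE when the phenotype distances are completely tied, in
#'   which case `rho` is reported as 0).
#' @export
structure_check <- function(f, line_means) {
  ids <- rownames(f$fst)
  if (length(ids) < 3) stop("need at least three lines")
  if (is.null(names(line_means))) {
    if (length(line_means) != length(ids)) stop("line_means length mismatch")
    names(line_means) <- ids
  }
  if (!all(ids %in% names(line_means))) stop("line_means missing some lines")
  m <- line_means[ids]
  ut <- upper.tri(f$fst)
  dphen <- abs(outer(m, m, "-"))[ut]
  dfst <- f$fst[ut]
  ok <- !is.na(dfst)
  if (sd(dphen[ok]) == 0) {
    res <- list(rho = 0, p_value = NA_real_, n_pairs = sum(ok), tied = TRUE)
  } else {
    ct <- suppressWarnings(cor.test(dfst[ok], dphen[ok], method = "spearman",
                                    exact = FALSE))
    res <- list(rho = unname(ct$estimate), p_value = ct$p.value,
                n_pairs = sum(ok), tied = FALSE)
  }
  class(res) <- "structure_check"
  res
}

#' @export
print.structure_check <- function(x, ...) {
  cat(sprintf("structure check: Spearman's r_s = %.3f, P = %s over %d line pairs\n",
              x$rho, format.pval(x$p_value, digits = 3), x$n_pairs))
  if (x$tied) cat("  (phenotype distances completely tied; r_s reported as 0)\n")
  invisible(x)
}
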