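# Windowed cross-trait overlap testing: do the most-associated SNPs for two
# traits coincide within genomic windows more than expected by chance?

#' Exact two-set intersection probability
#'
#' Upper-tail probability `P(X >= k)` that two random subsets of sizes `na`
#' and `nb` drawn from a universe of `n_universe` elements share at least
#' `k` elements; `X` is hypergeometric.  This is the two-set case of the
#' multi-set exact intersection test.
#'
#' @param k observed overlap.
#' @param na,nb subset sizes.
#' @param n_universe universe size.
#' @return the exact p-value in (0, 1]; `k = 0` gives 1.
#' @examples
#' overlap_exact_p(5, 5, 5, 10)   # 1/choose(10,5)
#' @export
overlap_exact_p <- function(k, na, nb, n_universe) {
  if (any(na > n_universe | nb > n_universe | k > pmin(na, nb) | k < 0 |
          na < 0 | nb < 0))
    stop("inconsistent set sizes")
  phyper(k - 1, nb, n_universe - nb, na, lower.tail = FALSE)
}

# Per-window summary p: SNPs ranked by p separately per trait (ties broken
# by position order); for each cutoff r the top-r sets are intersected and
# tested exactly; the summary is the minimum exact p over cutoffs.
# Vectorised: a SNP enters the intersection at r = max(rankA, rankB), so
# the overlap counts over r are a cumulative tabulation.
window_summary_p <- function(rank_a, rank_b, n, r_max) {
  r <- seq_len(min(r_max, n))
  m <- pmax(rank_a, rank_b)
  k_r <- cumsum(tabulate(m[m <= max(r)], nbins = max(r)))
  p_r <- phyper(k_r - 1, r, n - r, r, lower.tail = FALSE)
  min(p_r)
}

#' Windowed rank-overlap scan for two traits
#'
#' Splits each chromosome into non-overlapping windows of every size in
#' `window_sizes`.  Within a window, SNPs are ranked by p-value separately
#' per trait; for each cutoff r in `1..min(max_rank, N)` the top-r SNP sets
#' of the two traits are intersected and the overlap tested exactly against
#' the hypergeometric null with universe N = SNPs in the window.  The
#' window's summary p is the minimum exact p over cutoffs (selection over
#' cutoffs is absorbed later by the permutation null of
#' [overlap_permutation()], which applies the same minimum).
#'
#' @param res_a,res_b `gwas_result` tables over the same SNPs (matched by
#'   `snp_id`).
#' @param window_sizes window sizes in bp.
#' @param max_rank largest rank cutoff (default 25).
#' @return data frame of class `overlap_scan`: `chrom`, `start`, `end`,
#'   `size`, `n_snps`, `summary_p`; windows with < 2 SNPs are skipped and
#'   counted in attribute `"skipped"`.
#' @export
window_scan <- function(res_a, res_b,
                        window_sizes = c(25, 50, 100, 200, 400) * 1000,
                        max_rank = 25) {
  ab <- match_results(res_a, res_b)
  dt <- data.table::data.table(chrom = ab$chrom, pos = ab$pos,
                               pa = ab$pa, pb = ab$pb)
  out <- list(); skipped <- 0L
  for (ws in window_sizes) {
    dt[, win := (pos - 1) %/% ws]
    grp <- dt[, {
      n <- .N
      if (n < 2) list(start = NA_real_, n_snps = n, summary_p = NA_real_)
      else {
        o <- order(pa, pos); ra <- integer(n); ra[o] <- seq_len(n)
        o <- order(pb, pos); rb <- integer(n); rb[o] <- seq_len(n)
        list(start = as.numeric(win[1] * ws + 1), n_snps = n,
             summary_p = window_summary_p(ra, rb, n, max_rank))
      }
    }, by = .(chrom, win)]
    skipped <- skipped + sum(is.na(grp$summary_p))
    grp <- grp[!is.na(grp$summary_p)]
    out[[length(out) + 1]] <- data.frame(
      chrom = grp$chrom, start = as.integer(grp$win * ws + 1),
      end = as.integer((grp$win + 1) * ws), size = ws, n_snps = grp$n_snps,
      summary_p = grp$summary_p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  attr(res, "max_rank") <- max_rank
  class(res) <- c("overlap_scan", "data.frame")
  res
}

match_results <- function(res_a, res_b) {
  idx <- match(res_a$snp_id, res_b$snp_id)
  if (anyNA(idx)) stop("the two result sets do not cover the same SNPs")
  ok <- !is.na(res_a$p_value) & !is.na(res_b$p_value[idx])
  list(chrom = res_a$chrom[ok], pos = res_a$pos[ok],
       pa = res_a$p_value[ok], pb = res_b$p_value[idx][ok])
}

#' SNP-identity permutation null for the overlap scan
#'
#' Repeats the window scan on datasets in which SNP identities are permuted:
#' each SNP's (p_a, p_b) pair is kept intact but reassigned to a random
#' position, preserving both traits' p-value multisets, their genome-wide
#' coupling, and every window's SNP count, while destroying the local
#' assignment of p-values to windows.  A window is flagged significant when
#' its observed summary p is strictly below all `n_perm` permuted summary
#' p-values.
#'
#' @param res_a,res_b `gwas_result` tables over the same SNPs.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param window_sizes,max_rank as in [window_scan()].
#' @return the [window_scan()] table with added columns `perm_min_p` (the
#'   smallest permuted summary p per window) and `significant`.
#' @export
overlap_permutation <- function(res_a, res_b, n_perm = 100, seed = 1L,
                                window_sizes = c(25, 50, 100, 200, 400) * 1000,
                                max_rank = 25) {
  obs <- window_scan(res_a, res_b, window_sizes, max_rank)
  ab <- match_results(res_a, res_b)
  n <- length(ab$pos)
  set.seed(seed)
  perm_min <- rep(Inf, nrow(obs))
  key_obs <- paste(obs$chrom, obs$start, obs$size)
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    res_pa <- data.frame(snp_id = paste0(ab$chrom, "_", ab$pos),
                         chrom = ab$chrom, pos = ab$pos,
                         p_value = ab$pa[perm], stringsAsFactors = FALSE)
    res_pb <- data.frame(snp_id = res_pa$snp_id, chrom = ab$chrom, pos = ab$pos,
                         p_value = ab$pb[perm], stringsAsFactors = FALSE)
    sc <- window_scan(res_pa, res_pb, window_sizes, max_rank)
    idx <- match(key_obs, paste(sc$chrom, sc$start, sc$size))
    perm_min <- pmin(perm_min, sc$summary_p[idx], na.rm = TRUE)
  }
  obs$perm_min_p <- perm_min
  obs$significant <- obs$summary_p < perm_min
  class(obs) <- c("overlap_scan", "data.frame")
  obs
}

#' Cumulative overlap curve for one window
#'
#' Returns, for plotting, the overlap count and exact p at every rank
#' cutoff within one window.
#'
#' @param res_a,res_b `gwas_result` tables.
#' @param chrom,start,end the window.
#' @param max_rank largest cutoff.
#' @return data frame: `r`, `k`, `exact_p`.
#' @export
overlap_curve <- function(res_a, res_b, chrom, start, end, max_rank = 25) {
  ab <- match_results(res_a, res_b)
  in_w <- ab$chrom == chrom & ab$pos >= start & ab$pos <= end
  n <- sum(in_w)
  if (n < 2) stop("window holds fewer than 2 SNPs")
  pa <- ab$pa[in_w]; pb <- ab$pb[in_w]; pos <- ab$pos[in_w]
  o <- order(pa, pos); ra <- integer(n); ra[o] <- seq_len(n)
  o <- order(pb, pos); rb <- integer(n); rb[o] <- seq_len(n)
  r <- seq_len(min(max_rank, n))
  m <- pmax(ra, rb)
  k <- cumsum(tabulate(m[m <= max(r)], nbins = max(r)))
  data.frame(r = r, k = k,
             exact_p = phyper(k - 1, r, n - r, r, lower.tail = FALSE))
}
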