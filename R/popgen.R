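#' Build pooled site counts from a genotype matrix
#'
#' Converts per-line calls into pooled per-site allele counts (two pseudo-
#' reads per homozygous line, one of each allele per heterozygous line),
#' the input expected by [subsample_coverage()] and [window_diversity()].
#'
#' @param g a [genotype_matrix()].
#' @return data frame of class `site_counts`: `chrom`, `pos`, `n_ref`,
#'   `n_alt`, `coverage`.
#' @export
site_counts_from_genotypes <- function(g) {
  n_ref <- colSums(2L * (g$calls == 0L) + 1L * (g$calls == 1L), na.rm = TRUE)
  n_alt <- colSums(2L * (g$calls == 2L) + 1L * (g$calls == 1L), na.rm = TRUE)
  d <- data.frame(chrom = g$snps$chrom, pos = g$snps$pos,
                  n_ref = n_ref, n_alt = n_alt, coverage = n_ref + n_alt,
                  stringsAsFactors = FALSE)
  class(d) <- c("site_counts", "data.frame")
  d
}

#' Read site counts from a TSV
#'
#' Accepts the package's own site-count format (columns `chrom`, `pos`,
#' `n_ref`, `n_alt`).
#'
#' @param path TSV path.
#' @return a `site_counts` data frame.
#' @export
read_site_counts <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "n_ref", "n_alt")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("site counts missing columns: ", paste(miss, collapse = ", "))
  d$coverage <- d$n_ref + d$n_alt
  class(d) <- c("site_counts", "data.frame")
  d
}

#' Subsample site coverage to a fixed target
#'
#' Standardises per-site coverage by resampling allele counts to exactly
#' `target` draws (with replacement by default, mirroring pooled-sequencing
#' practice).  Sites below `min_cov` or above `max_cov` are flagged unusable
#' and excluded from diversity windows.
#'
#' @param sites a `site_counts` data frame.
#' @param target target coverage (draws per site), default 20.
#' @param max_cov maximum raw coverage for a usable site, default 400.
#' @param min_cov minimum raw coverage for a usable site, default 10.
#' @param with_replacement sample with replacement (default `TRUE`); without
#'   replacement additionally requires raw coverage >= target.
#' @param seed integer seed for the resampling.
#' @return a `site_counts` data frame with counts resampled to `target` and
#'   a logical `usable` column.
#' @export
subsample_coverage <- function(sites, target = 20, max_cov = 400, min_cov = 10,
                               with_replacement = TRUE, seed = 1L) {
  stopifnot(target > 0)
  set.seed(seed)
  usable <- sites$coverage >= min_cov & sites$coverage <= max_cov
  if (!with_replacement) usable <- usable & sites$coverage >= target
  out <- sites
  n <- nrow(sites)
  new_ref <- integer(n); new_alt <- integer(n)
  idx <- which(usable)
  if (length(idx)) {
    pr <- sites$n_ref[idx] / sites$coverage[idx]
    if (with_replacement) {
      new_ref[idx] <- rbinom(length(idx), target, pr)
    } else {
      new_ref[idx] <- vapply(idx, function(i)
        sum(sample(rep(c(1L, 0L), c(sites$n_ref[i], sites$n_alt[i])), target)),
        integer(1))
    }
    new_alt[idx] <- target - new_ref[idx]
  }
  out$n_ref <- new_ref; out$n_alt <- new_alt
  out$coverage <- ifelse(usable, as.integer(target), 0L)
  out$usable <- usable
  class(out) <- c("site_counts", "data.frame")
  out
}

# Tajima's D constants for sample size n (draws).
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Window diversity statistics from pooled site counts
#'
#' Computes per-window nucleotide diversity (pi), Watterson's theta and
#' Tajima's D from coverage-standardised allele counts, using the classical
#' estimators at a fixed sample size `n = target draws`.  Alleles observed
#' fewer than `min_count` times at a site are treated as absent when
#' deciding whether the site segregates.  Windows covering less than
#' `min_covered_fraction` of their length with usable sites are omitted.
#' Per-site pi is `(n/(n-1)) * (1 - sum(f_i^2))`; theta per site is
#' `S / (a1 * L_covered)`; D uses the standard constants and is reported
#' missing (`NA`) when a window has no segregating site.
#'
#' @param sites subsampled `site_counts` (see [subsample_coverage()]); the
#'   `coverage` of usable sites must be constant (the subsampling target).
#' @param pool_size nominal number of pooled individuals (metadata only,
#'   recorded in the output).
#' @param window,step window and step size in bp; `step = window` gives
#'   non-overlapping windows (the default geometry).
#' @param min_count minimum allele count for a segregating allele, default 5.
#' @param min_covered_fraction minimum fraction of window positions with a
#'   usable site statistic, computed as usable sites / window length
#'   relative to `site_density` (see below), default 0.5.
#' @param site_density expected usable sites per bp used to turn site counts
#'   into a covered fraction; defaults to the genome-wide mean density of
#'   usable sites, so an average window has covered fraction ~1.
#' @param chrom_lengths optional named lengths to fix the window grid;
#'   defaults to the maximum observed position per chromosome.
#' @return data frame of class `window_diversity`: `chrom`, `start`, `end`,
#'   `n_sites`, `S`, `pi`, `theta`, `tajimas_d`, `covered_fraction`.
#' @export
window_diversity <- function(sites, pool_size = 60, window = 400000,
                             step = window, min_count = 5,
                             min_covered_fraction = 0.5, site_density = NULL,
                             chrom_lengths = NULL) {
  s <- sites[sites$usable %||% (sites$coverage > 0), , drop = FALSE]
  if (!nrow(s)) stop("no usable sites")
  n <- unique(s$coverage)
  if (length(n) != 1) stop("usable sites must share one coverage; run subsample_coverage() first")
  if (n < 2) stop("coverage must be at least 2 draws")
  k <- tajima_constants(n)
  minor <- pmin(s$n_ref, s$n_alt)
  seg <- minor >= min_count & minor > 0
  f_alt <- s$n_alt / n
  pi_site <- ifelse(seg, (n / (n - 1)) * (1 - f_alt^2 - (1 - f_alt)^2), 0)

  if (is.null(site_density)) {
    span <- sum(vapply(split(s$pos, s$chrom), function(p) diff(range(p)) + 1, numeric(1)))
    site_density <- nrow(s) / span
  }
  out <- list()
  for (ch in unique(s$chrom)) {
    sc <- s[s$chrom == ch, ]
    Lc <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(sc$pos)
    starts <- seq(1, max(1, Lc), by = step)
    for (st in starts) {
      en <- min(st + window - 1, Lc)
      in_w <- sc$pos >= st & sc$pos <= en
      nsite <- sum(in_w)
      covered <- min(1, nsite / (site_density * (en - st + 1)))
      if (covered < min_covered_fraction) next
      S <- sum(seg[s$chrom == ch][in_w])
      Lcov <- nsite
      pi_tot <- sum(pi_site[s$chrom == ch][in_w])
      theta <- S / (k$a1 * Lcov)
      D <- if (S > 0) {
        (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = st, end = en, n_sites = nsite, S = S,
        pi = pi_tot / Lcov, theta = theta, tajimas_d = D,
        covered_fraction = covered, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no window passed the covered-fraction filter")
  res <- do.call(rbind, out)
  attr(res, "pool_size") <- pool_size
  attr(res, "n_draws") <- n
  class(res) <- c("window_diversity", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write window diversity as TSV
#'
#' @param wd a [window_diversity()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_window_diversity <- function(wd, path) {
  write.table(as.data.frame(wd), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
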