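#' Pairwise r-squared within a distance cap
#'
#' Squared Pearson correlation of homozygous allele codes (0/1) between all
#' SNP pairs on the same chromosome within `max_dist` bp.  Heterozygous and
#' missing calls are excluded pairwise; pairs with fewer than `min_lines`
#' complete lines, or monomorphic within the complete-line subset, are
#' skipped and counted.
#'
#' @param g a [genotype_matrix()].
#' @param max_dist distance cap in bp (default 1e6).
#' @param min_lines minimum complete lines per pair (default 10).
#' @param focal optional integer vector of SNP column indices: only pairs
#'   involving a focal SNP are returned (used by [decay_landscape()]).
#' @return data frame of class `ld_pairs`: `i`, `j` (SNP column indices),
#'   `chrom`, `dist`, `r2`, `n_lines`; attribute `"skipped"` counts pairs
#'   dropped for too few complete lines or monomorphism.
#' @export
pairwise_r2 <- function(g, max_dist = 1e6, min_lines = 10, focal = NULL) {
  x <- g$calls / 2
  x[g$calls == 1L] <- NA            # within-line segregating -> missing
  chrom <- g$snps$chrom; pos <- g$snps$pos
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  skipped <- 0L
  ns <- ncol(x)
  acc <- vector("list", ns)
  for (i in seq_len(ns)) {
    jmax <- i
    while (jmax < ns && chrom[jmax + 1] == chrom[i] && pos[jmax + 1] - pos[i] <= max_dist)
      jmax <- jmax + 1
    if (jmax == i) next
    js <- (i + 1):jmax
    if (!is.null(focal)) js <- js[(i %in% focal) | (js %in% focal)]
    if (!length(js)) next
    m <- obs[, i] & obs[, js, drop = FALSE]
    xi <- x0[, i] * m
    xj <- x0[, js, drop = FALSE] * m
    n <- colSums(m)
    sx <- colSums(xi); sy <- colSums(xj)
    sxx <- colSums(xi^2); syy <- colSums(xj^2); sxy <- colSums(xi * xj)
    vx <- sxx - sx^2 / n; vy <- syy - sy^2 / n
    cv <- sxy - sx * sy / n
    keep <- n >= min_lines & vx > 0 & vy > 0
    skipped <- skipped + sum(!keep)
    if (!any(keep)) next
    acc[[i]] <- data.frame(i = i, j = js[keep],
                           r2 = (cv[keep] / sqrt(vx[keep] * vy[keep]))^2,
                           n_lines = n[keep])
  }
  res <- do.call(rbind, acc)
  if (is.null(res))
    res <- data.frame(i = integer(), j = integer(), r2 = numeric(), n_lines = integer())
  res <- data.frame(i = res$i, j = res$j, chrom = chrom[res$i],
                    dist = pos[res$j] - pos[res$i], r2 = res$r2,
                    n_lines = res$n_lines, stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  class(res) <- c("ld_pairs", "data.frame")
  res
}

#' Fit the hyperbolic LD decay model
#'
#' Nonlinear least squares fit of `r2 = 1 / (1 + p * x)` to observed pair
#' r-squared versus distance.  The model forces `r2(0) = 1`; any observed
#' shortfall at near-zero distance is absorbed by the fit (no intercept
#' term).  The fit is deterministic given the input: starting value
#' `p0 = 1 / median(distance)`, PORT algorithm with convergence tolerance
#' 1e-10 and lower bound `p >= 1e-14`.  A fit at the lower bound (all r2
#' near 1 at all distances) is flagged as a boundary fit.
#'
#' @param pairs an [pairwise_r2()] data frame (needs >= 10 pairs).
#' @return object of class `lddecay_fit`: `p` (per bp), `half_decay_bp`
#'   (`= 1/p` exactly), `n_pairs`, `rss`, `boundary`.
#' @export
fit_decay <- function(pairs) {
  if (nrow(pairs) < 10) stop("need at least 10 pairs to fit LD decay")
  d <- pairs$dist; r2 <- pairs$r2
  p0 <- 1 / median(d)
  fit <- tryCatch(
    nls(r2 ~ 1 / (1 + p * d), start = list(p = p0), algorithm = "port",
        lower = c(p = 1e-14), control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("LD decay fit did not converge (start p0 = ",
                             signif(p0, 4), "): ", conditionMessage(e),
                             call. = FALSE))
  p <- unname(coef(fit)["p"])
  new_lddecay_fit(p, n_pairs = nrow(pairs), rss = sum(resid(fit)^2),
                  boundary = p <= 1.0001e-14)
}

#' Construct an LD decay fit object directly
#'
#' Mostly useful to evaluate the model identities (e.g. level-crossing
#' distances) for a known decay rate.
#'
#' @param p decay rate per bp (> 0).
#' @param n_pairs,rss,boundary optional fit metadata.
#' @return an `lddecay_fit` object.
#' @export
new_lddecay_fit <- function(p, n_pairs = NA_integer_, rss = NA_real_,
                            boundary = FALSE) {
  stopifnot(p > 0)
  structure(list(p = p, half_decay_bp = 1 / p, n_pairs = n_pairs, rss = rss,
                 boundary = boundary),
            class = "lddecay_fit")
}

#' @export
print.lddecay_fit <- function(x, ...) {
  cat(sprintf("hyperbolic LD decay fit r2 = 1/(1 + p x): p = %.4g per bp\n", x$p))
  cat(sprintf("  half-decay distance 1/p = %.1f kb", x$half_decay_bp / 1000))
  if (!is.na(x$n_pairs)) cat(sprintf("  (%d pairs, rss %.3g)", x$n_pairs, x$rss))
  cat("\n")
  if (x$boundary) cat("  note: fit at lower boundary (no detectable decay)\n")
  invisible(x)
}

#' Distance at which the fitted LD curve crosses a given r-squared level
#'
#' Inverts `r2 = 1/(1 + p x)`: the crossing distance is
#' `(1/level - 1) / p`.  At `level = 0.5` this is the half-decay distance
#' `1/p` exactly.
#'
#' @param fit an `lddecay_fit`.
#' @param level target r-squared in (0, 1).
#' @return distance in bp.
#' @examples
#' fit <- new_lddecay_fit(1 / 17800)
#' distance_at_r2(fit, 0.5) / 1000   # 17.8 kb
#' @export
distance_at_r2 <- function(fit, level) {
  if (any(level <= 0 | level >= 1)) stop("level must lie strictly in (0, 1)")
  (1 / level - 1) / fit$p
}

#' Per-SNP LD half-decay landscape
#'
#' Fits the hyperbolic decay model separately for every focal SNP using the
#' r-squared of that SNP against all SNPs within `window_flank` bp up- and
#' downstream.  SNPs with fewer than 10 usable flanking pairs, or whose fit
#' fails, are reported missing.
#'
#' @param g a [genotype_matrix()].
#' @param max_dist flank distance in bp (default 1e6, i.e. 1 Mb either side).
#' @param min_lines minimum complete lines per pair.
#' @param pairs optionally, a precomputed [pairwise_r2()] table at the same
#'   `max_dist`.
#' @return data frame: `chrom`, `pos`, `n_pairs`, `p`, `half_decay_bp`,
#'   `log10_half_decay`.
#' @export
decay_landscape <- function(g, max_dist = 1e6, min_lines = 10, pairs = NULL) {
  if (is.null(pairs)) pairs <- pairwise_r2(g, max_dist, min_lines)
  ns <- nrow(g$snps)
  p <- rep(NA_real_, ns); np <- integer(ns)
  idx <- c(split(seq_len(nrow(pairs)), factor(pairs$i, levels = seq_len(ns))),
           split(seq_len(nrow(pairs)), factor(pairs$j, levels = seq_len(ns))))
  for (s in seq_len(ns)) {
    rows <- c(idx[[s]], idx[[ns + s]])
    np[s] <- length(rows)
    if (np[s] < 10) next
    sub <- pairs[rows, ]
    p[s] <- tryCatch(fit_decay(sub)$p, error = function(e) NA_real_)
  }
  data.frame(chrom = g$snps$chrom, pos = g$snps$pos, n_pairs = np, p = p,
             half_decay_bp = 1 / p, log10_half_decay = log10(1 / p),
             stringsAsFactors = FALSE)
}

#' Write an LD pair table or landscape as TSV
#'
#' @param x an `ld_pairs` data frame or a [decay_landscape()] table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
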