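# Single-marker mixed-model association scans for line panels.
#
# Genotype and line effects both vary at the line level, so broods pool
# exactly: for sex ratio the per-line male/total counts are sufficient, and
# the model is m_i ~ Binomial(N_i, plogis(b0 + b1 g_i + u_i)),
# u_i ~ N(0, sigma^2).  Two fitters implement it:
#
# * "elogit" (scan default): at the panel's pooled denominators (thousands
#   of offspring per line) the per-line empirical logit is Gaussian with
#   known sampling variance, so the GLMM collapses to a line-level weighted
#   linear mixed model solved in closed form per SNP — fast enough to repeat
#   over full permutation scans.
# * "quadrature": maximum likelihood with adaptive Gauss-Hermite
#   integration (glmer-class accuracy), used for single-SNP work and as the
#   cross-check of the fast route.
#
# For clutch size the analogous linear mixed model is fitted through
# per-line summaries and generalised least squares.  Inference for the
# genotype effect uses a t reference with (lines used - 2) degrees of
# freedom, the between-line degrees of freedom of a line-level covariate.

# Pool broods to per-line sufficient statistics, ordered like `line_ids`.
line_summaries <- function(broods, line_ids) {
  b <- broods[broods$line_id %in% line_ids, , drop = FALSE]
  f <- factor(b$line_id, levels = line_ids)
  m <- tapply(b$n_males, f, sum, default = 0)
  N <- tapply(b$clutch_size, f, sum, default = 0)
  nb <- tapply(b$clutch_size, f, length, default = 0)
  ybar <- tapply(b$clutch_size, f, mean, default = NA_real_)
  ssw <- tapply(b$clutch_size, f, function(x) sum((x - mean(x))^2), default = 0)
  list(m = as.numeric(m), N = as.numeric(N), n_broods = as.numeric(nb),
       clutch_mean = as.numeric(ybar), clutch_ssw = as.numeric(ssw),
       line_ids = line_ids)
}

# log(1 + exp(eta)) without overflow
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

# Empirical logit and its binomial sampling variance for pooled counts.
elogit <- function(m, N) log((m + 0.5) / (N - m + 0.5))
elogit_var <- function(m, N) 1 / (m + 0.5) + 1 / (N - m + 0.5)

# Batched line-level fit of the binomial random-intercept model through the
# Gaussian working likelihood on empirical logits: y_i ~ N(b0 + b1 g_i,
# sigma_u^2 + c_i) with known binomial c_i.  sigma_u^2 is estimated once
# under the no-genotype model (method of moments on the weighted residuals);
# per-SNP inference rescales by the weighted residual mean square, which
# makes the balanced case an exact line-level regression with t_{L-2}
# calibration.  G: S x L dose in {0,1}; W: S x L usage mask.
elogit_scan_batch <- function(m, N, G, W) {
  use_line <- N > 0
  y <- ifelse(use_line, elogit(m, N), 0)
  ci <- ifelse(use_line, elogit_var(m, N), Inf)
  yl <- y[use_line]
  s2u <- max(0, var(yl) - mean(ci[use_line]))
  v <- ifelse(use_line, 1 / (s2u + ci), 0)
  gls_scan(y, v, G, sweep(W, 2, as.numeric(use_line), "*"))
}

# Weighted per-SNP regression of line-level responses y (variance weights v)
# on dose G with mask W; t-scale dispersion re-estimated per SNP.
gls_scan <- function(y, v, G, W) {
  VW <- sweep(W, 2, v, "*")
  sw <- rowSums(VW)
  swx <- rowSums(VW * G); swy <- as.vector(VW %*% y)
  swxx <- rowSums(VW * G * G); swxy <- as.vector((VW * G) %*% y)
  swyy <- as.vector(VW %*% (y * y))
  sxx <- swxx - swx^2 / sw
  sxy <- swxy - swx * swy / sw
  syy <- swyy - swy^2 / sw
  b1 <- sxy / sxx
  n_used <- rowSums(W > 0)
  rss <- pmax(syy - b1 * sxy, 0)
  phi <- rss / pmax(n_used - 2, 1)
  se <- sqrt(phi / sxx)
  list(b1 = b1, se_b1 = se, n_used = n_used)
}

#' Adaptive Gauss-Hermite ML fit of the binomial random-intercept model
#'
#' Fits `m_i ~ Binomial(N_i, plogis(b0 + b1 g_i + u_i))`,
#' `u_i ~ N(0, sigma^2)`, by maximum likelihood with adaptive Gauss-Hermite
#' quadrature (nodes recentred and rescaled at each line's conditional
#' mode), the same likelihood approximation class as `lme4::glmer` with
#' `nAGQ > 1`.
#'
#' @param m,N per-line male counts and totals.
#' @param g per-line allele dose in `{0, 1}` (`NA` drops the line).
#' @param k_nodes quadrature nodes (default 9).
#' @return list: `b0`, `b1`, `sigma`, `se_b1`, `loglik`, `converged`,
#'   `n_used`.
#' @export
binri_fit <- function(m, N, g, k_nodes = 9) {
  ok <- !is.na(g) & N > 0
  m <- m[ok]; N <- N[ok]; g <- as.numeric(g[ok])
  L <- length(m)
  gh <- gauss_hermite(k_nodes)
  z <- gh$x; lwz <- log(gh$w) + z^2

  negll <- function(th) {
    b0 <- th[1]; b1 <- th[2]; sig <- exp(th[3])
    eta0 <- b0 + b1 * g
    u <- rep(0, L)
    for (it in 1:30) {   # per-line conditional modes (Newton)
      p <- plogis(eta0 + u)
      g1 <- m - N * p - u / sig^2
      g2 <- -(N * p * (1 - p) + 1 / sig^2)
      step <- -g1 / g2
      u <- u + sign(step) * pmin(abs(step), 2)
      if (max(abs(g1)) < 1e-8) break
    }
    p <- plogis(eta0 + u)
    tau <- 1 / sqrt(N * p * (1 - p) + 1 / sig^2)
    # log integral exp(h(u)) du per line, h = binomial loglik + prior kernel
    hmat <- vapply(seq_len(k_nodes), function(k) {
      uk <- u + sqrt(2) * tau * z[k]
      etak <- eta0 + uk
      m * etak - N * log1pexp(etak) - uk^2 / (2 * sig^2) + lwz[k]
    }, numeric(L))
    hmax <- apply(hmat, 1, max)
    li <- hmax + log(rowSums(exp(hmat - hmax))) + log(sqrt(2) * tau) -
      log(sig * sqrt(2 * pi))
    -sum(li)
  }
  start <- c(qlogis((sum(m) + 0.5) / (sum(N) + 1)), 0,
             0.5 * log(max(var(elogit(m, N)) - mean(elogit_var(m, N)), 1e-3)))
  fit <- nlminb(start, negll, lower = c(-20, -20, log(1e-4)),
                upper = c(20, 20, log(10)))
  H <- stats::optimHess(fit$par, negll)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 3, 3))
  list(b0 = fit$par[1], b1 = fit$par[2], sigma = exp(fit$par[3]),
       se_b1 = sqrt(vc[2, 2]), loglik = -fit$objective,
       converged = fit$convergence == 0, n_used = L)
}

# Per-line clutch LMM scan via GLS on line means; variance components are
# estimated once, under the no-genotype model, by the one-way ANOVA
# (Henderson) method, and per-SNP inference rescales by the weighted
# residual mean square so the balanced case reduces to the exact
# line-means regression.
clutch_gls_batch <- function(ls_summ, G, W) {
  nb <- ls_summ$n_broods; ybar <- ls_summ$clutch_mean
  use_line <- nb > 0
  ssw <- sum(ls_summ$clutch_ssw[use_line])
  dfw <- sum(pmax(nb[use_line] - 1, 0))
  s2e <- if (dfw > 0) ssw / dfw else 0
  Ltot <- sum(use_line)
  ntot <- sum(nb)
  gm <- sum(nb[use_line] * ybar[use_line]) / ntot
  msb <- sum(nb[use_line] * (ybar[use_line] - gm)^2) / (Ltot - 1)
  n0 <- (ntot - sum(nb[use_line]^2) / ntot) / (Ltot - 1)
  s2u <- max(0, (msb - s2e) / n0)
  v <- ifelse(nb > 0, 1 / (s2u + s2e / pmax(nb, 1)), 0)
  y <- ifelse(is.na(ybar), 0, ybar)
  gls_scan(y, v, G, sweep(W, 2, as.numeric(use_line), "*"))
}

#' Single-marker association scan over all SNPs
#'
#' Fits, for every SNP, the single-marker mixed model with line as a random
#' intercept: a binomial (logit) model on brood male/female counts for
#' `trait = "sex_ratio"`, a linear model on clutch size for
#' `trait = "clutch"`.  Genotypes still segregating within a line
#' (heterozygous calls) and missing calls drop that line for that SNP's
#' test.  The p-value tests the genotype fixed effect against a t
#' reference with (lines used - 2) degrees of freedom.
#'
#' @param g a filtered [genotype_matrix()] (see [apply_gwas_filters()]).
#' @param broods a `brood_table` covering the panel lines.
#' @param trait `"sex_ratio"` or `"clutch"`.
#' @param method for sex ratio, `"elogit"` (line-level working-Gaussian
#'   mixed model; the scan default) or `"quadrature"` (per-SNP adaptive
#'   Gauss-Hermite ML, [binri_fit()]); ignored for clutch.
#' @param k_nodes Gauss-Hermite nodes for the quadrature method.
#' @return data frame of class `gwas_result`: `snp_id`, `chrom`, `pos`,
#'   `trait`, `beta`, `se`, `direction`, `p_value`, `neg_log10_p`, `maf`,
#'   `n_lines`, `converged`.
#' @export
gwas_scan <- function(g, broods, trait = c("sex_ratio", "clutch"),
                      method = c("elogit", "quadrature"), k_nodes = 9) {
  trait <- match.arg(trait)
  method <- match.arg(method)
  ls_summ <- line_summaries(broods, g$line_ids)
  GW <- scan_matrices(g, ls_summ)
  if (any(GW$mono))
    warning(sum(GW$mono), " SNP(s) monomorphic among phenotyped lines; p set missing")
  fit <- if (trait == "sex_ratio") {
    if (method == "elogit")
      elogit_scan_batch(ls_summ$m, ls_summ$N, GW$G, GW$W)
    else {
      per <- lapply(seq_len(nrow(GW$G)), function(s) {
        gd <- ifelse(GW$W[s, ] > 0, GW$G[s, ], NA)
        if (GW$mono[s]) return(list(b1 = NA_real_, se_b1 = NA_real_,
                                    converged = FALSE, n_used = sum(!is.na(gd))))
        binri_fit(ls_summ$m, ls_summ$N, gd, k_nodes = k_nodes)
      })
      list(b1 = vapply(per, `[[`, 0, "b1"),
           se_b1 = vapply(per, `[[`, 0, "se_b1"),
           converged = vapply(per, `[[`, TRUE, "converged"),
           n_used = vapply(per, `[[`, 0, "n_used"))
    }
  } else clutch_gls_batch(ls_summ, GW$G, GW$W)
  tstat <- fit$b1 / fit$se_b1
  df <- pmax(fit$n_used - 2, 1)
  p <- 2 * pt(-abs(tstat), df = df)
  conv <- if (is.null(fit$converged)) rep(TRUE, nrow(GW$G)) else fit$converged
  p[GW$mono | !conv] <- NA_real_
  res <- data.frame(snp_id = paste0(g$snps$chrom, "_", g$snps$pos),
                    chrom = g$snps$chrom, pos = g$snps$pos, trait = trait,
                    beta = fit$b1, se = fit$se_b1,
                    direction = ifelse(fit$b1 >= 0, "+", "-"),
                    p_value = p, neg_log10_p = -log10(p),
                    maf = GW$maf, n_lines = fit$n_used, converged = conv,
                    stringsAsFactors = FALSE)
  class(res) <- c("gwas_result", "data.frame")
  res
}

# S x L dose/mask matrices restricted to phenotyped lines; flags SNPs
# monomorphic among usable lines.
scan_matrices <- function(g, ls_summ) {
  calls <- t(g$calls)                     # S x L
  W <- (!is.na(calls) & calls != 1L) * 1
  W <- sweep(W, 2, as.numeric(ls_summ$n_broods > 0), "*")
  G <- (calls == 2L) * 1
  G[W == 0] <- 0
  nalt <- rowSums(G); nuse <- rowSums(W)
  maf <- pmin(nalt / nuse, 1 - nalt / nuse)
  mono <- nuse == 0 | nalt == 0 | nalt == nuse
  list(G = G, W = W, maf = maf, mono = mono)
}

#' Association test for a single SNP
#'
#' Convenience wrapper around [gwas_scan()] for one SNP; errors on a SNP
#' that is monomorphic among the phenotyped lines.
#'
#' @param broods a `brood_table`.
#' @param g a filtered [genotype_matrix()].
#' @param snp SNP column index or `snp_id` string.
#' @param trait `"sex_ratio"` or `"clutch"`.
#' @param method fitting method; single-SNP work defaults to the full
#'   `"quadrature"` likelihood fit.
#' @param ... passed to [gwas_scan()].
#' @return one-row `gwas_result` data frame.
#' @export
snp_association <- function(broods, g, snp, trait = c("sex_ratio", "clutch"),
                            method = "quadrature", ...) {
  trait <- match.arg(trait)
  if (is.character(snp))
    snp <- match(snp, paste0(g$snps$chrom, "_", g$snps$pos))
  if (is.na(snp) || snp < 1 || snp > nrow(g$snps)) stop("unknown SNP")
  sub <- g[, snp]
  res <- suppressWarnings(gwas_scan(sub, broods, trait, method = method, ...))
  if (is.na(res$p_value)) stop("SNP is monomorphic among phenotyped lines (or fit failed)")
  res
}

#' Permutation null distribution for the association scan
#'
#' Permutes iso-female line identity against the genotype columns (the
#' genotype vector is reassigned across lines while each line keeps its own
#' broods), breaking genotype-phenotype linkage while preserving the brood
#' structure, and repeats the full scan.  All per-SNP p-values are pooled
#' per permutation.
#'
#' @param g a filtered [genotype_matrix()].
#' @param broods a `brood_table`.
#' @param trait `"sex_ratio"` or `"clutch"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param ... passed to [gwas_scan()].
#' @return object of class `gwas_null`: list with `p` (list of numeric
#'   p-value vectors, one per permutation), `n_perm`, `trait`, `seed`.
#' @export
permutation_null <- function(g, broods, trait = c("sex_ratio", "clutch"),
                             n_perm = 100, seed = 1L, ...) {
  trait <- match.arg(trait)
  if (n_perm < 1) stop("n_perm must be at least 1")
  set.seed(seed)
  nl <- length(g$line_ids)
  store <- vector("list", n_perm)
  for (k in seq_len(n_perm)) {
    perm <- sample.int(nl)
    gp <- g
    gp$calls <- g$calls[perm, , drop = FALSE]
    rownames(gp$calls) <- g$line_ids
    store[[k]] <- suppressWarnings(gwas_scan(gp, broods, trait, ...))$p_value
  }
  structure(list(p = store, n_perm = n_perm, trait = trait, seed = seed),
            class = "gwas_null")
}

#' Empirical significance threshold from a permutation null
#'
#' For every candidate threshold t (the observed p-values in ascending
#' order) the empirical false discovery proportion is estimated as
#' `qhat(t) = mean per-permutation count of null p <= t / observed count of
#' p <= t`; monotonicity is enforced by a running minimum from the largest
#' candidate downwards (step-up), and the threshold is the largest t with
#' `qhat(t) <= q`.  When no candidate qualifies the minimum attainable
#' q-value is reported and no SNP is called significant.
#'
#' @param observed a `gwas_result` data frame (or numeric p-values).
#' @param null_store a [permutation_null()] object.
#' @param q target q-value (default 0.1).
#' @return object of class `gwas_threshold`: `q_target`, `p_threshold`
#'   (`NA` when nothing passes), `neg_log10_threshold`, `n_significant`,
#'   `min_q`, `n_perm`.
#' @export
empirical_threshold <- function(observed, null_store, q = 0.1) {
  p_obs <- if (is.data.frame(observed)) observed$p_value else observed
  p_obs <- sort(p_obs[!is.na(p_obs)])
  if (!length(p_obs)) stop("no observed p-values")
  null_p <- unlist(null_store$p)
  null_p <- sort(null_p[!is.na(null_p)])
  n_perm <- null_store$n_perm
  cnt_null <- findInterval(p_obs, null_p) / n_perm
  qhat <- cnt_null / seq_along(p_obs)
  qadj <- rev(cummin(rev(qhat)))
  pass <- which(qadj <= q)
  res <- list(q_target = q,
              p_threshold = if (length(pass)) p_obs[max(pass)] else NA_real_,
              neg_log10_threshold = if (length(pass)) -log10(p_obs[max(pass)]) else NA_real_,
              n_significant = if (length(pass)) max(pass) else 0L,
              min_q = min(qadj), n_perm = n_perm)
  class(res) <- "gwas_threshold"
  res
}

#' @export
print.gwas_threshold <- function(x, ...) {
  if (!is.na(x$p_threshold))
    cat(sprintf("empirical threshold at q = %.3g: P = %.3g (-log10 P = %.2f); %d SNP(s) significant (%d permutations)\n",
                x$q_target, x$p_threshold, x$neg_log10_threshold,
                x$n_significant, x$n_perm))
  else
    cat(sprintf("no SNP passes q = %.3g; minimum attainable q-value = %.3g (%d permutations)\n",
                x$q_target, x$min_q, x$n_perm))
  invisible(x)
}

#' Run the full GWAS for both traits
#'
#' Applies the panel filters when metadata are supplied, scans both traits,
#' derives each trait's permutation-based empirical threshold, and
#' (optionally) writes the association tables, thresholds and a
#' Manhattan-ready TSV into `out_dir`.
#'
#' @param g a [genotype_matrix()] (filtered, or raw plus `meta`).
#' @param broods a `brood_table`.
#' @param meta optional metadata; when given, [apply_gwas_filters()] is run
#'   first with `min_called_lines` and `maf_min`.
#' @param traits traits to scan.
#' @param q target q-value (default 0.1).
#' @param n_perm permutations per trait (default 100).
#' @param seed integer seed (mandatory for reproducibility).
#' @param min_called_lines,maf_min filter settings (see
#'   [apply_gwas_filters()]).
#' @param out_dir optional output directory.
#' @return list of class `gwas_run`: `results` (combined `gwas_result`),
#'   `thresholds` (per trait), `nulls` (per trait), `genotypes` (the
#'   filtered matrix).
#' @export
run_gwas <- function(g, broods, meta = NULL, traits = c("sex_ratio", "clutch"),
                     q = 0.1, n_perm = 100, seed = 1L,
                     min_called_lines = 18, maf_min = 0.04, out_dir = NULL) {
  if (!is.null(meta))
    g <- apply_gwas_filters(g, meta, min_called_lines = min_called_lines,
                            maf_min = maf_min)
  results <- list(); thresholds <- list(); nulls <- list()
  for (tr in traits) {
    res <- suppressWarnings(gwas_scan(g, broods, tr))
    null <- permutation_null(g, broods, tr, n_perm = n_perm,
                             seed = seed + match(tr, traits))
    thr <- empirical_threshold(res, null, q = q)
    results[[tr]] <- res; thresholds[[tr]] <- thr; nulls[[tr]] <- null
  }
  out <- structure(list(results = do.call(rbind, results),
                        thresholds = thresholds, nulls = nulls, genotypes = g),
                   class = "gwas_run")
  rownames(out$results) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out$results, file.path(out_dir, "associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    thr_df <- do.call(rbind, lapply(names(thresholds), function(tr)
      data.frame(trait = tr, q_target = thresholds[[tr]]$q_target,
                 p_threshold = thresholds[[tr]]$p_threshold,
                 neg_log10_threshold = thresholds[[tr]]$neg_log10_threshold,
                 n_significant = thresholds[[tr]]$n_significant,
                 min_q = thresholds[[tr]]$min_q,
                 n_perm = thresholds[[tr]]$n_perm)))
    write.table(thr_df, file.path(out_dir, "thresholds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (tr in names(nulls))
      write.table(data.frame(perm = rep(seq_len(nulls[[tr]]$n_perm),
                                        vapply(nulls[[tr]]$p, length, 1L)),
                             p_value = unlist(nulls[[tr]]$p)),
                  file.path(out_dir, paste0("null_", tr, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.gwas_run <- function(x, ...) {
  cat("GWAS run:", nrow(x$results), "tests over",
      length(x$genotypes$line_ids), "lines\n")
  for (tr in names(x$thresholds)) {
    cat(sprintf("  %s: ", tr)); print(x$thresholds[[tr]])
  }
  invisible(x)
}
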