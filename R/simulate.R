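#' Configuration for the synthetic line-panel generator
#'
#' Collects every tunable of the simulator with defaults chosen to emulate a
#' haplodiploid iso-female line panel of the kind used for line-based GWAS:
#' 34 lines derived from an outbred base population, 9 generations of
#' inbreeding (one mother-son cross followed by full-sib mating), hyperbolic
#' LD decay with a half-decay distance of 15 kb, brood-level binomial sex
#' ratios with a broad-sense heritability near 0.106 on the arcsine-square-
#' root scale, and clutch sizes around 60 eggs with line heritability 0.078.
#'
#' @param n_lines number of inbred lines to found.
#' @param n_snps_per_chrom SNPs simulated per chromosome (recycled).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_founder_haplotypes size of the outbred founder haplotype pool.
#' @param founder_beta length-2 Beta shape parameters of the block allele
#'   frequency spectrum (block frequencies are rescaled into `[0.05, 0.95]`).
#' @param freq_block_bp length of the blocks over which the founder allele
#'   frequency is constant.
#' @param p_sim hyperbolic LD decay rate per bp; mean founder r^2 at distance
#'   x follows `r2(0) / (1 + p_sim * x)`.  Default 1/15000 (half-decay 15 kb).
#' @param rate_segment_bp length of the segments over which the local copying
#'   switch rate is constant (recombination-rate heterogeneity scale).
#' @param rate_mixture when `TRUE` (default) segment switch rates are a
#'   stratified sample from the exponential distribution with mean
#'   `p_sim/2`, whose Laplace transform makes the distance-binned mean r^2
#'   hyperbolic and the half-decay landscape heterogeneous, as in real
#'   genomes; when `FALSE` every segment uses the constant rate `p_sim/2`,
#'   giving a uniform LD landscape with exponential pair decay
#'   `exp(-p_sim * d)`.
#' @param generations inbreeding generations (mother-son cross counts as the
#'   first; remaining ones are full-sib).
#' @param crossovers_per_meiosis mean crossovers per chromosome per meiosis.
#' @param broods_per_line broods phenotyped per line.
#' @param mu_clutch,sd_clutch mean and brood-level SD of clutch size (eggs).
#' @param beta0 baseline log-odds of a male offspring; the default gives the
#'   female-biased sex ratio (proportion male 0.25) typical under local mate
#'   competition.
#' @param h2_sex_ratio target broad-sense heritability of sex ratio on the
#'   arcsine-square-root scale; used to calibrate the among-line variance
#'   `sigma2_line` when that is `NULL` (see [calibrate_line_variance()]).
#' @param sigma2_line among-line variance of the logit proportion male;
#'   `NULL` (default) derives it from `h2_sex_ratio`.
#' @param h2_clutch target broad-sense heritability of clutch size; sets the
#'   among-line clutch variance `h2/(1-h2) * sd_clutch^2`.
#' @param causal_sr data frame (`chrom`, `pos`, `beta`) of causal sex-ratio
#'   SNPs (logit-scale allele substitution effects, applied to the nearest
#'   simulated SNP); `NULL` for none.
#' @param pleiotropy data frame (`chrom`, `start`, `end`, `n_causal`,
#'   `beta_sr`, `beta_clutch`) of windows holding SNPs that affect both
#'   traits; `NULL` for none.
#' @param causal_maf_min minimum minor-allele frequency (among lines) for a
#'   SNP to be eligible as a causal locus; causal variants of detectable
#'   effect are expected to be common in a panel descended from an outbred
#'   base population.
#' @param n_wolbachia_lost number of lines flagged as having lost their
#'   Wolbachia infection (excluded from GWAS).
#' @param n_outlier_excluded number of additional lines flagged as excluded
#'   outliers (e.g. transient infection status).
#' @param annotation_region_bp length of the chromosome-1 prefix for which a
#'   toy gene annotation and reference sequence are generated.
#' @param seed mandatory integer seed; the full output is a deterministic
#'   function of the configuration including the seed.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 34,
                       n_snps_per_chrom = 20000,
                       chrom_lengths = c(chr1 = 60e6, chr2 = 50e6, chr3 = 45e6,
                                         chr4 = 40e6, chr5 = 40e6),
                       n_founder_haplotypes = 200,
                       founder_beta = c(1.2, 1.2),
                       freq_block_bp = 2e6,
                       p_sim = 1 / 15000,
                       rate_segment_bp = 2e6,
                       rate_mixture = TRUE,
                       generations = 9,
                       crossovers_per_meiosis = 1,
                       broods_per_line = 38,
                       mu_clutch = 60,
                       sd_clutch = 15,
                       beta0 = qlogis(0.25),
                       h2_sex_ratio = 0.106,
                       sigma2_line = NULL,
                       h2_clutch = 0.078,
                       causal_sr = NULL,
                       pleiotropy = NULL,
                       causal_maf_min = 0.25,
                       n_wolbachia_lost = 8,
                       n_outlier_excluded = 1,
                       annotation_region_bp = 60000,
                       seed = 1L) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  n_snps_per_chrom <- rep_len(n_snps_per_chrom, length(chrom_lengths))
  stopifnot(n_lines >= 2, all(chrom_lengths >= 0), p_sim > 0,
            generations >= 0, broods_per_line >= 1, mu_clutch > 0,
            sd_clutch >= 0, h2_clutch >= 0, h2_clutch < 1,
            n_founder_haplotypes >= 4, length(seed) == 1)
  if (mu_clutch - 4 * sd_clutch < -mu_clutch)  # clutch model must keep a positive mean
    stop("clutch model mean must stay positive")
  if (!is.null(sigma2_line) && sigma2_line < 0) stop("sigma2_line must be >= 0")
  cfg <- list(n_lines = n_lines, n_snps_per_chrom = n_snps_per_chrom,
              chrom_lengths = chrom_lengths,
              n_founder_haplotypes = n_founder_haplotypes,
              founder_beta = founder_beta, freq_block_bp = freq_block_bp,
              p_sim = p_sim, rate_segment_bp = rate_segment_bp,
              rate_mixture = rate_mixture,
              generations = generations,
              crossovers_per_meiosis = crossovers_per_meiosis,
              broods_per_line = broods_per_line, mu_clutch = mu_clutch,
              sd_clutch = sd_clutch, beta0 = beta0,
              h2_sex_ratio = h2_sex_ratio, sigma2_line = sigma2_line,
              h2_clutch = h2_clutch, causal_sr = causal_sr,
              pleiotropy = pleiotropy, causal_maf_min = causal_maf_min,
              n_wolbachia_lost = n_wolbachia_lost,
              n_outlier_excluded = n_outlier_excluded,
              annotation_region_bp = annotation_region_bp,
              seed = as.integer(seed))
  if (!is.null(cfg$causal_sr))
    stopifnot(all(cfg$causal_sr$chrom %in% names(chrom_lengths)),
              all(cfg$causal_sr$pos >= 1),
              all(cfg$causal_sr$pos <= chrom_lengths[cfg$causal_sr$chrom]))
  if (!is.null(cfg$pleiotropy))
    stopifnot(all(cfg$pleiotropy$chrom %in% names(chrom_lengths)))
  class(cfg) <- "sim_config"
  cfg
}

#' Calibrate the among-line logit variance to a target heritability
#'
#' Solves for the variance of the line effect u (logit proportion male) such
#' that the variance partition on the arcsine-square-root scale,
#' `H2 = V_line / (V_line + V_res)`, equals the target.  `V_line` is computed
#' by Gauss-Hermite integration of `asin(sqrt(plogis(beta0 + u)))` over
#' `u ~ N(0, sigma2)`; `V_res` is the binomial sampling variance of the
#' transformed brood proportion, `E[1/(4n)]`, averaged over the rounded
#' truncated-normal clutch distribution.
#'
#' @param h2 target broad-sense heritability on the transformed scale.
#' @param mu_clutch,sd_clutch clutch size distribution parameters.
#' @param beta0 baseline log-odds of a male offspring.
#' @return the calibrated `sigma2_line`.
#' @export
calibrate_line_variance <- function(h2, mu_clutch = 60, sd_clutch = 15,
                                    beta0 = qlogis(0.25)) {
  stopifnot(h2 >= 0, h2 < 1)
  if (h2 == 0) return(0)
  n <- seq_len(ceiling(mu_clutch + 6 * sd_clutch))
  pn <- if (sd_clutch > 0) {
    w <- pnorm(n + 0.5, mu_clutch, sd_clutch) - pnorm(n - 0.5, mu_clutch, sd_clutch)
    w / sum(w)
  } else {
    as.numeric(n == round(mu_clutch))
  }
  v_res <- sum(pn / (4 * n))
  gh <- gauss_hermite(41)
  v_line <- function(s2) {
    y <- asin(sqrt(plogis(beta0 + sqrt(2 * s2) * gh$x)))
    m <- sum(gh$w * y) / sqrt(pi)
    sum(gh$w * (y - m)^2) / sqrt(pi)
  }
  target <- h2 / (1 - h2) * v_res
  stats::uniroot(function(s2) v_line(s2) - target, c(1e-8, 25), tol = 1e-10)$root
}

# Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  b <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Simulate a founder haplotype pool
#'
#' Generates `n_founder_haplotypes` haplotypes per chromosome under a
#' Markov copying process: along each chromosome a latent founder-lineage
#' indicator is copied from SNP to SNP and refreshed with a distance-
#' dependent probability `1 - exp(-rho * d)`.  The local switch rate `rho`
#' is constant within segments of `rate_segment_bp` and drawn from an
#' exponential distribution with mean `p_sim / 2`, which makes the expected
#' squared allelic correlation at distance x decay as `1 / (1 + p_sim * x)`
#' (the exponential rate mixture is the Laplace transform of the hyperbola).
#' Founder allele frequencies are constant within `freq_block_bp` blocks and
#' drawn from a rescaled Beta spectrum.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return object of class `founder_pool`: list with `snps` (chrom, pos,
#'   ref, alt), `H` (haplotype-by-SNP 0/1 matrix) and `freq` (block allele
#'   frequency per SNP).
#' @export
simulate_founder_haplotypes <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  nh <- cfg$n_founder_haplotypes
  snps <- list(); haps <- list(); freqs <- list()
  nts <- c("A", "C", "G", "T")
  # segment switch rates for the whole genome: a stratified exponential
  # sample (inverse-CDF on a jittered permuted grid) keeps the realised
  # rate mixture close to its target distribution even with few segments,
  # so the binned mean r^2 tracks the hyperbola 1/(1 + p_sim x)
  n_seg_chrom <- pmax(1L, as.integer(ceiling(cfg$chrom_lengths / cfg$rate_segment_bp)))
  n_seg <- sum(n_seg_chrom)
  rho_all <- if (isTRUE(cfg$rate_mixture)) {
    u <- (sample.int(n_seg) - runif(n_seg)) / n_seg
    stats::qexp(u, rate = 2 / cfg$p_sim)      # 2*rho ~ Exp(mean p_sim)
  } else rep(cfg$p_sim / 2, n_seg)
  seg_offset <- c(0L, cumsum(n_seg_chrom))[seq_along(n_seg_chrom)]
  for (ci in seq_along(cfg$chrom_lengths)) {
    chrom <- names(cfg$chrom_lengths)[ci]
    L <- cfg$chrom_lengths[ci]
    ns <- cfg$n_snps_per_chrom[ci]
    if (L <= 0 || ns == 0) next
    pos <- sort(sample.int(L, min(ns, L)))
    ns <- length(pos)
    block <- pos %/% cfg$freq_block_bp
    ublock <- unique(block)
    bf <- 0.05 + 0.9 * rbeta(length(ublock), cfg$founder_beta[1], cfg$founder_beta[2])
    f <- bf[match(block, ublock)]
    seg <- pos %/% cfg$rate_segment_bp
    rho <- rho_all[seg_offset[ci] + seg + 1L]
    d <- c(Inf, diff(pos))
    keep_p <- exp(-rho * d)
    keep_p[c(TRUE, diff(block) != 0)] <- 0  # refresh at frequency-block edges
    H <- matrix(0L, nh, ns)
    for (h in seq_len(nh)) {
      refresh <- runif(ns) >= keep_p
      draw <- as.integer(runif(ns) < f)
      idx <- cummax(ifelse(refresh, seq_len(ns), 0L))
      H[h, ] <- draw[idx]
    }
    ref <- sample(nts, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
    snps[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                stringsAsFactors = FALSE)
    haps[[chrom]] <- H
    freqs[[chrom]] <- f
  }
  if (!length(snps))
    return(structure(list(snps = data.frame(chrom = character(), pos = integer(),
                                            ref = character(), alt = character()),
                          H = matrix(0L, nh, 0), freq = numeric()),
                     class = "founder_pool"))
  structure(list(snps = do.call(rbind, c(snps, make.row.names = FALSE)),
                 H = do.call(cbind, haps),
                 freq = unlist(freqs, use.names = FALSE)),
            class = "founder_pool")
}

# One gamete from a diploid (2 x nsnp) pair of haplotype rows, with Poisson
# crossovers per chromosome.  `chrom_idx` is a list of SNP column indices per
# chromosome, `pos` the position vector, `len` chromosome lengths.
.gamete <- function(ha, hb, chrom_idx, pos, len, xover_mean) {
  out <- ha
  for (k in seq_along(chrom_idx)) {
    idx <- chrom_idx[[k]]
    if (!length(idx)) next
    nx <- stats::rpois(1, xover_mean)
    bp <- if (nx > 0) sort(runif(nx, 0, len[k])) else numeric()
    par0 <- runif(1) < 0.5
    parity <- (findInterval(pos[idx], bp) + par0) %% 2
    out[idx] <- ifelse(parity == 1, ha[idx], hb[idx])
  }
  out
}

#' Simulate inbred lines from a founder pool
#'
#' Each line descends from one founder female (two haplotypes sampled from
#' the pool) through an explicit haplodiploid pedigree: the foundress is
#' first crossed to one of her sons (a haploid male carrying one recombinant
#' maternal gamete), and the line is then propagated by full-sib mating.
#' Daughters arise from fertilised eggs (one maternal gamete plus the
#' father's haploid genome); sons arise from unfertilised eggs (one maternal
#' gamete).  The mother-son cross counts as the first of
#' `cfg$generations` generations.
#'
#' @param pool a [simulate_founder_haplotypes()] result.
#' @param cfg a [sim_config()].
#' @param seed integer seed; defaults to `cfg$seed + 1`.
#' @return a [genotype_matrix()] (no missing data; residual within-line
#'   segregation appears as heterozygous calls).  Attribute
#'   `"residual_het"` stores the per-line heterozygous fraction.
#' @export
simulate_inbred_lines <- function(pool, cfg, seed = cfg$seed + 1L) {
  if (nrow(pool$snps) == 0) stop("founder pool is empty")
  set.seed(seed)
  pos <- pool$snps$pos
  chroms <- names(cfg$chrom_lengths)
  chrom_idx <- lapply(chroms, function(ch) which(pool$snps$chrom == ch))
  names(chrom_idx) <- chroms
  len <- as.numeric(cfg$chrom_lengths)
  xm <- cfg$crossovers_per_meiosis
  nh <- nrow(pool$H)
  if (nh < 2 * cfg$n_lines)
    stop("need at least 2 founder haplotypes per line (distinct foundress females)")
  # every line descends from a distinct foundress: no founder haplotype is
  # shared between lines
  founder_draw <- matrix(sample.int(nh, 2 * cfg$n_lines), ncol = 2)
  calls <- matrix(0L, cfg$n_lines, nrow(pool$snps))
  for (l in seq_len(cfg$n_lines)) {
    founders <- founder_draw[l, ]
    Fa <- pool$H[founders[1], ]; Fb <- pool$H[founders[2], ]
    M <- .gamete(Fa, Fb, chrom_idx, pos, len, xm)  # her son
    for (g in seq_len(cfg$generations)) {
      egg1 <- .gamete(Fa, Fb, chrom_idx, pos, len, xm)
      egg2 <- .gamete(Fa, Fb, chrom_idx, pos, len, xm)
      Fa_new <- egg1; Fb_new <- M   # daughter: maternal gamete + paternal genome
      M <- egg2                     # son: unfertilised maternal gamete
      Fa <- Fa_new; Fb <- Fb_new
    }
    calls[l, ] <- Fa + Fb           # 0/1/2 from final female
  }
  g <- genotype_matrix(calls, pool$snps,
                       sprintf("L%02d", seq_len(cfg$n_lines)))
  attr(g, "residual_het") <- residual_heterozygosity(g)
  g
}

#' Simulate brood-level phenotypes with known architecture
#'
#' For line i, the proportion of male offspring is
#' `p_i = plogis(beta0 + sum(beta_j x_ij) + u_i)` with
#' `u_i ~ N(0, sigma2_line)` and `x_ij` the allele dose (0, 0.5, 1) at causal
#' SNP j.  Each brood's male count is Binomial(clutch, p_i); clutch size is
#' a rounded truncated-at-1 Normal with mean
#' `mu_clutch + v_i + sum(betaC_j x_ij)`, `v_i ~ N(0, sigma2_line_clutch)`.
#' Causal SNPs come from `cfg$causal_sr` (sex ratio only) and from
#' `cfg$pleiotropy` windows (SNPs sampled inside each window affecting both
#' traits).
#'
#' @param g a [genotype_matrix()] holding the causal SNPs.
#' @param cfg a [sim_config()].
#' @param seed integer seed; defaults to `cfg$seed + 2`.
#' @return a `brood_table` (see [read_brood_table()]) with attribute
#'   `"truth"`: list with per-line effects (`lines`) and the causal SNP
#'   table (`causal`) including each SNP's column index in `g`.
#' @export
simulate_phenotypes <- function(g, cfg, seed = cfg$seed + 2L) {
  set.seed(seed)
  nl <- length(g$line_ids)
  sigma2 <- if (is.null(cfg$sigma2_line))
    calibrate_line_variance(cfg$h2_sex_ratio, cfg$mu_clutch, cfg$sd_clutch, cfg$beta0)
  else cfg$sigma2_line
  sigma2_c <- cfg$h2_clutch / (1 - cfg$h2_clutch) * cfg$sd_clutch^2

  causal <- data.frame(chrom = character(), pos = integer(), snp = integer(),
                       beta_sr = numeric(), beta_clutch = numeric())
  if (!is.null(cfg$causal_sr) && nrow(cfg$causal_sr)) {
    maf_all <- snp_maf(g)
    for (k in seq_len(nrow(cfg$causal_sr))) {
      on_chr <- which(g$snps$chrom == cfg$causal_sr$chrom[k] &
                        !is.na(maf_all) & maf_all >= cfg$causal_maf_min)
      if (!length(on_chr))
        stop("no common SNP on causal chromosome ", cfg$causal_sr$chrom[k])
      j <- on_chr[which.min(abs(g$snps$pos[on_chr] - cfg$causal_sr$pos[k]))]
      causal <- rbind(causal, data.frame(chrom = g$snps$chrom[j], pos = g$snps$pos[j],
                                         snp = j, beta_sr = cfg$causal_sr$beta[k],
                                         beta_clutch = 0))
    }
  }
  if (!is.null(cfg$pleiotropy) && nrow(cfg$pleiotropy)) {
    for (k in seq_len(nrow(cfg$pleiotropy))) {
      w <- cfg$pleiotropy[k, ]
      inw <- which(g$snps$chrom == w$chrom & g$snps$pos >= w$start & g$snps$pos <= w$end)
      maf_w <- snp_maf(g)[inw]
      common <- inw[!is.na(maf_w) & maf_w >= cfg$causal_maf_min]
      if (length(common) < w$n_causal)
        stop("pleiotropy window ", w$chrom, ":", w$start, "-", w$end,
             " holds fewer than n_causal common SNPs")
      # spread causal loci evenly through the window and require them to be
      # decorrelated across lines, so each contributes an independent
      # shared association rather than a redundant (or cancelling) one
      targets <- w$start + (seq_len(w$n_causal) - 0.5) / w$n_causal * (w$end - w$start)
      dose_of <- function(s) {
        d <- g$calls[, s] / 2
        if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
        d
      }
      j <- integer(0)
      for (tg in targets) {
        cand <- setdiff(common, j)
        if (length(j)) {
          picked <- vapply(j, dose_of, numeric(length(g$line_ids)))
          maxcor <- vapply(cand, function(s)
            max(abs(suppressWarnings(cor(dose_of(s), picked)))), numeric(1))
          indep <- cand[!is.na(maxcor) & maxcor <= 0.2]
          if (length(indep)) cand <- indep
        }
        j <- c(j, cand[which.min(abs(g$snps$pos[cand] - tg))])
      }
      j <- sort(j)
      # mixed effect directions: shared loci need not act in the same
      # direction on both traits, and orthogonal sign patterns keep the
      # shared local basis from doubling as a global line-effect
      # correlation between the traits
      idx <- seq_along(j) - 1
      s_sr <- ifelse(idx %% 4 %in% c(0, 1), 1, -1)
      s_cl <- ifelse(idx %% 2 == 0, 1, -1)
      causal <- rbind(causal, data.frame(chrom = g$snps$chrom[j], pos = g$snps$pos[j],
                                         snp = j, beta_sr = s_sr * w$beta_sr,
                                         beta_clutch = s_cl * w$beta_clutch))
    }
  }
  dose <- matrix(0, nl, nrow(causal))
  if (nrow(causal)) {
    dose <- g$calls[, causal$snp, drop = FALSE] / 2
    if (anyNA(dose)) {
      cm <- colMeans(dose, na.rm = TRUE)
      for (j in seq_len(ncol(dose))) dose[is.na(dose[, j]), j] <- cm[j]
    }
  }
  u <- rnorm(nl, 0, sqrt(sigma2))
  v <- rnorm(nl, 0, sqrt(sigma2_c))
  eta <- cfg$beta0 + as.vector(dose %*% causal$beta_sr) + u
  p_line <- plogis(eta)
  mu_c <- cfg$mu_clutch + as.vector(dose %*% causal$beta_clutch) + v
  if (any(mu_c <= 0)) stop("clutch model produced a non-positive line mean")

  nb <- cfg$broods_per_line
  line_id <- rep(g$line_ids, each = nb)
  clutch <- pmax(1L, as.integer(round(rnorm(nl * nb, rep(mu_c, each = nb), cfg$sd_clutch))))
  males <- rbinom(nl * nb, clutch, rep(p_line, each = nb))
  broods <- data.frame(line_id = line_id,
                       female_id = paste0(line_id, "_f", rep(seq_len(nb), nl)),
                       n_males = males, n_females = clutch - males,
                       stringsAsFactors = FALSE)
  broods <- read_brood_table(broods)
  attr(broods, "truth") <- list(
    lines = data.frame(line_id = g$line_ids, u = u, v = v, p_line = p_line,
                       mu_clutch = mu_c, stringsAsFactors = FALSE),
    causal = causal, sigma2_line = sigma2, sigma2_line_clutch = sigma2_c)
  broods
}

#' Simulate line metadata (Wolbachia status and exclusions)
#'
#' Flags `n_wolbachia_lost` randomly chosen lines as infection-negative and
#' `n_outlier_excluded` further lines as excluded outliers.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [sim_config()].
#' @param seed integer seed; defaults to `cfg$seed + 3`.
#' @return metadata data frame as accepted by [apply_gwas_filters()].
#' @export
simulate_metadata <- function(g, cfg, seed = cfg$seed + 3L) {
  set.seed(seed)
  nl <- length(g$line_ids)
  nw <- min(cfg$n_wolbachia_lost, nl)
  lost <- sample(g$line_ids, nw)
  rest <- setdiff(g$line_ids, lost)
  outl <- sample(rest, min(cfg$n_outlier_excluded, length(rest)))
  data.frame(line_id = g$line_ids,
             wolbachia_positive = !(g$line_ids %in% lost),
             excluded = g$line_ids %in% outl,
             reason = ifelse(g$line_ids %in% outl, "sex-ratio outlier, transient infection", ""),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic line panel
#'
#' Convenience wrapper running [simulate_founder_haplotypes()],
#' [simulate_inbred_lines()], [simulate_phenotypes()],
#' [simulate_metadata()] and [simulate_annotation()] with seeds derived from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `genotypes`, `broods`, `meta`, `annotation`,
#'   `truth` and `config`.
#' @export
simulate_panel <- function(cfg) {
  pool <- simulate_founder_haplotypes(cfg)
  g <- simulate_inbred_lines(pool, cfg)
  broods <- simulate_phenotypes(g, cfg)
  meta <- simulate_metadata(g, cfg)
  ann <- simulate_annotation(g, cfg)
  list(genotypes = g, broods = broods, meta = meta, annotation = ann,
       truth = attr(broods, "truth"), config = cfg)
}

#' Write a synthetic panel as a plain-text fixture set
#'
#' Emits `genotypes.vcf`, `broods.csv`, `metadata.csv`, `annotation.gff3`,
#' `genome.fa` and `truth.json` into `dir`.  Re-reading the three core files
#' reproduces the in-memory objects.
#'
#' @param dir output directory (created if needed).
#' @param g a [genotype_matrix()].
#' @param broods a `brood_table`.
#' @param meta metadata data frame.
#' @param annotation optional [simulate_annotation()] result.
#' @param truth optional truth list (stored as JSON).
#' @return character vector of written paths, invisibly.
#' @export
write_fixture <- function(dir, g, broods, meta, annotation = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             broods = file.path(dir, "broods.csv"),
             meta = file.path(dir, "metadata.csv"))
  write_genotype_matrix(g, paths["vcf"])
  write.csv(broods[, c("line_id", "female_id", "n_males", "n_females")],
            paths["broods"], row.names = FALSE, quote = FALSE)
  write.csv(meta, paths["meta"], row.names = FALSE, quote = TRUE)
  if (!is.null(annotation)) {
    paths["gff"] <- file.path(dir, "annotation.gff3")
    paths["fasta"] <- file.path(dir, "genome.fa")
    write_annotation(annotation, paths["gff"], paths["fasta"])
  }
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    writeLines(jsonlite::toJSON(truth, digits = NA, auto_unbox = TRUE, pretty = TRUE),
               paths["truth"])
  }
  invisible(paths)
}
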