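# The generator's statistical contracts: determinism, LD calibration,
# heterozygosity decay, phenotype architecture, fixture round trips.

ld_pool <- function() cached("ld_pool", function() {
  cfg <- sim_config(n_lines = 10, n_snps_per_chrom = 2500,
                    chrom_lengths = setNames(rep(24e6, 5), paste0("chr", 1:5)),
                    n_founder_haplotypes = 260,
                    p_sim = 1 / 15000, seed = 421)
  list(cfg = cfg, pool = simulate_founder_haplotypes(cfg))
})

# founder haplotypes as a haploid genotype matrix
pool_as_matrix <- function(pool)
  genotype_matrix(2L * pool$H, pool$snps, sprintf("H%03d", seq_len(nrow(pool$H))))

test_that("generator output is deterministic and seed-sensitive", {
  cfg <- sim_config(n_lines = 8, n_snps_per_chrom = 60, chrom_lengths = c(chr1 = 2e6),
                    n_wolbachia_lost = 2, n_outlier_excluded = 1, seed = 3)
  a <- simulate_panel(cfg); b <- simulate_panel(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$broods$n_males, b$broods$n_males)
  expect_identical(a$meta, b$meta)
  cfg2 <- sim_config(n_lines = 8, n_snps_per_chrom = 60, chrom_lengths = c(chr1 = 2e6),
                     n_wolbachia_lost = 2, n_outlier_excluded = 1, seed = 4)
  expect_false(identical(simulate_panel(cfg2)$genotypes$calls, a$genotypes$calls))
})

test_that("fixture files are byte-identical under a fixed seed and round-trip", {
  p <- small_panel()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_fixture(d1, p$genotypes, p$broods, p$meta, p$annotation, p$truth)
  f2 <- write_fixture(d2, p$genotypes, p$broods, p$meta, p$annotation, p$truth)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  g2 <- read_genotype_matrix(f1[["vcf"]])
  expect_identical(unname(g2$calls), unname(p$genotypes$calls))
  b2 <- read_brood_table(f1[["broods"]])
  expect_equal(b2$n_males, p$broods$n_males)
  m2 <- read_line_metadata(f1[["meta"]])
  expect_equal(m2$excluded, p$meta$excluded)
})

test_that("empty brood list writes a header-only CSV", {
  p <- small_panel()
  d <- withr::local_tempdir()
  empty <- p$broods[0, ]
  f <- write_fixture(d, p$genotypes, empty, p$meta)
  expect_equal(length(readLines(f[["broods"]])), 1)
})

test_that("zero-length chromosome yields an empty pool", {
  cfg <- sim_config(n_lines = 4, n_snps_per_chrom = 10, chrom_lengths = c(chr1 = 0),
                    seed = 1)
  pool <- simulate_founder_haplotypes(cfg)
  expect_equal(nrow(pool$snps), 0)
  expect_error(simulate_inbred_lines(pool, cfg), "empty")
})

test_that("binned founder r2 decays as the hyperbola 1/(1 + p x)", {
  lp <- ld_pool()
  gh <- pool_as_matrix(lp$pool)
  pr <- pairwise_r2(gh, max_dist = 7.5e4, min_lines = 150)
  br <- cut(pr$dist, breaks = seq(0, 7.5e4, by = 12500))
  obs <- tapply(pr$r2, br, mean)
  mid <- tapply(pr$dist, br, median)
  expect_true(all(table(br) > 1e4))
  model <- 1 / (1 + lp$cfg$p_sim * mid)
  expect_true(all(abs(obs / model - 1) < 0.10))
})

test_that("global decay fit on panel genotypes recovers the generating rate", {
  lp <- ld_pool()
  cfg <- lp$cfg
  cfg$n_lines <- 120
  g <- simulate_inbred_lines(lp$pool, cfg, seed = 5)
  gf <- apply_gwas_filters(g, NULL, min_called_lines = 60, maf_min = 0.04)
  pr <- pairwise_r2(gf, max_dist = 7.5e4, min_lines = 40)
  expect_gt(nrow(pr), 1e4)
  fit <- fit_decay(pr)
  expect_lt(abs(fit$half_decay_bp * cfg$p_sim - 1), 0.10)
})

test_that("inbreeding removes heterozygosity below the diploid expectation", {
  cfg <- sim_config(n_lines = 34, n_snps_per_chrom = 300,
                    chrom_lengths = setNames(rep(8e6, 5), paste0("chr", 1:5)),
                    seed = 10)
  pool <- simulate_founder_haplotypes(cfg)
  g9 <- simulate_inbred_lines(pool, cfg)
  het9 <- mean(attr(g9, "residual_het"))
  expect_lt(het9, 1 - inbreeding_coefficient(9))   # 14.1% diploid expectation
  expect_gt(het9, 0)                               # but some residual segregation
  cfg0 <- cfg; cfg0$generations <- 0
  g0 <- simulate_inbred_lines(pool, cfg0)
  # identity limit: no inbreeding reproduces founder diploid heterozygosity
  f <- colMeans(pool$H)
  expect_equal(mean(attr(g0, "residual_het")), mean(2 * f * (1 - f)),
               tolerance = 0.05)
  expect_identical(simulate_inbred_lines(pool, cfg, seed = 77)$calls,
                   simulate_inbred_lines(pool, cfg, seed = 77)$calls)
})

test_that("phenotype generator honours degenerate configurations", {
  p <- small_panel()
  cfg <- p$config
  cfg$sigma2_line <- 0
  br <- simulate_phenotypes(p$genotypes, cfg, seed = 1)
  tr <- attr(br, "truth")
  expect_true(all(abs(tr$lines$p_line - plogis(cfg$beta0)) < 1e-12))
  cfg$beta0 <- 0
  br2 <- simulate_phenotypes(p$genotypes, cfg, seed = 2)
  expect_equal(mean(br2$sex_ratio), 0.5, tolerance = 0.02)  # symmetry
  cfg_bad <- cfg; cfg_bad$mu_clutch <- 1; cfg_bad$h2_clutch <- 0.9; cfg_bad$sd_clutch <- 30
  expect_error(suppressWarnings(simulate_phenotypes(p$genotypes, cfg_bad, seed = 3)),
               "positive")
})

test_that("line-variance calibration hits the requested heritability", {
  for (h2 in c(0.05, 0.106, 0.3)) {
    s2 <- calibrate_line_variance(h2, mu_clutch = 60, sd_clutch = 15)
    # verify with the same variance-partition arithmetic, independently coded
    u <- qnorm(seq(0.0005, 0.9995, by = 0.001), 0, sqrt(s2))
    vl <- var(asin(sqrt(plogis(qlogis(0.25) + u)))) * (length(u) - 1) / length(u)
    n <- 1:150
    w <- pnorm(n + 0.5, 60, 15) - pnorm(n - 0.5, 60, 15)
    vr <- sum(w / (4 * n)) / sum(w)
    expect_equal(vl / (vl + vr), h2, tolerance = 0.01)
  }
  expect_equal(calibrate_line_variance(0), 0)
})

test_that("causal SNPs land on common, decorrelated loci inside their window", {
  pl <- data.frame(chrom = "chr2", start = 1e6, end = 1.4e6, n_causal = 3,
                   beta_sr = 0.5, beta_clutch = 10)
  cfg <- sim_config(n_lines = 30, n_snps_per_chrom = 300,
                    chrom_lengths = setNames(rep(4e6, 5), paste0("chr", 1:5)),
                    rate_mixture = FALSE, freq_block_bp = 1e5,
                    pleiotropy = pl, n_wolbachia_lost = 0,
                    n_outlier_excluded = 0, seed = 8)
  panel <- simulate_panel(cfg)
  causal <- panel$truth$causal
  expect_equal(nrow(causal), 3)
  expect_true(all(causal$chrom == "chr2" & causal$pos >= 1e6 & causal$pos <= 1.4e6))
  maf <- snp_maf(panel$genotypes)[causal$snp]
  expect_true(all(maf >= cfg$causal_maf_min))
  # mixed effect directions on both traits
  expect_true(length(unique(sign(causal$beta_sr))) > 1 ||
                length(unique(sign(causal$beta_clutch))) > 1)
})
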