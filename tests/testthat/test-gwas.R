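# Scan fitters, permutation null and empirical threshold.

gwas_fixture <- function() cached("gwas_fixture", function() {
  cfg <- sim_config(n_lines = 25, n_snps_per_chrom = 60,
                    chrom_lengths = setNames(rep(4e6, 5), paste0("chr", 1:5)),
                    n_wolbachia_lost = 0, n_outlier_excluded = 0, seed = 77)
  panel <- simulate_panel(cfg)
  gf <- apply_gwas_filters(panel$genotypes, panel$meta)
  list(panel = panel, gf = gf)
})

test_that("adaptive-quadrature fit agrees with lme4::glmer", {
  fx <- gwas_fixture()
  b <- fx$panel$broods
  idx <- match(b$line_id, fx$gf$line_ids)
  for (j in c(5, 120)) {
    mine <- snp_association(b, fx$gf, j, "sex_ratio")
    gcall <- fx$gf$calls[idx, j]
    keep <- !is.na(gcall) & gcall != 1
    d <- data.frame(m = b$n_males[keep], f = b$n_females[keep],
                    g = (gcall[keep] == 2) * 1, line = b$line_id[keep])
    ref <- lme4::glmer(cbind(m, f) ~ g + (1 | line), data = d,
                       family = binomial, nAGQ = 9)
    co <- summary(ref)$coefficients
    expect_equal(mine$beta, co[2, 1], tolerance = 1e-3)
    expect_equal(mine$se, co[2, 2], tolerance = 1e-2)
  }
})

test_that("fast empirical-logit scan tracks the quadrature likelihood fit", {
  fx <- gwas_fixture()
  fast <- suppressWarnings(gwas_scan(fx$gf, fx$panel$broods, "sex_ratio"))
  slow <- suppressWarnings(gwas_scan(fx$gf[, 1:25], fx$panel$broods, "sex_ratio",
                                     method = "quadrature"))
  ok <- !is.na(slow$p_value)
  expect_gt(cor(fast$beta[1:25][ok], slow$beta[ok]), 0.999)
  expect_equal(fast$beta[1:25][ok], slow$beta[ok], tolerance = 0.05)
})

test_that("clutch scan matches lme4::lmer on a balanced panel", {
  fx <- gwas_fixture()
  res <- suppressWarnings(gwas_scan(fx$gf, fx$panel$broods, "clutch"))
  b <- fx$panel$broods
  idx <- match(b$line_id, fx$gf$line_ids)
  j <- 7
  gcall <- fx$gf$calls[idx, j]
  keep <- !is.na(gcall) & gcall != 1
  d <- data.frame(y = b$clutch_size[keep], g = (gcall[keep] == 2) * 1,
                  line = b$line_id[keep])
  ref <- lme4::lmer(y ~ g + (1 | line), data = d, REML = TRUE)
  expect_equal(res$beta[j], unname(lme4::fixef(ref)["g"]), tolerance = 1e-2)
})

test_that("p-values are invariant to allele label swap with flipped direction", {
  fx <- gwas_fixture()
  g <- fx$gf
  gsw <- g
  gsw$calls <- 2L - g$calls
  gsw$snps$ref <- g$snps$alt; gsw$snps$alt <- g$snps$ref
  a <- suppressWarnings(gwas_scan(g, fx$panel$broods, "sex_ratio"))
  b <- suppressWarnings(gwas_scan(gsw, fx$panel$broods, "sex_ratio"))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  expect_equal(a$beta, -b$beta, tolerance = 1e-10)
})

test_that("single-SNP association rejects monomorphic SNPs and finds effects", {
  fx <- gwas_fixture()
  mono <- fx$gf
  mono$calls[, 1] <- 0L
  expect_error(snp_association(fx$panel$broods, mono, 1, "sex_ratio"),
               "monomorphic")
  # inject a large line-level effect along SNP 10's genotype split
  cfg <- fx$panel$config
  cfg$causal_sr <- data.frame(chrom = fx$gf$snps$chrom[10],
                              pos = fx$gf$snps$pos[10], beta = 1)
  br <- simulate_phenotypes(fx$panel$genotypes, cfg, seed = 5)
  causal <- attr(br, "truth")$causal
  id <- paste0(causal$chrom, "_", causal$pos)
  hit <- snp_association(br, fx$gf, id, "sex_ratio")
  expect_lt(hit$p_value, 1e-4)
  expect_equal(sign(hit$beta), sign(causal$beta_sr))
})

test_that("permutation null is seeded, reproducible and has uniform minima", {
  fx <- gwas_fixture()
  g20 <- fx$gf[, 1:20]
  expect_error(permutation_null(g20, fx$panel$broods, "sex_ratio", n_perm = 0),
               "at least 1")
  n1 <- permutation_null(g20, fx$panel$broods, "sex_ratio", n_perm = 5, seed = 3)
  n2 <- permutation_null(g20, fx$panel$broods, "sex_ratio", n_perm = 5, seed = 3)
  expect_identical(n1$p, n2$p)
  # order statistics: min over 20 SNPs x 10 perms of ~U(0,1) has mean 1/201
  set.seed(8)
  mins <- vapply(1:30, function(k) {
    br <- simulate_phenotypes(fx$panel$genotypes, fx$panel$config, seed = 400 + k)
    min(unlist(permutation_null(g20, br, "sex_ratio", n_perm = 10,
                                seed = 500 + k)$p), na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(mins), 0.002)
  expect_lt(mean(mins), 0.010)
})

test_that("empirical threshold honours exchangeability and spiked mixtures", {
  # null identical to observed -> qhat ~ 1, nothing passes
  set.seed(9)
  obs <- runif(500)
  null_store <- structure(list(p = replicate(10, runif(500), simplify = FALSE),
                               n_perm = 10, trait = "sex_ratio", seed = 1),
                          class = "gwas_null")
  thr <- empirical_threshold(obs, null_store, q = 0.1)
  expect_equal(thr$n_significant, 0)
  expect_gt(thr$min_q, 0.3)
  # 10 observed p of 1e-8 spiked into a uniform background
  spiked <- c(rep(1e-8, 10), runif(490))
  thr2 <- empirical_threshold(spiked, null_store, q = 0.1)
  expect_gte(thr2$p_threshold, 1e-8)
  expect_gte(thr2$n_significant, 10)
  expect_error(empirical_threshold(numeric(0), null_store), "no observed")
  # threshold decreases as q decreases
  thr3 <- empirical_threshold(spiked, null_store, q = 0.01)
  expect_lte(thr3$p_threshold, thr2$p_threshold)
})

test_that("run_gwas recovers an injected causal SNP as the top hit, reproducibly", {
  cfg <- sim_config(n_lines = 25, n_snps_per_chrom = 100,
                    chrom_lengths = setNames(rep(4e6, 5), paste0("chr", 1:5)),
                    causal_sr = data.frame(chrom = "chr3", pos = 2e6, beta = 0.5),
                    n_wolbachia_lost = 0, n_outlier_excluded = 0, seed = 21)
  panel <- simulate_panel(cfg)
  run1 <- run_gwas(panel$genotypes, panel$broods, panel$meta,
                   traits = "sex_ratio", n_perm = 20, seed = 2)
  run2 <- run_gwas(panel$genotypes, panel$broods, panel$meta,
                   traits = "sex_ratio", n_perm = 20, seed = 2)
  expect_identical(run1$results$p_value, run2$results$p_value)
  expect_identical(run1$thresholds$sex_ratio$p_threshold,
                   run2$thresholds$sex_ratio$p_threshold)
  top <- run1$results[which.min(run1$results$p_value), ]
  causal <- panel$truth$causal
  expect_equal(top$chrom, causal$chrom)
  expect_equal(top$pos, causal$pos)
})

test_that("a causal SNP explaining most line variance is found at q = 0.1", {
  # power regression at panel scale: 25 lines x 38 broods, effect share > 50%
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_lines = 25, n_snps_per_chrom = 100,
                      chrom_lengths = setNames(rep(4e6, 5), paste0("chr", 1:5)),
                      causal_sr = data.frame(chrom = "chr2", pos = 2e6, beta = 0.4),
                      n_wolbachia_lost = 0, n_outlier_excluded = 0, seed = 600 + s)
    panel <- simulate_panel(cfg)
    gf <- apply_gwas_filters(panel$genotypes, panel$meta)
    res <- suppressWarnings(gwas_scan(gf, panel$broods, "sex_ratio"))
    null <- permutation_null(gf, panel$broods, "sex_ratio", n_perm = 20,
                             seed = 700 + s)
    thr <- empirical_threshold(res, null, q = 0.1)
    causal <- panel$truth$causal
    id <- paste0(causal$chrom, "_", causal$pos)
    p_causal <- res$p_value[match(id, res$snp_id)]
    hits <- hits + (!is.na(thr$p_threshold) && !is.na(p_causal) &&
                      p_causal <= thr$p_threshold)
  }
  expect_gte(hits, 8)
})
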