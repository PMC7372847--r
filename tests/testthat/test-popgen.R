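mk_sites <- function(n_ref, n_alt, chrom = "chr1", pos = seq_along(n_ref)) {
  d <- data.frame(chrom = chrom, pos = pos, n_ref = n_ref, n_alt = n_alt,
                  coverage = n_ref + n_alt, stringsAsFactors = FALSE)
  class(d) <- c("site_counts", "data.frame")
  d
}

test_that("coverage subsampling respects bounds and expectation", {
  s <- mk_sites(c(30, 450, 6), c(10, 100, 2))
  sub <- subsample_coverage(s, target = 20, max_cov = 400, min_cov = 10, seed = 1)
  expect_equal(sub$usable, c(TRUE, FALSE, FALSE))   # 550 > 400; 8 < 10
  expect_equal(sub$coverage[1], 20)
  expect_equal(sub$n_ref[1] + sub$n_alt[1], 20)
  # expectation: ref fraction 0.75, mean over seeds within 3 SE
  fr <- vapply(1:1000, function(k)
    subsample_coverage(mk_sites(30, 10), 20, seed = k)$n_ref / 20, numeric(1))
  se <- sd(fr) / sqrt(1000)
  expect_lt(abs(mean(fr) - 0.75), 3 * se)
  # reproducibility
  expect_identical(subsample_coverage(s, 20, seed = 9),
                   subsample_coverage(s, 20, seed = 9))
})

test_that("theta per site follows the harmonic-sum formula", {
  # 1000 usable sites at n = 20 draws, 5 segregating with minor count >= 5
  n_alt <- c(rep(8, 5), rep(0, 995))
  s <- mk_sites(20 - n_alt, n_alt, pos = 1:1000)
  s$usable <- TRUE
  wd <- window_diversity(s, window = 2000, min_count = 5,
                         min_covered_fraction = 0, site_density = 0.5)
  a1 <- sum(1 / 1:19)
  expect_equal(wd$S, 5)
  expect_equal(wd$theta, 5 / (a1 * 1000))
  expect_equal(wd$pi, (20 / 19) * (1 - 0.4^2 - 0.6^2) * 5 / 1000)
})

test_that("Tajima's D is exactly zero when pi equals theta by construction", {
  # n = 5 draws: three singleton sites (pi = 0.4) and two doubleton sites
  # (pi = 0.6) give total pi = 2.4 = S/a1 with S = 5, a1 = 25/12
  n_alt <- c(1, 1, 1, 2, 2, rep(0, 95))
  s <- mk_sites(5 - n_alt, n_alt, pos = 1:100)
  s$usable <- TRUE
  wd <- window_diversity(s, window = 200, min_count = 1,
                         min_covered_fraction = 0, site_density = 0.5)
  expect_equal(wd$S, 5)
  expect_equal(wd$tajimas_d, 0)
})

test_that("D is missing without segregating sites and signed by spectrum skew", {
  s0 <- mk_sites(rep(20, 50), rep(0, 50))
  s0$usable <- TRUE
  wd0 <- window_diversity(s0, window = 100, min_count = 2,
                          min_covered_fraction = 0, site_density = 0.5)
  expect_equal(wd0$S, 0)
  expect_true(is.na(wd0$tajimas_d))
  expect_equal(wd0$pi, 0)
  # excess intermediate-frequency alleles -> D > 0
  si <- mk_sites(rep(10, 50), rep(10, 50)); si$usable <- TRUE
  expect_gt(window_diversity(si, window = 100, min_count = 2,
                             min_covered_fraction = 0, site_density = 0.5)$tajimas_d, 0)
  # excess near-singletons -> D < 0
  sr <- mk_sites(rep(18, 50), rep(2, 50)); sr$usable <- TRUE
  expect_lt(window_diversity(sr, window = 100, min_count = 2,
                             min_covered_fraction = 0, site_density = 0.5)$tajimas_d, 0)
})

test_that("window statistics are invariant to allele label swap", {
  set.seed(2)
  n_alt <- rbinom(200, 20, 0.3)
  s <- mk_sites(20 - n_alt, n_alt, pos = 1:200); s$usable <- TRUE
  sw <- mk_sites(n_alt, 20 - n_alt, pos = 1:200); sw$usable <- TRUE
  w1 <- window_diversity(s, window = 500, min_covered_fraction = 0, site_density = 0.5)
  w2 <- window_diversity(sw, window = 500, min_covered_fraction = 0, site_density = 0.5)
  expect_equal(w1$pi, w2$pi)
  expect_equal(w1$theta, w2$theta)
  expect_equal(w1$tajimas_d, w2$tajimas_d)
})

test_that("pairwise F_ST identities: identical, opposite, and ratio of averages", {
  # identical lines sharing polymorphism -> clamped to 0
  calls <- rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 0L, 0L, 0L))
  g <- genotype_matrix(calls, data.frame(chrom = "c", pos = 1:4, ref = "A", alt = "G"),
                       c("A", "B", "C"))
  f <- pairwise_fst(g)
  expect_equal(unname(f$fst["A", "B"]), 0)
  expect_equal(diag(f$fst), setNames(rep(0, 3), c("A", "B", "C")))
  expect_true(isSymmetric(f$fst))
  # two lines fixed opposite everywhere -> 1
  g2 <- genotype_matrix(rbind(rep(0L, 5), rep(2L, 5)),
                        data.frame(chrom = "c", pos = 1:5, ref = "A", alt = "G"),
                        c("A", "B"))
  expect_equal(unname(pairwise_fst(g2)$fst["A", "B"]), 1)
  # hand-worked toy: frequencies (0,1), (0.5,0.5), (1,1)
  g3 <- genotype_matrix(rbind(c(0L, 1L, 2L), c(2L, 1L, 2L)),
                        data.frame(chrom = "c", pos = 1:3, ref = "A", alt = "G"),
                        c("A", "B"))
  # site1: N = 1, D = 1; site2: N = -0.5, D = 0.5; site3 not variable
  expect_equal(unname(pairwise_fst(g3)$fst["A", "B"]), 0.5 / 1.5)
  # identical fully fixed lines -> no variable site -> missing
  g4 <- genotype_matrix(rbind(c(0L, 2L), c(0L, 2L)),
                        data.frame(chrom = "c", pos = 1:2, ref = "A", alt = "G"),
                        c("A", "B"))
  f4 <- pairwise_fst(g4)
  expect_true(is.na(f4$fst["A", "B"]))
  expect_equal(f4$n_na_pairs, 1)
})

test_that("complete-linkage clustering matches a brute-force oracle", {
  p <- small_panel()
  gf <- apply_gwas_filters(p$genotypes, p$meta)
  f <- pairwise_fst(gf[1:5, ])
  hc <- cluster_lines(f)
  # brute-force agglomeration with maximum linkage
  d <- f$fst; active <- as.list(seq_len(5)); heights <- numeric()
  while (length(active) > 1) {
    best <- c(1, 2); bh <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) if (i < j) {
      h <- max(d[active[[i]], active[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  expect_equal(hc$height, heights)
  # two lines: single join at their F_ST
  f2 <- pairwise_fst(gf[1:2, ])
  expect_equal(cluster_lines(f2)$height, unname(f2$fst[1, 2]))
  f$fst[1, 2] <- f$fst[2, 1] <- NA
  expect_error(cluster_lines(f), "missing")
})

test_that("structure check matches a direct rank-correlation computation", {
  set.seed(12)
  ids <- sprintf("L%02d", 1:6)
  fst <- matrix(0, 6, 6, dimnames = list(ids, ids))
  fst[upper.tri(fst)] <- runif(15, 0.1, 0.5)
  fst <- fst + t(fst)
  f <- structure(list(fst = fst, n_sites = matrix(100L, 6, 6), n_na_pairs = 0L),
                 class = "fst_matrix")
  means <- setNames(c(0.21, 0.30, 0.18, 0.25, 0.33, 0.27), ids)
  chk <- structure_check(f, means)
  ut <- upper.tri(f$fst)
  rho <- cor(rank(f$fst[ut]), rank(abs(outer(means, means, "-"))[ut]))
  expect_equal(chk$rho, rho, tolerance = 1e-12)
  expect_false(chk$tied)
  expect_true(is.finite(chk$p_value))
  # F_ST strictly increasing in phenotype distance -> rho = 1
  m2 <- setNames(seq(0.1, 0.6, 0.1), rownames(f$fst))
  fmono <- f
  fmono$fst <- abs(outer(m2, m2, "-")) * 2
  expect_equal(structure_check(fmono, m2)$rho, 1)
  # completely tied phenotype -> 0 with flag
  tied <- structure_check(f, setNames(rep(0.25, 6), rownames(f$fst)))
  expect_equal(tied$rho, 0)
  expect_true(tied$tied)
  f2 <- structure(list(fst = fst[1:2, 1:2], n_sites = matrix(10L, 2, 2),
                       n_na_pairs = 0L), class = "fst_matrix")
  expect_error(structure_check(f2, c(L01 = 1, L02 = 2)), "three")
})

test_that("pooled site counts reflect genotype allele counts", {
  g <- genotype_matrix(rbind(c(0L, 1L), c(2L, NA)),
                       data.frame(chrom = "c", pos = 1:2, ref = "A", alt = "G"),
                       c("A", "B"))
  sc <- site_counts_from_genotypes(g)
  expect_equal(sc$n_ref, c(2, 1))
  expect_equal(sc$n_alt, c(2, 1))
  expect_equal(sc$coverage, c(4, 2))
})
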