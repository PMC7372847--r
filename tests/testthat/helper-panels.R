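# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small complete panel (25 lines, 500 SNPs over 5 short chromosomes).
small_panel <- function() cached("small_panel", function() {
  cfg <- sim_config(n_lines = 25, n_snps_per_chrom = 100,
                    chrom_lengths = setNames(rep(4e6, 5), paste0("chr", 1:5)),
                    n_wolbachia_lost = 3, n_outlier_excluded = 1, seed = 42)
  simulate_panel(cfg)
})

# A 10-SNP hand-coded genotype matrix for filter tests: 26 lines.
toy_filter_matrix <- function() {
  set.seed(7)
  nl <- 26
  calls <- matrix(0L, nl, 10)
  for (j in 1:10) calls[, j] <- sample(c(0L, 2L), nl, replace = TRUE)
  calls[, 3] <- 1L                      # het-only SNP: fixed after masking
  calls[, 5] <- c(2L, rep(0L, nl - 1))  # low-MAF SNP (1/25 after exclusion)
  calls[, 7] <- 0L; calls[1:12, 7] <- NA  # low call count
  calls[, 9] <- 2L                      # fixed alt
  snps <- data.frame(chrom = "chr1", pos = seq(1000, by = 1000, length.out = 10),
                     ref = "A", alt = "G")
  genotype_matrix(calls, snps, sprintf("L%02d", 1:nl))
}

toy_filter_meta <- function(g) data.frame(
  line_id = g$line_ids,
  wolbachia_positive = g$line_ids != "L26",
  excluded = FALSE, reason = "")

# Hand-built toy annotation: one 3-exon gene per strand on a random 6 kb
# sequence, CDS length divisible by 3 (same template as the generator).
toy_annotation <- function(seed = 5, strand = "+") {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq, "chrT"))
  off <- 2000
  feat <- data.frame(
    chrom = "chrT",
    start = off + c(1, 1, 1, 501, 1101, 151, 501, 1101),
    end   = off + c(1400, 1400, 300, 900, 1400, 300, 900, 1150),
    strand = strand,
    type  = c("gene", "mRNA", "exon", "exon", "exon", "CDS", "CDS", "CDS"),
    id    = c("g1", "t1", "t1_e1", "t1_e2", "t1_e3", "t1_cds", "t1_cds", "t1_cds"),
    parent = c(NA, "g1", "t1", "t1", "t1", "t1", "t1", "t1"),
    phase = c(NA, NA, NA, NA, NA, if (strand == "+") c(0, 0, 2) else c(2, 0, 0)),
    stringsAsFactors = FALSE)
  if (strand == "-") {
    # phases in transcription order (high coordinate first): 1150-end CDS
    # first (50 bp, phase 0), then 400 bp (phase 1? recompute): lengths in
    # transcription order are 50, 400, 150 -> phases 0, (3-50%%3)%%3 = 1,
    # (3-450%%3)%%3 = 0
    feat$phase[feat$type == "CDS"] <- c(0, 1, 0)[order(-feat$start[feat$type == "CDS"])]
  }
  list(ann = linepanel:::build_annotation(feat), genome = genome, offset = off,
       features = feat)
}

expect_snp_term <- function(calls, pos, term) {
  row <- calls[calls$pos == pos, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$so_term, term)
}
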