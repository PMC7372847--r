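# Variant-effect classification against a hand-built toy gene and a
# re-translation oracle.

base_at <- function(genome, pos) as.character(Biostrings::subseq(genome[["chrT"]], pos, pos))

# pick an alt allele that turns the codon holding `pos` into `target_aa`
# (oracle-free helper used to construct specific cases)
codon_of <- function(genome, off, cds_pos) {
  # plus-strand template: CDS pieces 151-300, 501-900, 1101-1150 (rel)
  rel <- c(151:300, 501:900, 1101:1150)
  gpos <- off + rel
  idx <- ((cds_pos - 1) %/% 3) * 3 + 1:3
  gpos[idx]
}

test_that("coding changes classify as synonymous, missense or stop gained", {
  toy <- toy_annotation(seed = 5, strand = "+")
  ann <- toy$ann; genome <- toy$genome; off <- toy$offset
  rel <- c(151:300, 501:900, 1101:1150)
  found <- c(syn = FALSE, mis = FALSE, stop = FALSE)
  for (cds_pos in seq(1, 598, by = 1)) {
    gpos <- codon_of(genome, off, cds_pos)
    codon <- paste(vapply(gpos, base_at, "", genome = genome), collapse = "")
    within <- (cds_pos - 1) %% 3 + 1
    ref <- substr(codon, within, within)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt
      aa_r <- Biostrings::GENETIC_CODE[[codon]]
      aa_a <- Biostrings::GENETIC_CODE[[alt_codon]]
      want <- if (aa_a == "*" && aa_r != "*") "stop" else if (aa_r == aa_a) "syn" else "mis"
      if (found[[want]]) next
      pos <- gpos[within]
      call <- classify_variant("chrT", pos, ref, alt, ann, genome)
      term <- call$so_term[!is.na(call$tx_id)][1]
      expected <- c(syn = "synonymous_variant", mis = "missense_variant",
                    stop = "stop_gained")[[want]]
      expect_equal(term, expected, label = paste("cds", cds_pos, alt))
      found[[want]] <- TRUE
    }
    if (all(found)) break
  }
  expect_true(all(found))
})

test_that("full CDS scan agrees with a whole-protein re-translation oracle", {
  toy <- toy_annotation(seed = 6, strand = "+")
  ann <- toy$ann; genome <- toy$genome; off <- toy$offset
  rel <- c(151:300, 501:900, 1101:1150)
  cds_seq <- paste(vapply(off + rel, base_at, "", genome = genome), collapse = "")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                             if.fuzzy.codon = "X"))
  set.seed(1)
  for (cds_pos in sample(598, 60)) {
    gpos_all <- off + rel
    pos <- gpos_all[cds_pos]
    ref <- base_at(genome, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mut <- cds_seq
    substr(mut, cds_pos, cds_pos) <- alt
    prot2 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                                if.fuzzy.codon = "X"))
    aa_i <- (cds_pos - 1) %/% 3 + 1
    aa_r <- substr(prot, aa_i, aa_i); aa_a <- substr(prot2, aa_i, aa_i)
    want <- if (aa_a == "*" && aa_r != "*") "stop_gained"
    else if (aa_r == aa_a) "synonymous_variant" else "missense_variant"
    call <- classify_variant("chrT", pos, ref, alt, ann, genome)
    expect_equal(call$so_term[!is.na(call$tx_id)][1], want,
                 label = paste("cds_pos", cds_pos))
  }
})

test_that("non-coding regions classify by position and strand", {
  toy <- toy_annotation(seed = 5, strand = "+")
  ann <- toy$ann; genome <- toy$genome; off <- toy$offset
  probe <- function(pos) {
    ref <- base_at(genome, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    classify_variant("chrT", pos, ref, alt, ann, genome)
  }
  expect_equal(probe(off + 50)$so_term[1], "5_prime_UTR_variant")
  expect_equal(probe(off + 1300)$so_term[1], "3_prime_UTR_variant")
  expect_equal(probe(off + 400)$so_term[1], "intron_variant")
  expect_equal(probe(off - 100)$so_term[1], "upstream_gene_variant")
  expect_equal(probe(off + 1400 + 100)$so_term[1], "downstream_gene_variant")
  ref <- base_at(genome, off - 300)
  far <- classify_variant("chrT", off - 300, ref,
                          setdiff(c("A", "C", "G", "T"), ref)[1],
                          ann, genome, updown_bp = 200)
  expect_equal(far$so_term[1], "intergenic_variant")
  # splice region: 2 bp inside an internal exon end, carried as a flag
  sp <- probe(off + 899)
  expect_true(sp$splice_region[1])
  expect_match(sp$label[1], "splice_region_variant & ")
  # 5 bp into the intron
  expect_true(probe(off + 905)$splice_region[1])
  expect_false(probe(off + 700)$splice_region[1])
})

test_that("minus-strand genes mirror the classification", {
  toy <- toy_annotation(seed = 5, strand = "-")
  ann <- toy$ann; genome <- toy$genome; off <- toy$offset
  probe <- function(pos) {
    ref <- base_at(genome, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    classify_variant("chrT", pos, ref, alt, ann, genome)
  }
  # UTR sides flip with strand
  expect_equal(probe(off + 50)$so_term[1], "3_prime_UTR_variant")
  expect_equal(probe(off + 1300)$so_term[1], "5_prime_UTR_variant")
  expect_equal(probe(off - 100)$so_term[1], "downstream_gene_variant")
  expect_equal(probe(off + 1500)$so_term[1], "upstream_gene_variant")
})

test_that("classification is symmetric under reverse complementation", {
  toy <- toy_annotation(seed = 9, strand = "+")
  L <- length(toy$genome[[1]])
  # mirrored fixture: reverse-complement genome, flip strand and coordinates
  rcg <- Biostrings::reverseComplement(toy$genome)
  names(rcg) <- "chrT"
  feat <- toy$features
  feat2 <- feat
  feat2$start <- L + 1 - feat$end
  feat2$end <- L + 1 - feat$start
  feat2$strand <- "-"
  cds <- feat$type == "CDS"
  feat2$phase[cds] <- feat$phase[cds]   # same phases in transcription order
  ann2 <- linepanel:::build_annotation(feat2)
  set.seed(2)
  rel <- c(151:300, 501:900, 1101:1150)
  for (cds_pos in sample(598, 25)) {
    pos <- toy$offset + rel[cds_pos]
    ref <- base_at(toy$genome, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    c1 <- classify_variant("chrT", pos, ref, alt, toy$ann, toy$genome)
    pos2 <- L + 1 - pos
    c2 <- classify_variant("chrT", pos2, chartr("ACGT", "TGCA", ref),
                           chartr("ACGT", "TGCA", alt), ann2, rcg)
    i1 <- which(!is.na(c1$tx_id))[1]; i2 <- which(!is.na(c2$tx_id))[1]
    expect_equal(c1$so_term[i1], c2$so_term[i2], label = paste("pos", pos))
    expect_equal(c1$aa_change[i1], c2$aa_change[i2], label = paste("aa", pos))
  }
})

test_that("annotation model validation and reference checks fire", {
  toy <- toy_annotation(seed = 5, strand = "+")
  bad <- toy$features
  bad$end[bad$type == "CDS"][3] <- bad$end[bad$type == "CDS"][3] + 1
  expect_error(linepanel:::build_annotation(bad), "divisible by 3")
  ref <- base_at(toy$genome, toy$offset + 10)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(classify_variant("chrT", toy$offset + 10, wrong, ref,
                                toy$ann, toy$genome), "mismatch")
  expect_error(classify_variant("chrX", 5, "A", "G", toy$ann, toy$genome), "absent")
})

test_that("GFF3 + FASTA round trip through the writer and rtracklayer", {
  p <- small_panel()
  d <- withr::local_tempdir()
  gff <- file.path(d, "ann.gff3"); fa <- file.path(d, "genome.fa")
  write_annotation(p$annotation, gff, fa)
  ann <- read_annotation(gff)
  expect_equal(nrow(ann$genes), nrow(p$annotation$ann$genes))
  expect_equal(ann$cds$phase, p$annotation$ann$cds$phase)
  genome <- Biostrings::readDNAStringSet(fa)
  names(genome) <- sub("\\s.*", "", names(genome))
  calls <- classify_variants(p$genotypes, ann, genome)
  expect_gt(attr(calls, "skipped"), 0)
  expect_true(all(calls$so_term %in% linepanel:::SO_SEVERITY))
})

test_that("effect summary counts and pN/pS arithmetic", {
  es <- effect_summary_from_counts(12344, 6634, 89)
  expect_equal(es$n_nonsynonymous, 6723)
  expect_equal(es$pn_ps, 0.545)
  expect_equal(effect_summary_from_counts(1, 1, 0)$pn_ps, 1)
  expect_true(is.na(effect_summary_from_counts(0, 5, 1)$pn_ps))
  # severity selection: one SNP with stop_gained on one transcript and
  # synonymous on another counts once, as stop_gained
  calls <- data.frame(chrom = "c", pos = c(1, 1, 2), gene_id = "g", tx_id = c("t1", "t2", "t1"),
                      so_term = c("synonymous_variant", "stop_gained", "missense_variant"),
                      splice_region = FALSE, aa_change = NA, label = NA,
                      stringsAsFactors = FALSE)
  es2 <- effect_summary(calls)
  expect_equal(es2$n_nonsense, 1)
  expect_equal(es2$n_missense, 1)
  expect_equal(es2$n_synonymous, 0)
  expect_equal(es2$pn_ps, NA_real_)
})
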