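#' Generate a toy gene annotation and matching reference sequence
#'
#' Builds a small synthetic annotation over the first
#' `cfg$annotation_region_bp` of chromosome 1: a handful of three-exon
#' protein-coding genes on alternating strands, each with 5' and 3' UTRs and
#' a CDS whose length is divisible by 3.  The reference sequence is random
#' DNA with the panel's SNP reference alleles substituted at their
#' positions, so every SNP in the region validates against the genome.
#'
#' @param g a [genotype_matrix()] (supplies SNP positions and ref alleles).
#' @param cfg a [sim_config()].
#' @param seed integer seed; defaults to `cfg$seed + 4`.
#' @param n_genes number of genes to place (default 4).
#' @return list of class `toy_annotation` with elements `ann` (an
#'   `annotation_model`), `features` (flat GFF3-style feature table),
#'   `genome` (a [Biostrings::DNAStringSet]) and `region`.
#' @export
simulate_annotation <- function(g, cfg, seed = cfg$seed + 4L, n_genes = 4) {
  set.seed(seed)
  chrom <- names(cfg$chrom_lengths)[1]
  L <- min(cfg$annotation_region_bp, cfg$chrom_lengths[1])
  seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  in_region <- g$snps$chrom == chrom & g$snps$pos <= L
  seq[g$snps$pos[in_region]] <- g$snps$ref[in_region]

  # gene template, relative 1-based coordinates
  ex <- rbind(c(1, 300), c(501, 900), c(1101, 1400))
  cd <- rbind(c(151, 300), c(501, 900), c(1101, 1150))  # 600 bp CDS
  span <- 1400
  gap <- max(2000, floor((L - n_genes * span) / (n_genes + 1)))
  feats <- list()
  for (k in seq_len(n_genes)) {
    off <- (k - 1) * (span + gap) + gap
    if (off + span > L) break
    strand <- if (k %% 2 == 1) "+" else "-"
    gid <- sprintf("gene%02d", k); tid <- sprintf("tx%02d", k)
    add <- function(type, s, e, id = NA, parent = NA, phase = NA)
      data.frame(chrom = chrom, start = off + s, end = off + e, strand = strand,
                 type = type, id = id, parent = parent, phase = phase,
                 stringsAsFactors = FALSE)
    cdo <- cd[order(cd[, 1], decreasing = (strand == "-")), , drop = FALSE]
    lens <- cdo[, 2] - cdo[, 1] + 1
    phase <- c(0, cumsum(lens)[-length(lens)] %% 3)
    phase <- (3 - phase) %% 3  # standard GFF3 phase of each segment
    phase[1] <- 0
    cds_rows <- lapply(seq_len(nrow(cdo)), function(i)
      add("CDS", cdo[i, 1], cdo[i, 2], id = paste0(tid, "_cds"), parent = tid,
          phase = phase[i]))
    feats[[length(feats) + 1]] <- do.call(rbind, c(
      list(add("gene", 1, span, id = gid),
           add("mRNA", 1, span, id = tid, parent = gid),
           add("exon", ex[1, 1], ex[1, 2], id = paste0(tid, "_e1"), parent = tid),
           add("exon", ex[2, 1], ex[2, 2], id = paste0(tid, "_e2"), parent = tid),
           add("exon", ex[3, 1], ex[3, 2], id = paste0(tid, "_e3"), parent = tid)),
      cds_rows))
  }
  features <- do.call(rbind, feats)

  # force a valid start/stop-free reading frame is unnecessary for the toy
  # model, but avoid premature effects being degenerate: sequence is random.
  genome <- Biostrings::DNAStringSet(setNames(paste(seq, collapse = ""), chrom))
  structure(list(ann = build_annotation(features), features = features,
                 genome = genome, region = c(chrom = chrom, start = 1, end = L)),
            class = "toy_annotation")
}

#' Write a toy annotation as GFF3 + FASTA
#'
#' @param annotation a [simulate_annotation()] result.
#' @param gff_path,fasta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_annotation <- function(annotation, gff_path, fasta_path) {
  f <- annotation$features
  attrs <- ifelse(is.na(f$parent),
                  paste0("ID=", f$id),
                  ifelse(is.na(f$id), paste0("Parent=", f$parent),
                         paste0("ID=", f$id, ";Parent=", f$parent)))
  lines <- paste(f$chrom, "linepanel", f$type, f$start, f$end, ".",
                 f$strand, ifelse(is.na(f$phase), ".", f$phase), attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), gff_path)
  Biostrings::writeXStringSet(annotation$genome, fasta_path)
  invisible(c(gff_path, fasta_path))
}
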