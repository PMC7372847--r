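#' Read a gene annotation model from GFF3
#'
#' Parses gene / mRNA / exon / CDS features into the internal annotation
#' model and validates it: exons must not overlap within a transcript, CDS
#' spans must lie inside exons, and the total CDS length (after phase
#' adjustment of the first coding segment) must be divisible by 3.
#'
#' @param gff_path path to a GFF3 file.
#' @return object of class `annotation_model`: list of data frames `genes`,
#'   `transcripts`, `exons`, `cds`.
#' @export
read_annotation <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  type = as.character(gr$type),
                  id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
                  phase = if (is.null(gr$phase)) NA_integer_ else as.integer(gr$phase),
                  stringsAsFactors = FALSE)
  par <- gr$Parent
  d$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(x) if (length(x)) x[[1]] else NA_character_, character(1))
  build_annotation(d)
}

# Build and validate the annotation model from a flat feature table with
# columns chrom, start, end, strand, type, id, parent, phase.
build_annotation <- function(d) {
  genes <- d[d$type == "gene", c("id", "chrom", "start", "end", "strand")]
  names(genes)[1] <- "gene_id"
  tx <- d[d$type %in% c("mRNA", "transcript"), c("id", "parent", "chrom", "start", "end", "strand")]
  names(tx)[1:2] <- c("tx_id", "gene_id")
  exons <- d[d$type == "exon", c("parent", "start", "end")]
  names(exons)[1] <- "tx_id"
  cds <- d[d$type == "CDS", c("parent", "start", "end", "phase")]
  names(cds)[1] <- "tx_id"
  for (t in tx$tx_id) {
    ex <- exons[exons$tx_id == t, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", t)
    cd <- cds[cds$tx_id == t, ]
    if (nrow(cd)) {
      in_exon <- vapply(seq_len(nrow(cd)), function(i)
        any(ex$start <= cd$start[i] & ex$end >= cd$end[i]), logical(1))
      if (!all(in_exon)) stop("CDS outside exons in transcript ", t)
      strand <- tx$strand[tx$tx_id == t][1]
      cd <- cd[order(cd$start, decreasing = (strand == "-")), ]
      ph <- cd$phase[1]
      if (is.na(ph)) ph <- 0L
      tot <- sum(cd$end - cd$start + 1) - ph
      if (tot %% 3 != 0)
        stop("CDS length of transcript ", t, " not divisible by 3")
    }
  }
  structure(list(genes = genes, transcripts = tx, exons = exons, cds = cds),
            class = "annotation_model")
}

#' @export
print.annotation_model <- function(x, ...) {
  cat("annotation_model:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter")

SO_SEVERITY <- c("stop_gained", "missense_variant", "splice_region_variant",
                 "synonymous_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
                 "intron_variant", "upstream_gene_variant", "downstream_gene_variant",
                 "intergenic_variant")

revcomp1 <- function(x) chartr("ACGT", "TGCA", x)

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify the predicted effect of one SNP
#'
#' Assigns Sequence Ontology terms per overlapping transcript, strand- and
#' phase-aware.  Inside CDS the reference and alternate codons are
#' translated: a stop-introducing change is `stop_gained`, an amino-acid
#' change `missense_variant`, a silent change `synonymous_variant` (with
#' protein notation such as `p.Ala2Ala`).  Exonic non-CDS positions become
#' 5' or 3' UTR variants by transcription direction, intronic positions
#' `intron_variant`, positions within `updown_bp` of a gene
#' `upstream_gene_variant`/`downstream_gene_variant`, and everything else
#' `intergenic_variant`.  Positions within `splice_exon_bp` of an
#' exon/intron junction (exonic side) or `splice_intron_bp` into the intron
#' additionally carry a splice-region flag.
#'
#' @param chrom,pos,ref,alt the SNP (1-based position, single nucleotides).
#' @param ann an [read_annotation()] model.
#' @param genome a named [Biostrings::DNAStringSet] of reference sequences.
#' @param updown_bp up/downstream window (default 5000).
#' @param splice_exon_bp,splice_intron_bp splice-region extent into the exon
#'   (1-3 bp) and intron (3-8 bp), following common annotation-tool
#'   convention.
#' @return data frame with one row per (SNP, transcript) call: `chrom`,
#'   `pos`, `gene_id`, `tx_id`, `so_term`, `splice_region`, `aa_change`,
#'   `label` (term with ` & splice_region_variant` appended when flagged).
#' @export
classify_variant <- function(chrom, pos, ref, alt, ann, genome,
                             updown_bp = 5000, splice_exon_bp = 3,
                             splice_intron_bp = 8) {
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " absent from genome")
  seqlen <- length(genome[[chrom]])
  if (pos < 1 || pos > seqlen) stop("position ", pos, " outside sequence ", chrom)
  gbase <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (gbase != ref)
    stop("reference mismatch at ", chrom, ":", pos, " (VCF ", ref, ", genome ", gbase, ")")

  out <- list()
  genes <- ann$genes[ann$genes$chrom == chrom, ]
  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, ]
    in_gene <- pos >= gene$start & pos <= gene$end
    near <- pos >= gene$start - updown_bp & pos <= gene$end + updown_bp
    if (!near) next
    if (!in_gene) {
      before <- pos < gene$start
      term <- if ((before && gene$strand == "+") || (!before && gene$strand == "-"))
        "upstream_gene_variant" else "downstream_gene_variant"
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, pos = pos, gene_id = gene$gene_id, tx_id = NA_character_,
        so_term = term, splice_region = FALSE, aa_change = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    txs <- ann$transcripts[ann$transcripts$gene_id == gene$gene_id, ]
    for (ti in seq_len(nrow(txs))) {
      tx <- txs[ti, ]
      ex <- ann$exons[ann$exons$tx_id == tx$tx_id, ]
      ex <- ex[order(ex$start), ]
      cd <- ann$cds[ann$cds$tx_id == tx$tx_id, ]
      splice <- is_splice_region(pos, ex, splice_exon_bp, splice_intron_bp)
      in_exon <- any(pos >= ex$start & pos <= ex$end)
      aa_change <- NA_character_
      if (!in_exon) {
        term <- "intron_variant"
      } else if (nrow(cd) && any(pos >= cd$start & pos <= cd$end)) {
        cc <- classify_coding(pos, ref, alt, cd, tx$strand, chrom, genome)
        term <- cc$term; aa_change <- cc$aa_change
      } else if (nrow(cd)) {
        cds_lo <- min(cd$start); cds_hi <- max(cd$end)
        five <- (tx$strand == "+" && pos < cds_lo) || (tx$strand == "-" && pos > cds_hi)
        term <- if (five) "5_prime_UTR_variant" else "3_prime_UTR_variant"
      } else {
        term <- "intron_variant"  # non-coding transcript exon: nearest available term
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, pos = pos, gene_id = gene$gene_id, tx_id = tx$tx_id,
        so_term = term, splice_region = splice, aa_change = aa_change,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    out[[1]] <- data.frame(chrom = chrom, pos = pos, gene_id = NA_character_,
                           tx_id = NA_character_, so_term = "intergenic_variant",
                           splice_region = FALSE, aa_change = NA_character_,
                           stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  res$label <- ifelse(res$splice_region & !res$so_term %in% "splice_region_variant",
                      paste0("splice_region_variant & ", res$so_term), res$so_term)
  res
}

# splice region: 1..k bp inside an exon boundary that adjoins an intron, or
# a..b bp into the intron.
is_splice_region <- function(pos, ex, k_ex, k_in) {
  if (nrow(ex) < 2) return(FALSE)
  for (i in seq_len(nrow(ex))) {
    if (i > 1 && pos >= ex$start[i] && pos <= ex$start[i] + k_ex - 1) return(TRUE)
    if (i < nrow(ex) && pos <= ex$end[i] && pos >= ex$end[i] - k_ex + 1) return(TRUE)
  }
  for (i in seq_len(nrow(ex) - 1)) {
    if (pos >= ex$end[i] + 3 && pos <= ex$end[i] + k_in) return(TRUE)
    if (pos <= ex$start[i + 1] - 3 && pos >= ex$start[i + 1] - k_in) return(TRUE)
  }
  FALSE
}

classify_coding <- function(pos, ref, alt, cd, strand, chrom, genome) {
  cd <- cd[order(cd$start, decreasing = (strand == "-")), ]
  ph <- cd$phase[1]
  if (is.na(ph)) ph <- 0L
  # genomic positions of the CDS in transcription order
  gpos <- unlist(lapply(seq_len(nrow(cd)), function(i) {
    p <- cd$start[i]:cd$end[i]
    if (strand == "-") rev(p) else p
  }))
  if (ph > 0) gpos <- gpos[-seq_len(ph)]
  cpos <- match(pos, gpos)
  if (is.na(cpos)) stop("internal: position not in CDS after phase trim")
  codon_i <- (cpos - 1) %/% 3 + 1
  idx <- ((codon_i - 1) * 3 + 1):(codon_i * 3)
  codon_gpos <- gpos[idx]
  bases <- vapply(codon_gpos, function(p)
    as.character(Biostrings::subseq(genome[[chrom]], p, p)), character(1))
  if (strand == "-") bases <- revcomp1(bases)
  ref_codon <- paste(bases, collapse = "")
  within <- which(codon_gpos == pos)
  alt_base <- if (strand == "-") revcomp1(alt) else alt
  alt_bases <- bases
  alt_bases[within] <- alt_base
  alt_codon <- paste(alt_bases, collapse = "")
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  term <- if (aa_alt == "*" && aa_ref != "*") "stop_gained"
  else if (aa_ref == aa_alt) "synonymous_variant"
  else "missense_variant"
  list(term = term,
       aa_change = paste0("p.", AA3[[aa_ref]], codon_i, AA3[[aa_alt]]))
}

#' Classify all SNPs of a genotype matrix
#'
#' Applies [classify_variant()] to every SNP whose position is covered by
#' the supplied reference sequences; uncovered SNPs are skipped and counted.
#'
#' @param g a [genotype_matrix()].
#' @param ann an [read_annotation()] model.
#' @param genome named [Biostrings::DNAStringSet].
#' @param ... passed to [classify_variant()].
#' @return data frame of per-(SNP, transcript) calls with attribute
#'   `"skipped"` (count of SNPs outside the reference sequences).
#' @export
classify_variants <- function(g, ann, genome, ...) {
  covered <- g$snps$chrom %in% names(genome) &
    g$snps$pos <= vapply(g$snps$chrom, function(ch)
      if (ch %in% names(genome)) length(genome[[ch]]) else 0L, numeric(1))
  rows <- lapply(which(covered), function(j)
    classify_variant(g$snps$chrom[j], g$snps$pos[j], g$snps$ref[j], g$snps$alt[j],
                     ann, genome, ...))
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), gene_id = character(),
               tx_id = character(), so_term = character(), splice_region = logical(),
               aa_change = character(), label = character())
  attr(res, "skipped") <- sum(!covered)
  res
}

#' Summarise variant-effect calls
#'
#' Selects one primary call per SNP by a fixed severity order
#' (`stop_gained > missense > splice_region > synonymous > 5'UTR > 3'UTR >
#' intron > upstream/downstream > intergenic`; a splice-region flag promotes
#' a call to the splice level for selection) and tabulates category counts.
#' The headline ratio `pn_ps` is the raw count ratio of nonsynonymous
#' (missense + nonsense) to synonymous variants — an unnormalised proxy for
#' a dN/dS-style constraint measure, not a rate-corrected dN/dS.
#'
#' @param calls data frame from [classify_variants()].
#' @param digits rounding applied to `pn_ps` (default 3).
#' @return object of class `effect_summary`: list with `counts` (named
#'   vector over SO terms), `n_splice_region`, `n_synonymous`, `n_missense`,
#'   `n_nonsense`, `n_nonsynonymous`, `pn_ps`.
#' @export
effect_summary <- function(calls, digits = 3) {
  if (nrow(calls)) {
    sev <- match(calls$so_term, SO_SEVERITY)
    sev[calls$splice_region] <- pmin(sev[calls$splice_region],
                                     match("splice_region_variant", SO_SEVERITY))
    key <- paste(calls$chrom, calls$pos)
    ord <- order(key, sev)
    primary <- calls[ord, ][!duplicated(key[ord]), ]
  } else primary <- calls
  counts <- table(factor(primary$so_term, levels = SO_SEVERITY))
  effect_summary_from_counts(
    n_synonymous = unname(counts["synonymous_variant"]),
    n_missense = unname(counts["missense_variant"]),
    n_nonsense = unname(counts["stop_gained"]),
    counts = as.vector(counts) |> setNames(SO_SEVERITY),
    n_splice_region = sum(primary$splice_region),
    digits = digits)
}

#' Variant-effect summary from raw category counts
#'
#' Arithmetic-only path: derives the nonsynonymous count and the pN/pS
#' ratio from given synonymous, missense and nonsense counts.
#'
#' @param n_synonymous,n_missense,n_nonsense category counts.
#' @param counts optional full named count vector to carry along.
#' @param n_splice_region optional splice-region count.
#' @param digits rounding for `pn_ps`.
#' @return an `effect_summary` object (see [effect_summary()]).
#' @export
effect_summary_from_counts <- function(n_synonymous, n_missense, n_nonsense,
                                       counts = NULL, n_splice_region = NA_integer_,
                                       digits = 3) {
  n_nonsyn <- n_missense + n_nonsense
  pn_ps <- if (n_synonymous > 0) round(n_nonsyn / n_synonymous, digits) else NA_real_
  structure(list(counts = counts, n_splice_region = n_splice_region,
                 n_synonymous = n_synonymous, n_missense = n_missense,
                 n_nonsense = n_nonsense, n_nonsynonymous = n_nonsyn,
                 pn_ps = pn_ps),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("Variant effect summary\n")
  if (!is.null(x$counts)) {
    for (nm in names(x$counts))
      if (x$counts[nm] > 0) cat(sprintf("  %-26s %d\n", nm, x$counts[nm]))
  }
  cat(sprintf("  nonsynonymous = %d (missense %d + nonsense %d), synonymous = %d\n",
              x$n_nonsynonymous, x$n_missense, x$n_nonsense, x$n_synonymous))
  cat(sprintf("  pN/pS = %s\n", format(x$pn_ps)))
  invisible(x)
}
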