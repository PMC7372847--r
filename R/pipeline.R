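# End-to-end pipeline: simulate/load -> filter -> popgen -> LD -> h2 ->
# GWAS -> overlap -> effects, driven by a single validated configuration
# with a master seed, writing file artifacts plus a checksummed manifest.

PIPELINE_STAGES <- c("simulate", "filter", "popgen", "ld", "h2", "gwas",
                     "overlap", "effects")

#' Build and validate a pipeline configuration
#'
#' @param ... configuration entries; unknown keys are rejected.  Recognised
#'   keys: `out_dir` (required), `seed` (required), input paths `vcf`,
#'   `broods`, `meta`, `gff`, `fasta` (all optional when `simulate = TRUE`),
#'   `simulate` (logical; default TRUE when no `vcf` is given), `sim`
#'   (list of [sim_config()] overrides), `min_called_lines`, `maf_min`,
#'   `window_bp`, `step_bp`, `ld_max_dist`, `ld_min_lines`, `q`, `n_perm`,
#'   `overlap_window_sizes`, `overlap_max_rank`, `updown_bp`, `stages`
#'   (subset of the stage names to run).
#' @param file optional YAML file whose keys are merged (flags in `...`
#'   override the file).
#' @return list of class `pipeline_config` with defaults filled in.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(...)
  if (!is.null(file)) {
    fromfile <- yaml::read_yaml(file)
    cfg <- utils::modifyList(fromfile, cfg)
  }
  known <- c("out_dir", "seed", "vcf", "broods", "meta", "gff", "fasta",
             "simulate", "sim", "min_called_lines", "maf_min", "window_bp",
             "step_bp", "ld_max_dist", "ld_min_lines", "q", "n_perm",
             "overlap_window_sizes", "overlap_max_rank", "updown_bp", "stages")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  if (is.null(cfg$seed)) stop("config needs a seed")
  defaults <- list(simulate = is.null(cfg$vcf), sim = list(),
                   min_called_lines = 18, maf_min = 0.04,
                   window_bp = 400000, step_bp = 400000,
                   ld_max_dist = 1e6, ld_min_lines = 10, q = 0.1, n_perm = 100,
                   overlap_window_sizes = c(25, 50, 100, 200, 400) * 1000,
                   overlap_max_rank = 25, updown_bp = 5000,
                   stages = PIPELINE_STAGES)
  cfg <- utils::modifyList(defaults, cfg)
  cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (!cfg$simulate) {
    for (k in c("vcf", "broods", "meta"))
      if (is.null(cfg[[k]]) || !file.exists(cfg[[k]]))
        stop("input file for '", k, "' missing or not found")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Derive a reproducible per-stage seed from the master seed
#'
#' Hashes the stage name into the master seed so stages can be re-run in
#' isolation with the same randomness as in a full run.
#'
#' @param master master integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 97651L
  as.integer((as.numeric(master) * 1009 + h * 7919) %% 2147483629)
}

#' Run the full line-panel analysis pipeline
#'
#' Executes the configured stages in dependency order, writing each stage's
#' artifacts under `out_dir` together with a run log, the resolved
#' configuration, and a manifest listing every artifact with its MD5
#' checksum.  Fully deterministic given the configuration (including the
#' master seed, from which per-stage seeds are derived).
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_manifest`: `artifacts` (data frame with
#'   `file`, `md5`), `stages_run`, `config`, and in-memory results in
#'   `objects`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "pipeline.log")
  cat("", file = logfile)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg); cat(msg, "\n", file = logfile, append = TRUE)
  }
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(cfg$out_dir, "config_resolved.yaml"))
  arts <- character()
  add_art <- function(...) arts <<- unique(c(arts, unlist(list(...))))
  objects <- list()

  if (cfg$simulate && "simulate" %in% cfg$stages) {
    say("simulate: generating synthetic panel")
    sim <- do.call(sim_config, utils::modifyList(cfg$sim,
                                                 list(seed = derive_seed(cfg$seed, "simulate"))))
    panel <- simulate_panel(sim)
    fix_dir <- file.path(cfg$out_dir, "fixture")
    p <- write_fixture(fix_dir, panel$genotypes, panel$broods, panel$meta,
                       panel$annotation, panel$truth)
    add_art(p)
    cfg$vcf <- p[["vcf"]]; cfg$broods <- p[["broods"]]; cfg$meta <- p[["meta"]]
    cfg$gff <- p[["gff"]]; cfg$fasta <- p[["fasta"]]
    objects$truth <- panel$truth
  }

  say("load: reading genotypes, broods, metadata")
  g <- read_genotype_matrix(cfg$vcf)
  broods <- read_brood_table(cfg$broods)
  meta <- read_line_metadata(cfg$meta)

  gf <- g
  if ("filter" %in% cfg$stages) {
    say("filter: applying panel GWAS filters")
    gf <- apply_gwas_filters(g, meta, cfg$min_called_lines, cfg$maf_min)
    add_art(write_filter_log(gf, file.path(cfg$out_dir, "filter_log.tsv")))
    log <- attr(gf, "filter_log")
    for (i in seq_len(nrow(log)))
      say("filter: %-18s removed %6d, remaining %6d",
          log$step[i], log$removed[i], log$remaining[i])
  }
  objects$genotypes <- gf

  if ("popgen" %in% cfg$stages) {
    say("popgen: window diversity, F_ST, structure check")
    sc <- site_counts_from_genotypes(g)
    sub <- subsample_coverage(sc, target = 20, max_cov = 400,
                              min_cov = min(10, max(sc$coverage)),
                              seed = derive_seed(cfg$seed, "popgen"))
    wd <- window_diversity(sub, window = cfg$window_bp, step = cfg$step_bp)
    add_art(write_window_diversity(wd, file.path(cfg$out_dir, "window_diversity.tsv")))
    fst <- pairwise_fst(gf)
    utils::write.table(fst$fst, file.path(cfg$out_dir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    add_art(file.path(cfg$out_dir, "fst_matrix.tsv"))
    sr_means <- tapply(broods$sex_ratio, broods$line_id, mean)
    sr_means <- sr_means[names(sr_means) %in% gf$line_ids]
    chk <- structure_check(fst, sr_means)
    say("popgen: structure check r_s = %.3f, P = %.3g", chk$rho,
        ifelse(is.na(chk$p_value), NA, chk$p_value))
    objects$window_diversity <- wd; objects$fst <- fst; objects$structure <- chk
  }

  if ("ld" %in% cfg$stages) {
    say("ld: pairwise r2 and decay fit")
    pairs <- pairwise_r2(gf, max_dist = cfg$ld_max_dist, min_lines = cfg$ld_min_lines)
    fit <- fit_decay(pairs)
    say("ld: half-decay = %.1f kb over %d pairs", fit$half_decay_bp / 1000, fit$n_pairs)
    add_art(write_ld_table(pairs, file.path(cfg$out_dir, "ld_pairs.tsv")))
    land <- decay_landscape(gf, cfg$ld_max_dist, cfg$ld_min_lines, pairs = pairs)
    add_art(write_ld_table(land, file.path(cfg$out_dir, "ld_landscape.tsv")))
    objects$ld_fit <- fit; objects$ld_landscape <- land
  }

  if ("h2" %in% cfg$stages) {
    say("h2: among-line tests and heritability")
    keep <- broods$line_id %in% gf$line_ids
    b <- broods[keep, , drop = FALSE]
    alt <- among_line_ftest(b)
    h2_sr <- broad_sense_h2(b$sex_ratio, b$line_id, "arcsine-sqrt", trait = "sex_ratio")
    h2_cl <- broad_sense_h2(b$clutch_size, b$line_id, "identity", trait = "clutch_size")
    tc <- trait_correlation(tapply(b$clutch_size, b$line_id, mean),
                            tapply(b$sex_ratio, b$line_id, mean))
    h2df <- data.frame(trait = c("sex_ratio", "clutch_size"),
                       transform = c(h2_sr$transform, h2_cl$transform),
                       v_line = c(h2_sr$v_line, h2_cl$v_line),
                       v_res = c(h2_sr$v_res, h2_cl$v_res),
                       h2 = c(h2_sr$h2, h2_cl$h2),
                       lr = c(h2_sr$lr, h2_cl$lr),
                       p_value = c(h2_sr$p_value, h2_cl$p_value))
    utils::write.table(h2df, file.path(cfg$out_dir, "heritability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_art(file.path(cfg$out_dir, "heritability.tsv"))
    say("h2: sex ratio H2 = %.3f (LR %.2f), clutch H2 = %.3f (LR %.2f); among-line F_%d,%d = %.2f",
        h2_sr$h2, h2_sr$lr, h2_cl$h2, h2_cl$lr, alt$df1, alt$df2, alt$F)
    objects$among_line <- alt; objects$h2 <- list(sex_ratio = h2_sr, clutch = h2_cl)
    objects$trait_correlation <- tc
  }

  gw <- NULL
  if ("gwas" %in% cfg$stages) {
    say("gwas: single-marker scans with %d permutations", cfg$n_perm)
    gw <- run_gwas(gf, broods, meta = NULL, q = cfg$q, n_perm = cfg$n_perm,
                   seed = derive_seed(cfg$seed, "gwas"),
                   out_dir = file.path(cfg$out_dir, "gwas"))
    add_art(file.path(cfg$out_dir, "gwas",
                      c("associations.tsv", "thresholds.tsv",
                        "null_sex_ratio.tsv", "null_clutch.tsv")))
    for (tr in names(gw$thresholds))
      say("gwas: %s -> %d significant at q = %.2f", tr,
          gw$thresholds[[tr]]$n_significant, cfg$q)
    objects$gwas <- gw
  }

  if ("overlap" %in% cfg$stages) {
    if (is.null(gw)) stop("overlap stage requires the gwas stage")
    say("overlap: windowed rank-overlap with permutation null")
    res <- gw$results
    ov <- overlap_permutation(res[res$trait == "sex_ratio", ],
                              res[res$trait == "clutch", ],
                              n_perm = cfg$n_perm,
                              seed = derive_seed(cfg$seed, "overlap"),
                              window_sizes = cfg$overlap_window_sizes,
                              max_rank = cfg$overlap_max_rank)
    utils::write.table(as.data.frame(ov), file.path(cfg$out_dir, "overlap_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_art(file.path(cfg$out_dir, "overlap_windows.tsv"))
    say("overlap: %d window(s) significant", sum(ov$significant))
    objects$overlap <- ov
  }

  if ("effects" %in% cfg$stages && !is.null(cfg$gff) && !is.null(cfg$fasta)) {
    say("effects: variant-effect classification")
    ann <- read_annotation(cfg$gff)
    genome <- Biostrings::readDNAStringSet(cfg$fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    calls <- classify_variants(g, ann, genome, updown_bp = cfg$updown_bp)
    summ <- effect_summary(calls)
    utils::write.table(calls, file.path(cfg$out_dir, "variant_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_art(file.path(cfg$out_dir, "variant_effects.tsv"))
    writeLines(jsonlite::toJSON(unclass(summ), auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(cfg$out_dir, "effect_summary.json"))
    add_art(file.path(cfg$out_dir, "effect_summary.json"))
    say("effects: %d calls over %d SNPs in the annotated region",
        nrow(calls), length(unique(paste(calls$chrom, calls$pos))))
    objects$effects <- list(calls = calls, summary = summ)
  }

  # the timestamped log and the resolved config (which embeds out_dir) are
  # artifacts but stay out of the checksummed manifest, so that identical
  # configurations yield identical manifests wherever they are written
  arts <- arts[file.exists(arts)]
  manifest <- data.frame(file = sub(paste0("^", cfg$out_dir, "/?"), "", arts),
                         md5 = unname(tools::md5sum(arts)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("done: %d artifacts", nrow(manifest))
  structure(list(artifacts = manifest, stages_run = cfg$stages, config = cfg,
                 objects = objects),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline run:", nrow(x$artifacts), "artifacts in", x$config$out_dir, "\n")
  cat("  stages:", paste(x$stages_run, collapse = ", "), "\n")
  invisible(x)
}
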