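# End-to-end orchestration: (simulate | load) -> QC -> structure -> scan ->
# annotate, per breed dataset, with a YAML config and a run manifest.

default_pipeline_config <- function() {
  list(
    qc = list(max_missing_rate = 0.02, hwe_alpha = 1e-7, rel_cutoff = 0.75,
              ld_window_snps = 50, ld_step_snps = 5, ld_r2_max = 0.2),
    structure = list(k = 10),
    scan = list(estimator = "weir_cockerham", smooth_window_snps = 9,
                smooth_kernel = "uniform_mean", outlier_quantile = 0.99,
                region_merge_gap_bp = 1e6, clamp_negative = TRUE),
    annotate = list(genes = NULL, genes_format = "tsv",
                    qtl = NULL, qtl_format = "bed", categories = NULL)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full selection-signature pipeline
#'
#' Reads a YAML configuration (or takes an equivalent named list), then for
#' each breed dataset runs the QC chain, computes the GRM structure
#' diagnostic (jointly over breeds), scans for outlier FST regions, and, if
#' annotation files are configured, overlaps the regions with gene/QTL sets
#' and runs the enrichment test. All stage outputs, a log of the
#' bookkeeping counts and a run manifest are written under `out_dir`.
#'
#' Config sections (all optional except one of `simulate`/`input`):
#' `simulate` (arguments of [sim_config()]), `input` (`prefix`, `dialect`,
#' optional `groups` TSV), `qc` ([qc_config()] arguments), `structure`
#' (`k`), `scan` ([fst_config()] arguments), `annotate` (`genes`,
#' `genes_format`, `qtl`, `qtl_format`, `categories` TSV with columns
#' `gene`, `category`).
#'
#' @param config path of a YAML file or a named list.
#' @param out_dir output directory, created if needed.
#' @param seed optional integer overriding the config seed.
#' @return Invisibly, a named list of per-breed results (`qc`, `structure`,
#'   `scan`, `overlaps`, `enrichment`) plus the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  user_cfg <- if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config else stop("config must be a path or a list")
  cfg <- merge_config(default_pipeline_config(), user_cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logcon <- file(log_path, "w")
  on.exit(close(logcon), add = TRUE)
  log_info <- function(...) {
    msg <- paste0(...)
    writeLines(msg, logcon)
    message(msg)
  }
  input_digests <- list()

  if (!is.null(seed)) {
    if (!is.null(cfg$simulate)) cfg$simulate$seed <- as.integer(seed)
    cfg$seed <- as.integer(seed)
  }

  # --- inputs -------------------------------------------------------------
  genes_ann <- NULL
  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(sim_config, cfg$simulate)
    log_info("simulate: ", sim_cfg$n_snps, " SNPs, ",
             sim_cfg$n_samples_per_group, " samples/group, ",
             sim_cfg$n_breeds, " breed(s), seed ", sim_cfg$seed)
    sim <- simulate_genotypes(sim_cfg)
    g <- sim$genotypes
    genes_ann <- sim$genes
    write_sim_truth(sim$truth, file.path(out_dir, "sim"))
  } else if (!is.null(cfg$input)) {
    if (is.null(cfg$input$prefix)) stop("config field input$prefix is required")
    dialect <- if (is.null(cfg$input$dialect)) "binary" else cfg$input$dialect
    g <- read_genotypes(cfg$input$prefix, dialect)
    ext <- if (dialect == "binary") c(".bed", ".bim", ".fam") else c(".ped", ".map")
    for (f in paste0(cfg$input$prefix, ext))
      input_digests[[basename(f)]] <- unname(tools::md5sum(f))
    if (!is.null(cfg$input$groups)) {
      input_digests[[basename(cfg$input$groups)]] <-
        unname(tools::md5sum(cfg$input$groups))
      g <- attach_groups(g, cfg$input$groups)
    }
    log_info("input: ", n_samples(g), " samples x ", n_variants(g),
             " variants from ", cfg$input$prefix)
  } else stop("config must contain a simulate or input section")
  g <- drop_nonautosomal(g)

  # --- annotation inputs --------------------------------------------------
  qtl_ann <- NULL; categories <- NULL
  if (!is.null(cfg$annotate$genes)) {
    genes_ann <- load_annotations(cfg$annotate$genes, cfg$annotate$genes_format)
    input_digests[[basename(cfg$annotate$genes)]] <-
      unname(tools::md5sum(cfg$annotate$genes))
  }
  if (!is.null(cfg$annotate$qtl)) {
    qtl_ann <- load_annotations(cfg$annotate$qtl, cfg$annotate$qtl_format)
    input_digests[[basename(cfg$annotate$qtl)]] <-
      unname(tools::md5sum(cfg$annotate$qtl))
  }
  if (!is.null(cfg$annotate$categories)) {
    categories <- utils::read.table(cfg$annotate$categories, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    input_digests[[basename(cfg$annotate$categories)]] <-
      unname(tools::md5sum(cfg$annotate$categories))
  }

  # --- joint structure diagnostic ----------------------------------------
  qc_cfg <- do.call(qc_config, cfg$qc)
  fst_cfg <- do.call(fst_config, cfg$scan)
  gmat <- grm(g)
  sres <- svd_structure(gmat, k = min(cfg$structure$k, n_samples(g)))
  write_structure_scores(sres, file.path(out_dir, "structure_scores.tsv"))
  crep <- cluster_report(sres, g$samples,
                         plot_file = file.path(out_dir, "structure.png"))
  log_info(sprintf("structure: breed separation %.3f, group separation %.3f",
                   crep$breed_separation, crep$group_separation))

  # --- per-breed QC + scan + annotation ----------------------------------
  breeds <- unique(g$samples$breed)
  if (all(is.na(breeds))) breeds <- NA_character_
  results <- list()
  counts <- list()
  for (b in breeds) {
    tag <- if (is.na(b)) "all" else b
    sel <- if (is.na(b)) rep(TRUE, n_samples(g)) else g$samples$breed %in% b
    gb <- keep_samples(g, sel)
    qc <- run_qc(gb, qc_cfg)
    log_info("qc[", tag, "]: variants ", qc$report$n_variants_in, " -> ",
             qc$report$n_variants_out, "; samples ", qc$report$n_samples_in,
             " -> ", qc$report$n_samples_out)
    write_qc_report(qc$report, file.path(out_dir, paste0(tag, "_qc_report.tsv")))
    scan <- fst_scan(qc$genotypes, fst_cfg)
    log_info("scan[", tag, "]: ", sum(scan$track$is_outlier, na.rm = TRUE),
             " SNPs flagged above threshold ", sprintf("%.5f", scan$threshold),
             "; ", nrow(scan$regions), " region(s)")
    write_fst_track(scan, file.path(out_dir, paste0(tag, "_fst_track.tsv")))
    write_regions(scan, file.path(out_dir, paste0(tag, "_regions")))
    res <- list(qc = qc$report, scan = scan)
    if (!is.null(genes_ann)) {
      ov <- overlap_regions(scan$regions, genes_ann)
      utils::write.table(ov, file.path(out_dir, paste0(tag, "_gene_hits.tsv")),
                         quote = FALSE, sep = "\t", row.names = FALSE)
      log_info("annotate[", tag, "]: ", length(unique(ov$name)),
               " distinct gene(s) hit")
      res$overlaps <- ov
      if (!is.null(categories) && nrow(ov)) {
        enr <- enrichment_test(unique(ov$name), categories, genes_ann$name)
        utils::write.table(enr, file.path(out_dir, paste0(tag, "_enrichment.tsv")),
                           quote = FALSE, sep = "\t", row.names = FALSE)
        res$enrichment <- enr
      }
    }
    if (!is.null(qtl_ann)) {
      ovq <- overlap_regions(scan$regions, qtl_ann)
      utils::write.table(ovq, file.path(out_dir, paste0(tag, "_qtl_hits.tsv")),
                         quote = FALSE, sep = "\t", row.names = FALSE)
      log_info("annotate[", tag, "]: ", nrow(ovq), " QTL hit(s)")
      res$qtl_overlaps <- ovq
    }
    counts[[tag]] <- list(variants_in = qc$report$n_variants_in,
                          variants_out = qc$report$n_variants_out,
                          samples_out = qc$report$n_samples_out,
                          snps_flagged = sum(scan$track$is_outlier, na.rm = TRUE),
                          regions = nrow(scan$regions))
    results[[tag]] <- res
  }

  manifest <- list(tool = "driftscan",
                   version = as.character(utils::packageVersion("driftscan")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = if (!is.null(cfg$simulate)) cfg$simulate$seed else cfg$seed,
                   config = cfg[setdiff(names(cfg), "seed")],
                   input_digests = input_digests,
                   stage_counts = counts)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  results$structure <- sres
  results$cluster_report <- crep
  invisible(results)
}
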