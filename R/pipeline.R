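#' Pipeline configuration
#'
#' Collects thresholds and settings for the full RIP-Chip analysis. Values
#' mirror the defaults of the stage functions; any can be overridden. The
#' configuration round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param sim A [ripchip_sim_config()] describing the synthetic experiment
#'   to generate (the no-download path), or `NULL` when `signal_path` inputs
#'   are given.
#' @param signal_path,design_path,annotation_path,utr_path Paths for a
#'   file-based run (signal TSV, design TSV, probe annotation TSV, UTR
#'   FASTA). Ignored when `sim` is given.
#' @param mirna_name,mirna_sequence The miRNA whose seed sites are scanned;
#'   defaults to hsa-miR-155-5p.
#' @param detection_quantile,max_dye_fold,min_detected_fraction Array QC
#'   thresholds (see [detect_calls()], [filter_probes()]).
#' @param min_ratio,min_ratio_fold Specific-target thresholds
#'   (see [call_specific_targets()]).
#' @param site_types Site types to scan.
#' @param n_perm,gsea_weight_p,n_random_sets GSEA settings; for synthetic
#'   runs the collection is one motif set (the planted targets) plus
#'   `n_random_sets` size-matched random sets.
#' @param top_k Top-k for the motif-set summary.
#' @param rng_seed Global seed fanned out to per-stage child seeds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = ripchip_sim_config(),
                            signal_path = NULL, design_path = NULL,
                            annotation_path = NULL, utr_path = NULL,
                            mirna_name = "hsa-miR-155-5p",
                            mirna_sequence = MIR155_5P,
                            detection_quantile = 0.10,
                            max_dye_fold = 2.0,
                            min_detected_fraction = 0.5,
                            min_ratio = 2.0, min_ratio_fold = 2.0,
                            site_types = c("6mer", "8mer"),
                            n_perm = 500, gsea_weight_p = 1,
                            n_random_sets = 30, top_k = 20,
                            rng_seed = 1) {
  cfg <- list(sim = sim, signal_path = signal_path, design_path = design_path,
              annotation_path = annotation_path, utr_path = utr_path,
              mirna_name = mirna_name, mirna_sequence = mirna_sequence,
              detection_quantile = detection_quantile,
              max_dye_fold = max_dye_fold,
              min_detected_fraction = min_detected_fraction,
              min_ratio = min_ratio, min_ratio_fold = min_ratio_fold,
              site_types = site_types, n_perm = n_perm,
              gsea_weight_p = gsea_weight_p, n_random_sets = n_random_sets,
              top_k = top_k, rng_seed = as.integer(rng_seed))
  if (!is_prob(cfg$detection_quantile) || cfg$detection_quantile <= 0 ||
      cfg$detection_quantile >= 1) {
    stop_config("detection_quantile", "must lie strictly in (0,1)")
  }
  if (!is_nonneg(cfg$max_dye_fold) || cfg$max_dye_fold < 1) {
    stop_config("max_dye_fold", "must be >= 1")
  }
  if (!is_prob(cfg$min_detected_fraction)) {
    stop_config("min_detected_fraction", "must be a probability")
  }
  if (!is_nonneg(cfg$min_ratio)) stop_config("min_ratio", "must be >= 0")
  if (!is_nonneg(cfg$min_ratio_fold)) stop_config("min_ratio_fold", "must be >= 0")
  if (is.null(cfg$sim) &&
      (is.null(cfg$signal_path) || is.null(cfg$design_path) ||
       is.null(cfg$annotation_path))) {
    stop("config needs either a simulation block or signal/design/annotation paths",
         call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    raw$sim <- do.call(ripchip_sim_config, raw$sim)
  } else {
    raw["sim"] <- list(NULL)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full RIP-Chip analysis pipeline
#'
#' Executes the stages in fixed order — simulate (or load), quantile
#' normalize, detection calls, probe filtering, dye averaging, IP/T ratios,
#' targetome and specific-target calling, gene collapse, seed-site scan of
#' the specific genes' UTRs, and motif-set enrichment — writing per-stage
#' outputs plus a machine-readable report (`report.json`) and an audit log
#' (`run.log`) listing every threshold applied. Any stage failure aborts
#' with the stage name.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly: a list with per-stage counts, the
#'   specific probe/gene calls, seed-site fractions, motif-set rank, and —
#'   for synthetic runs — recall/precision against planted truth.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ripchip_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("signals", "targetome", "seedscan", "gsea")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  log_lines <- character(0)
  log <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  report <- list(seed = config$rng_seed,
                 thresholds = list(
                   detection_quantile = config$detection_quantile,
                   max_dye_fold = config$max_dye_fold,
                   min_detected_fraction = config$min_detected_fraction,
                   min_ratio = config$min_ratio,
                   min_ratio_fold = config$min_ratio_fold))

  # --- stage 1: inputs ------------------------------------------------------
  simulated <- !is.null(config$sim)
  catalog <- derive_sites(mature_mirna(config$mirna_name, config$mirna_sequence))
  if (simulated) {
    simcfg <- config$sim
    simcfg$rng_seed <- child_seed(config$rng_seed, 0L)
    simcfg <- do.call(ripchip_sim_config, unclass(simcfg))
    sim_exp <- stage("simulate", {
      e <- generate_ripchip(simcfg)
      generate_utrs(e, catalog, simcfg)
    })
    mat <- sim_exp$matrix; design <- sim_exp$design
    annotation <- sim_exp$annotation
    utrs <- sim_exp$utr_sequences
    write_signal_table(mat, design, file.path(out_dir, "signals", "raw_signals.tsv"),
                       file.path(out_dir, "signals", "design.tsv"))
    write.table(annotation, file.path(out_dir, "signals", "annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sim_exp$truth_targets,
               file.path(out_dir, "signals", "truth_targets.txt"))
    log("simulate: n_genes=%d probes=%d planted_targets=%d seed=%d",
        simcfg$n_genes, nrow(mat$signals), length(sim_exp$truth_targets),
        simcfg$rng_seed)
  } else {
    inp <- stage("load", read_signal_table(config$signal_path, config$design_path))
    mat <- inp$matrix; design <- inp$design
    annotation <- stage("load", read.delim(config$annotation_path,
                                           stringsAsFactors = FALSE))
    utrs <- if (!is.null(config$utr_path)) {
      normalize_seq_input(config$utr_path)
    } else NULL
    sim_exp <- NULL
    log("load: %d probes, %d channels", nrow(mat$signals), ncol(mat$signals))
  }

  # --- stage 2: preprocessing ----------------------------------------------
  norm <- stage("normalize", quantile_normalize(mat))
  det <- stage("detect", detect_calls(norm, config$detection_quantile))
  log("detect: detection_quantile=%.3g", config$detection_quantile)
  filt <- stage("filter", filter_probes(det, design,
                                        max_dye_fold = config$max_dye_fold,
                                        min_detected_fraction = config$min_detected_fraction))
  log("filter: max_dye_fold=%.3g min_detected_fraction=%.3g retained=%d/%d",
      config$max_dye_fold, config$min_detected_fraction,
      filt$report$n_probes_retained, filt$report$n_probes_input)
  avg <- stage("average", average_dye_replicates(filt$matrix, design))
  report$filter <- list(n_probes_input = filt$report$n_probes_input,
                        n_removed_detection = filt$report$n_removed_detection,
                        n_removed_consistency = filt$report$n_removed_consistency,
                        n_probes_retained = filt$report$n_probes_retained)

  # --- stage 3: targetome ---------------------------------------------------
  ratios <- stage("targetome", compute_ratios(avg, member_threshold = config$min_ratio))
  constructs <- unique(ratios$construct)
  design_type <- if (simulated) config$sim$design_type
                 else if ("sponge" %in% constructs) "sponge" else "overexpression"
  if (design_type == "overexpression") {
    test_con <- "overexpression"; ref_con <- "control"
  } else {
    test_con <- "control"; ref_con <- "sponge"
  }
  specific <- stage("specific", call_specific_targets(
    ratios, test_con, ref_con, min_ratio = config$min_ratio,
    min_ratio_fold = config$min_ratio_fold))
  log("specific: test=%s ref=%s min_ratio=%.3g min_ratio_fold=%.3g n=%d",
      test_con, ref_con, config$min_ratio, config$min_ratio_fold,
      length(specific))
  collapse <- stage("collapse", collapse_to_genes(
    ratios, annotation, construct = test_con, specific_probes = specific))
  utils::write.csv(ratios, file.path(out_dir, "targetome", "ratios.csv"),
                   row.names = FALSE)
  writeLines(specific, file.path(out_dir, "targetome", "specific_probes.txt"))
  writeLines(collapse$specific_genes,
             file.path(out_dir, "targetome", "specific_genes.txt"))
  ip_frac <- vapply(split(ratios$targetome_member, ratios$construct), mean,
                    numeric(1))
  report$targetome <- list(
    ip_enriched_probe_fraction = as.list(ip_frac),
    n_specific_probes = length(specific),
    n_specific_genes = length(collapse$specific_genes),
    n_unannotated_specific = length(collapse$unannotated_specific))
  if (simulated) {
    truth <- sim_exp$truth_targets
    called <- collapse$specific_genes
    report$truth <- list(
      n_truth_targets = length(truth),
      recall = if (length(truth)) length(intersect(called, truth)) / length(truth) else NA,
      precision = if (length(called)) length(intersect(called, truth)) / length(called) else NA)
  }

  # --- stage 4: seed scan ---------------------------------------------------
  if (!is.null(utrs) && length(collapse$specific_genes)) {
    hits <- stage("seedscan", scan_sequences(
      utrs[intersect(names(utrs), collapse$genes$gene)], catalog,
      site_types = config$site_types))
    sitesum <- stage("seedscan",
                     summarize_site_content(hits, collapse$specific_genes))
    write.table(sitesum, file.path(out_dir, "seedscan", "site_content.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$seed_sites <- lapply(split(sitesum, sitesum$site_type), function(r) {
      list(k = r$k, n = r$n, fraction = r$fraction)
    })
    log("seedscan: site_types=%s over %d specific genes",
        paste(config$site_types, collapse = ","), length(collapse$specific_genes))
  }

  # --- stage 5: motif-set enrichment ---------------------------------------
  ranked <- stage("gsea", rank_genes(collapse))
  collection <- NULL
  if (simulated && length(sim_exp$truth_targets) >= 2) {
    collection <- stage("gsea", synthetic_gene_sets(
      ranked$gene, sim_exp$truth_targets, n_random_sets = config$n_random_sets,
      mirna_name = config$mirna_name,
      rng_seed = child_seed(config$rng_seed, 2L)))
  }
  if (!is.null(collection)) {
    gsea <- stage("gsea", gsea_permutation_test(
      ranked, collection, n_perm = config$n_perm,
      rng_seed = child_seed(config$rng_seed, 3L),
      weight_p = config$gsea_weight_p))
    write.table(as.data.frame(gsea), file.path(out_dir, "gsea", "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    motif_name <- paste0(config$mirna_name, "_motif_set")
    msum <- motif_set_summary(gsea, top_k = min(config$top_k, nrow(gsea)),
                              named_set = motif_name)
    report$gsea <- list(n_sets = nrow(gsea),
                        n_perm = config$n_perm,
                        fraction_motif_in_top_k = msum$fraction_motif_in_top_k,
                        motif_set_rank = msum$rank_of_named_set)
    log("gsea: n_perm=%d weight_p=%.3g motif_set_rank=%d", config$n_perm,
        config$gsea_weight_p, msum$rank_of_named_set)
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Build a synthetic gene-set collection around planted targets
#'
#' One miRNA binding-site motif set holding the planted target genes plus
#' size-matched random sets drawn from the ranked universe, mimicking a
#' motif-set database for enrichment testing without any download.
#'
#' @param universe Character vector of ranked gene ids.
#' @param truth_targets Planted target genes (the motif set).
#' @param n_random_sets Number of random non-motif sets.
#' @param mirna_name Used to name the motif set (`<name>_motif_set`).
#' @param rng_seed Seed for the random sets.
#' @return A [gene_set_collection()].
#' @export
synthetic_gene_sets <- function(universe, truth_targets, n_random_sets = 30,
                                mirna_name = "hsa-miR-155-5p", rng_seed = 1) {
  truth_in <- intersect(truth_targets, universe)
  if (length(truth_in) < 2) stop("need >= 2 planted targets in the universe",
                                 call. = FALSE)
  set.seed(rng_seed)
  sets <- c(list(truth_in),
            lapply(seq_len(n_random_sets), function(i) {
              sample(universe, length(truth_in))
            }))
  names(sets) <- c(paste0(mirna_name, "_motif_set"),
                   sprintf("RANDOM_SET_%03d", seq_len(n_random_sets)))
  gene_set_collection(sets, is_motif = c(TRUE, rep(FALSE, n_random_sets)))
}

#' Write a complete miniature input bundle for a named scenario
#'
#' Presets:
#' * `"paper-like"`: ~8000 genes, 54 planted targets with IP enrichment
#'   folds drawn uniformly from 2.0-12.6, log2 noise sd 0.25 — the scale of
#'   a real overexpression RIP-Chip screen.
#' * `"zero-noise"`: all noise, dye and dropout parameters 0 with a fixed
#'   4-fold enrichment; downstream calls recover the planted truth exactly.
#' * `"null"`: no planted targets.
#' * `"sponge-weak"`: sponge design whose enrichment folds are shrunk only
#'   20% toward 1 in the sponge construct, emulating incomplete miRNA
#'   sequestration.
#'
#' @param preset Preset name.
#' @param out_dir Output directory.
#' @param rng_seed Seed for the generated bundle.
#' @return Invisibly, a list with the generated experiment and file paths.
#' @export
make_fixture <- function(preset = c("paper-like", "null", "zero-noise",
                                    "sponge-weak"),
                         out_dir, rng_seed = 1) {
  presets <- c("paper-like", "null", "zero-noise", "sponge-weak")
  if (!is.character(preset) || !preset[1] %in% presets) {
    stop("unknown preset '", preset[1], "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  preset <- preset[1]
  cfg <- switch(preset,
    "paper-like" = ripchip_sim_config(n_genes = 8000, probes_per_gene = 2,
                                      n_planted_targets = 54,
                                      ip_enrichment_fold_targets = c(2.0, 12.6),
                                      noise_sd_log2 = 0.25, rng_seed = rng_seed),
    "null" = ripchip_sim_config(n_genes = 2000, n_planted_targets = 0,
                                rng_seed = rng_seed),
    "zero-noise" = ripchip_sim_config(n_genes = 2000, n_planted_targets = 54,
                                      ip_enrichment_fold_targets = 4,
                                      noise_sd_log2 = 0, dye_effect_sd_log2 = 0,
                                      detection_dropout_rate = 0,
                                      rng_seed = rng_seed),
    "sponge-weak" = ripchip_sim_config(n_genes = 2000, n_planted_targets = 54,
                                       ip_enrichment_fold_targets = 4,
                                       design_type = "sponge",
                                       sponge_shrink = 0.2,
                                       rng_seed = rng_seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- derive_sites(mature_mirna("hsa-miR-155-5p", MIR155_5P))
  exp <- generate_utrs(generate_ripchip(cfg), catalog, cfg)
  paths <- list(
    signals = file.path(out_dir, "signals.tsv"),
    design = file.path(out_dir, "design.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    utrs = file.path(out_dir, "utrs.fasta"),
    truth_targets = file.path(out_dir, "truth_targets.txt"),
    truth_site_genes = file.path(out_dir, "truth_site_genes.txt"))
  write_signal_table(exp$matrix, exp$design, paths$signals, paths$design)
  write.table(exp$annotation, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(paste0(">", names(exp$utr_sequences), "\n", exp$utr_sequences),
             paths$utrs)
  writeLines(exp$truth_targets, paths$truth_targets)
  writeLines(exp$truth_site_genes, paths$truth_site_genes)
  invisible(list(experiment = exp, config = cfg, paths = paths))
}
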