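#' Configuration for a synthetic RIP-Chip experiment
#'
#' Defines the generative model for a two-construct Ago2 RIP-Chip experiment
#' with planted miRNA targets. Signals are simulated on the linear
#' fluorescence scale as `2^(log2 baseline + effects + noise)`, with probe
#' baselines drawn from Normal(10, 1.5) on the log2 scale to mimic array
#' dynamic range. Planted targets receive an IP enrichment multiplier only
#' in the miRNA-manipulated construct (overexpression designs) or in the
#' control construct (sponge designs, where the sponge only partially
#' releases the enrichment).
#'
#' @param n_genes Number of genes on the array.
#' @param probes_per_gene Probes per gene (>= 1).
#' @param n_planted_targets Number of genes planted as true miRNA targets.
#' @param ip_enrichment_fold_targets IP/T fold applied to planted targets
#'   (linear scale). Either a single fold or a length-2 range `c(lo, hi)`
#'   from which per-target folds are drawn uniformly.
#' @param ip_enrichment_fold_background Baseline IP/T of non-targets.
#' @param noise_sd_log2 Per-cell lognormal signal noise (sd on log2 scale).
#' @param dye_effect_sd_log2 Per-channel dye offset sd (log2 scale).
#' @param detection_dropout_rate Probability a cell's detection flag is unset.
#' @param utr_length Length (nt) of simulated 3'UTR sequences.
#' @param site_plant_rate_targets Probability a planted target's UTR gets a
#'   seed site inserted.
#' @param site_plant_rate_background Same for non-target genes.
#' @param n_unannotated_probes Extra probes mapping to no known gene.
#' @param design_type `"overexpression"` (control vs overexpression) or
#'   `"sponge"` (control vs sponge).
#' @param sponge_shrink For sponge designs, the fraction by which the target
#'   enrichment fold is shrunk toward 1 in the sponge construct (1 = fully
#'   effective sponge; 0.2 = weak sponge).
#' @param cell_line Cell line label used in the design.
#' @param rng_seed Integer seed; the whole experiment is reproducible from it.
#' @return A validated list of class `ripchip_sim_config`.
#' @export
ripchip_sim_config <- function(n_genes = 8000,
                               probes_per_gene = 2,
                               n_planted_targets = 54,
                               ip_enrichment_fold_targets = 4,
                               ip_enrichment_fold_background = 1,
                               noise_sd_log2 = 0.25,
                               dye_effect_sd_log2 = 0.1,
                               detection_dropout_rate = 0.02,
                               utr_length = 800,
                               site_plant_rate_targets = 0.48,
                               site_plant_rate_background = 0.02,
                               n_unannotated_probes = 0,
                               design_type = c("overexpression", "sponge"),
                               sponge_shrink = 1,
                               cell_line = "SIM1",
                               rng_seed = 1) {
  design_type <- match.arg(design_type)
  cfg <- list(n_genes = n_genes, probes_per_gene = probes_per_gene,
              n_planted_targets = n_planted_targets,
              ip_enrichment_fold_targets = ip_enrichment_fold_targets,
              ip_enrichment_fold_background = ip_enrichment_fold_background,
              noise_sd_log2 = noise_sd_log2,
              dye_effect_sd_log2 = dye_effect_sd_log2,
              detection_dropout_rate = detection_dropout_rate,
              utr_length = utr_length,
              site_plant_rate_targets = site_plant_rate_targets,
              site_plant_rate_background = site_plant_rate_background,
              n_unannotated_probes = n_unannotated_probes,
              design_type = design_type, sponge_shrink = sponge_shrink,
              cell_line = cell_line, rng_seed = as.integer(rng_seed))
  if (!is_count(cfg$n_genes, 1)) stop_config("n_genes", "must be a positive count")
  if (!is_count(cfg$probes_per_gene, 1)) stop_config("probes_per_gene", "must be >= 1")
  if (!is_count(cfg$n_planted_targets)) stop_config("n_planted_targets", "must be a count")
  if (cfg$n_planted_targets > cfg$n_genes) {
    stop_config("n_planted_targets", "cannot exceed n_genes")
  }
  ft <- cfg$ip_enrichment_fold_targets
  if (!is.numeric(ft) || !length(ft) %in% c(1L, 2L) || any(ft < 0)) {
    stop_config("ip_enrichment_fold_targets", "must be a fold or c(lo, hi) range, >= 0")
  }
  if (length(ft) == 2L && ft[2] < ft[1]) {
    stop_config("ip_enrichment_fold_targets", "range must be increasing")
  }
  if (!is_nonneg(cfg$ip_enrichment_fold_background)) {
    stop_config("ip_enrichment_fold_background", "must be >= 0")
  }
  if (!is_nonneg(cfg$noise_sd_log2)) stop_config("noise_sd_log2", "must be >= 0")
  if (!is_nonneg(cfg$dye_effect_sd_log2)) stop_config("dye_effect_sd_log2", "must be >= 0")
  if (!is_prob(cfg$detection_dropout_rate)) {
    stop_config("detection_dropout_rate", "must be a probability in [0,1]")
  }
  if (!is_count(cfg$utr_length, 1)) stop_config("utr_length", "must be a positive count")
  if (!is_prob(cfg$site_plant_rate_targets)) {
    stop_config("site_plant_rate_targets", "must be a probability in [0,1]")
  }
  if (!is_prob(cfg$site_plant_rate_background)) {
    stop_config("site_plant_rate_background", "must be a probability in [0,1]")
  }
  if (!is_count(cfg$n_unannotated_probes)) {
    stop_config("n_unannotated_probes", "must be a count")
  }
  if (!is_prob(cfg$sponge_shrink)) stop_config("sponge_shrink", "must be in [0,1]")
  class(cfg) <- "ripchip_sim_config"
  cfg
}

sim_constructs <- function(config) {
  if (config$design_type == "overexpression") c("control", "overexpression")
  else c("control", "sponge")
}

#' Generate a synthetic RIP-Chip experiment
#'
#' Simulates a paired total (T) / Ago2-IP experiment for two constructs with
#' Cy3/Cy5 dye replicate channels, planted target genes, lognormal noise,
#' per-channel dye effects and detection dropout. Ground truth (planted
#' target genes and their folds) is recorded in the returned object.
#'
#' @param config A [ripchip_sim_config()].
#' @return A list of class `synthetic_experiment` with elements `matrix`
#'   (raw [signal_matrix()]), `design`, `annotation` (data.frame
#'   `probe_id`, `gene`; `NA` gene for unannotated probes), `truth_targets`
#'   (character gene ids), `truth_folds` (named numeric), `utr_sequences`
#'   and `truth_site_genes` (filled by [generate_utrs()]), and `config`.
#' @export
generate_ripchip <- function(config) {
  stopifnot(inherits(config, "ripchip_sim_config"))
  set.seed(config$rng_seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  annotation <- data.frame(
    probe_id = sprintf("%s_p%d", rep(genes, each = config$probes_per_gene),
                       rep(seq_len(config$probes_per_gene), config$n_genes)),
    gene = rep(genes, each = config$probes_per_gene),
    stringsAsFactors = FALSE)
  if (config$n_unannotated_probes > 0) {
    annotation <- rbind(annotation, data.frame(
      probe_id = sprintf("UNANN_p%d", seq_len(config$n_unannotated_probes)),
      gene = NA_character_, stringsAsFactors = FALSE))
  }
  n_probes <- nrow(annotation)

  targets <- sort(sample(genes, config$n_planted_targets))
  ft <- config$ip_enrichment_fold_targets
  folds <- if (length(ft) == 2L) runif(length(targets), ft[1], ft[2])
           else rep(ft, length(targets))
  names(folds) <- targets

  constructs <- sim_constructs(config)
  design <- expand.grid(dye = c("Cy3", "Cy5"), fraction = c("T", "IP"),
                        construct = constructs, stringsAsFactors = FALSE)
  design <- data.frame(
    sample_channel_id = paste(config$cell_line, design$construct,
                              design$fraction, design$dye, sep = "."),
    cell_line = config$cell_line, construct = design$construct,
    fraction = design$fraction, dye = design$dye, replicate = "r1",
    stringsAsFactors = FALSE)
  design <- experiment_design(design)

  # per-probe IP enrichment (log2) by construct: targets get their fold in
  # the miRNA-high construct (overexpression; control for sponge designs),
  # partially released in the sponge construct
  probe_fold <- function(construct) {
    lf <- rep(log2(max(config$ip_enrichment_fold_background, .Machine$double.eps)),
              n_probes)
    idx <- !is.na(annotation$gene) & annotation$gene %in% targets
    f <- folds[annotation$gene[idx]]
    enriched_in <- if (config$design_type == "overexpression") "overexpression"
                   else "control"
    if (construct == enriched_in) {
      lf[idx] <- log2(f)
    } else if (construct == "sponge") {
      lf[idx] <- log2(1 + (1 - config$sponge_shrink) * (f - 1))
    }
    lf
  }

  baseline <- rnorm(n_probes, mean = 10, sd = 1.5)
  dye_effects <- rnorm(nrow(design), 0, config$dye_effect_sd_log2)
  sig <- matrix(0, n_probes, nrow(design),
                dimnames = list(annotation$probe_id, design$sample_channel_id))
  for (j in seq_len(nrow(design))) {
    lf <- if (design$fraction[j] == "IP") probe_fold(design$construct[j]) else 0
    noise <- if (config$noise_sd_log2 > 0) {
      rnorm(n_probes, 0, config$noise_sd_log2)
    } else 0
    sig[, j] <- 2^(baseline + lf + dye_effects[j] + noise)
  }
  detected <- matrix(TRUE, n_probes, nrow(design), dimnames = dimnames(sig))
  if (config$detection_dropout_rate > 0) {
    detected[] <- runif(length(detected)) >= config$detection_dropout_rate
  }
  structure(list(matrix = signal_matrix(sig, detected = detected, state = "raw"),
                 design = design, annotation = annotation,
                 truth_targets = targets, truth_folds = folds,
                 utr_sequences = NULL, truth_site_genes = NULL,
                 config = config),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic RIP-Chip experiment: %d probes, %d genes, %d planted targets (%s design)\n",
              nrow(x$matrix$signals), x$config$n_genes,
              length(x$truth_targets), x$config$design_type))
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic 3'UTR sequences with planted seed sites
#'
#' Every gene receives a random DNA 3'UTR of `utr_length` nt. Background
#' sequence is rejection-sampled so that the catalog's 8mer site never occurs
#' by chance; genes selected for planting (at `site_plant_rate_targets` for
#' truth targets, `site_plant_rate_background` otherwise) then get exactly one
#' 8mer site inserted at a random position. The planted gene set is recorded
#' as ground truth on the experiment.
#'
#' @param experiment A `synthetic_experiment` from [generate_ripchip()].
#' @param site_catalog A [derive_sites()] catalog; its `8mer` entry is planted.
#' @param config Optional [ripchip_sim_config()]; defaults to the
#'   experiment's own config.
#' @return The experiment with `utr_sequences` (named character vector) and
#'   `truth_site_genes` filled in.
#' @export
generate_utrs <- function(experiment, site_catalog, config = experiment$config) {
  stopifnot(inherits(experiment, "synthetic_experiment"),
            inherits(site_catalog, "seed_site_catalog"))
  site <- unname(site_catalog["8mer"])
  if (is.na(site) || !nzchar(site)) stop("site catalog has no 8mer entry", call. = FALSE)
  if (config$utr_length < nchar(site)) {
    stop_config("utr_length", sprintf("must be >= site length (%d nt)", nchar(site)))
  }
  set.seed(child_seed(config$rng_seed, 1L))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  is_target <- genes %in% experiment$truth_targets
  rate <- ifelse(is_target, config$site_plant_rate_targets,
                 config$site_plant_rate_background)
  plant <- runif(length(genes)) < rate
  utrs <- character(length(genes))
  for (i in seq_along(genes)) {
    repeat {
      s <- random_dna(config$utr_length)
      if (!grepl(site, s, fixed = TRUE)) break  # keep truth exact
    }
    if (plant[i]) {
      repeat {
        pos <- sample.int(config$utr_length - nchar(site) + 1L, 1L)
        planted <- paste0(substr(s, 1, pos - 1), site,
                          substr(s, pos + nchar(site), config$utr_length))
        # insertion must not create a second, unintended occurrence
        if (length(gregexpr(site, planted, fixed = TRUE)[[1]]) == 1L) break
      }
      s <- planted
    }
    utrs[i] <- s
  }
  names(utrs) <- genes
  experiment$utr_sequences <- utrs
  experiment$truth_site_genes <- genes[plant]
  experiment
}

#' Configuration for a synthetic GFP competition assay
#'
#' Emulates a growth competition between GFP+ transduced and untransduced
#' cells measured by flow cytometry roughly every 2-3 days for three weeks.
#' Control replicates have flat expected relative GFP+ percentage 1; test
#' replicates follow `1 + growth_advantage_per_day * (day - first day)`.
#'
#' @param n_replicates Biological replicates per construct.
#' @param days Strictly increasing measurement days.
#' @param baseline_gfp_pct Expected GFP+ percentage at the first day, in (0,100).
#' @param growth_advantage_per_day Difference in daily relative-growth slope
#'   between test and control construct (units: relative value per day).
#' @param replicate_sd Replicate-level Gaussian sd on the relative scale.
#' @param residual_sd Per-measurement Gaussian sd on the relative scale.
#' @param rng_seed Integer seed.
#' @return A validated list of class `growth_sim_config`.
#' @export
growth_sim_config <- function(n_replicates = 3,
                              days = c(4, 7, 10, 13, 16, 19, 22),
                              baseline_gfp_pct = 30,
                              growth_advantage_per_day = 1 / 18,
                              replicate_sd = 0.05,
                              residual_sd = 0.05,
                              rng_seed = 1) {
  cfg <- list(n_replicates = n_replicates, days = as.integer(days),
              baseline_gfp_pct = baseline_gfp_pct,
              growth_advantage_per_day = growth_advantage_per_day,
              replicate_sd = replicate_sd, residual_sd = residual_sd,
              rng_seed = as.integer(rng_seed))
  if (!is_count(cfg$n_replicates, 1)) stop_config("n_replicates", "must be >= 1")
  if (length(cfg$days) < 2 || any(diff(cfg$days) <= 0)) {
    stop_config("days", "must be >= 2 strictly increasing days")
  }
  if (!is.numeric(cfg$baseline_gfp_pct) || cfg$baseline_gfp_pct <= 0 ||
      cfg$baseline_gfp_pct >= 100) {
    stop_config("baseline_gfp_pct", "must lie in (0, 100)")
  }
  if (!is_nonneg(cfg$replicate_sd)) stop_config("replicate_sd", "must be >= 0")
  if (!is_nonneg(cfg$residual_sd)) stop_config("residual_sd", "must be >= 0")
  class(cfg) <- "growth_sim_config"
  cfg
}

#' Generate a synthetic GFP competition time course
#'
#' @param config A [growth_sim_config()].
#' @return A data.frame with columns `construct` ("control"/"test"),
#'   `replicate`, `day`, `gfp_pct`, suitable for [normalize_series()].
#' @export
generate_growth <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  set.seed(config$rng_seed)
  rows <- list()
  for (construct in c("control", "test")) {
    adv <- if (construct == "test") config$growth_advantage_per_day else 0
    for (r in seq_len(config$n_replicates)) {
      b <- if (config$replicate_sd > 0) rnorm(1, 0, config$replicate_sd) else 0
      expected <- 1 + adv * (config$days - config$days[1])
      eps <- if (config$residual_sd > 0) {
        rnorm(length(config$days), 0, config$residual_sd)
      } else 0
      gfp <- config$baseline_gfp_pct * (expected + b + eps)
      gfp <- pmin(pmax(gfp, 1e-6), 100 - 1e-6)
      rows[[length(rows) + 1L]] <- data.frame(
        construct = construct, replicate = sprintf("%s_r%d", construct, r),
        day = config$days, gfp_pct = gfp, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
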