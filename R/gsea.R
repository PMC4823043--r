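#' Rank genes by IP fold enrichment
#'
#' Produces the preranked list used for gene-set enrichment: genes ordered
#' by decreasing log2 gene ratio (the max-probe IP/T fold from
#' [collapse_to_genes()]), with ties broken deterministically by gene id.
#'
#' @param collapse A [collapse_to_genes()] result (or a data.frame with
#'   columns `gene` and `gene_ratio`).
#' @return A data.frame of class `ranked_gene_list` with columns `gene`,
#'   `metric` (log2 gene ratio), ordered descending.
#' @export
rank_genes <- function(collapse) {
  genes <- if (inherits(collapse, "gene_collapse")) collapse$genes else collapse
  stopifnot(is.data.frame(genes), all(c("gene", "gene_ratio") %in% names(genes)))
  if (!nrow(genes)) stop("no genes to rank", call. = FALSE)
  metric <- log2(genes$gene_ratio)
  ord <- order(-metric, genes$gene)
  out <- data.frame(gene = genes$gene[ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Gene-set collection
#'
#' @param sets Named list of character gene-id vectors.
#' @param is_motif Logical vector flagging miRNA binding-site motif sets, or
#'   a regular expression matched against set names, or `NULL` (no motif
#'   flags).
#' @return A list of class `gene_set_collection` with `sets` and `is_motif`.
#' @export
gene_set_collection <- function(sets, is_motif = NULL) {
  stopifnot(is.list(sets), length(sets) > 0)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("gene sets must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names", call. = FALSE)
  flags <- if (is.null(is_motif)) {
    rep(FALSE, length(sets))
  } else if (is.character(is_motif) && length(is_motif) == 1L) {
    grepl(is_motif, names(sets))
  } else {
    stopifnot(is.logical(is_motif), length(is_motif) == length(sets))
    is_motif
  }
  structure(list(sets = lapply(sets, as.character),
                 is_motif = setNames(flags, names(sets))),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (tab-separated: name, description, member genes).
#' @param motif_pattern Optional regex on set names flagging miRNA
#'   binding-site motif sets (e.g. seed-heptamer style names).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, motif_pattern = NULL) {
  gene_set_collection(fgsea::gmtPathways(path), is_motif = motif_pattern)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (collection$is_motif[[nm]]) "motif" else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ES from sorted 1-based hit positions; O(n_hits) per evaluation.
# weights: |metric|^p of the full ranked list (precomputed by the caller).
es_from_positions <- function(hit_pos, weights, n) {
  s <- length(hit_pos)
  if (s == 0L || s == n) stop("gene set empty or spans the whole universe",
                              call. = FALSE)
  w <- weights[hit_pos]
  tot <- sum(w)
  inc <- if (tot > 0) cumsum(w) / tot else cumsum(rep(1 / s, s))
  miss_before <- (hit_pos - seq_len(s)) / (n - s)     # misses before each hit
  after_hit <- inc - miss_before                      # running sum just after hit i
  before_hit <- c(0, inc[-s]) - miss_before           # just before hit i
  cand <- c(after_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' GSEA enrichment score of one gene set
#'
#' The weighted Kolmogorov-Smirnov running-sum statistic: walking down the
#' ranked list, the sum increases by `|metric|^p / sum(hit |metric|^p)` at
#' each set member and decreases by `1/(N - N_hits)` at each non-member; the
#' enrichment score (ES) is the signed maximum deviation from zero.
#'
#' @param ranked A [rank_genes()] list.
#' @param gene_set Character vector of gene ids.
#' @param weight_p Weighting exponent p (1 = standard weighted statistic,
#'   0 = classic Kolmogorov-Smirnov).
#' @return A list with `es` and `running_sum` (length N, value after each
#'   rank position).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  n <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  s <- sum(hit)
  if (s == 0L) stop("gene set does not intersect the ranked universe", call. = FALSE)
  if (s == n) stop("gene set spans the whole ranked universe", call. = FALSE)
  w <- abs(ranked$metric)^weight_p
  wh <- w * hit
  tot <- sum(wh)
  steps <- if (tot > 0) wh / tot else hit / s
  steps[!hit] <- -1 / (n - s)
  running <- cumsum(steps)
  es <- running[which.max(abs(running))]
  list(es = es, running_sum = running)
}

#' Permutation-based gene-set enrichment over a collection
#'
#' Preranked GSEA with a gene-label permutation null: for each set-size
#' stratum, null enrichment scores are computed on random gene subsets of
#' the ranked universe. NES is the observed ES divided by the mean |null ES|
#' of matching sign; permutation p-values are sign-stratified with add-one
#' smoothing, `p = (1 + #(same-sign null >= observed)) / (1 + #same-sign
#' nulls)` for positive ES (mirrored for negative), the convention that
#' makes null-set p-values uniform. With `exact = TRUE` (small universes)
#' the null enumerates every subset of the stratum size and p is the exact
#' same-sign tail fraction without smoothing.
#'
#' @param ranked A [rank_genes()] list.
#' @param collection A [gene_set_collection()].
#' @param n_perm Number of permutations (>= 100 unless `exact`).
#' @param rng_seed Integer seed; results are fully reproducible.
#' @param weight_p Weighting exponent passed to the score.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked universe.
#' @param exact Enumerate all subsets instead of sampling (only feasible for
#'   tiny universes).
#' @return A data.frame of class `enrichment_result` with columns `set`,
#'   `size`, `es`, `nes`, `p_value`, `padj` (Benjamini-Hochberg, provided as
#'   a convenience), `rank_by_nes`, `is_motif`, ordered by NES rank.
#' @export
gsea_permutation_test <- function(ranked, collection, n_perm = 1000,
                                  rng_seed = 1, weight_p = 1, min_size = 2,
                                  max_size = Inf, exact = FALSE) {
  stopifnot(inherits(ranked, "ranked_gene_list"),
            inherits(collection, "gene_set_collection"))
  if (!exact && n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  n <- nrow(ranked)
  weights <- abs(ranked$metric)^weight_p
  idx_of <- setNames(seq_len(n), ranked$gene)
  sizes <- vapply(collection$sets, function(s) {
    length(intersect(unique(s), ranked$gene))
  }, integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) stop("no gene set passes the size bounds", call. = FALSE)
  sets <- collection$sets[keep]
  sizes <- sizes[keep]
  set.seed(rng_seed)
  null_by_size <- list()
  for (s in sort(unique(sizes))) {
    null_by_size[[as.character(s)]] <- if (exact) {
      combs <- utils::combn(n, s)
      apply(combs, 2, function(p) es_from_positions(sort(p), weights, n))
    } else {
      vapply(seq_len(n_perm), function(i) {
        es_from_positions(sort(sample.int(n, s)), weights, n)
      }, numeric(1))
    }
  }
  res <- lapply(names(sets), function(nm) {
    pos <- sort(unname(idx_of[intersect(unique(sets[[nm]]), ranked$gene)]))
    es <- es_from_positions(pos, weights, n)
    null <- null_by_size[[as.character(length(pos))]]
    same_sign <- if (es >= 0) null[null >= 0] else null[null < 0]
    denom <- mean(abs(same_sign))
    nes <- if (length(same_sign) && denom > 0) es / denom else NA_real_
    tail_n <- if (es >= 0) sum(same_sign >= es) else sum(same_sign <= es)
    p <- if (exact) {
      if (length(same_sign)) tail_n / length(same_sign) else 1
    } else {
      (1 + tail_n) / (1 + length(same_sign))
    }
    data.frame(set = nm, size = length(pos), es = es, nes = nes, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- p.adjust(res$p_value, method = "BH")
  ord <- order(-res$nes, res$set)
  res <- res[ord, , drop = FALSE]
  res$rank_by_nes <- seq_len(nrow(res))
  res$is_motif <- unname(collection$is_motif[res$set])
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Motif-set summary of an enrichment result
#'
#' Reports the fraction of the `top_k` sets (by NES rank) that are miRNA
#' binding-site motif sets, and optionally the rank of a named set.
#'
#' @param results An [gsea_permutation_test()] result.
#' @param top_k Number of top sets to summarize.
#' @param named_set Optional set name whose NES rank is returned.
#' @return A list with `fraction_motif_in_top_k` and (if requested)
#'   `rank_of_named_set`.
#' @export
motif_set_summary <- function(results, top_k = 20, named_set = NULL) {
  stopifnot(inherits(results, "enrichment_result"))
  if (top_k > nrow(results)) {
    stop(sprintf("top_k (%d) exceeds the number of sets (%d)", top_k,
                 nrow(results)), call. = FALSE)
  }
  top <- results[results$rank_by_nes <= top_k, ]
  out <- list(fraction_motif_in_top_k = mean(top$is_motif))
  if (!is.null(named_set)) {
    hit <- results$rank_by_nes[results$set == named_set]
    if (!length(hit)) stop("named set not in results: ", named_set, call. = FALSE)
    out$rank_of_named_set <- hit
  }
  out
}
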