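#' Compute IP/T fold enrichments and call the targetome
#'
#' For every retained probe and every (cell line, construct) sample pair,
#' the IP fold enrichment is the averaged IP signal divided by the averaged
#' total (T) signal, with a linear-scale floor on the denominator to prevent
#' infinite ratios from dropout-level totals. The targetome of a sample is
#' every probe with IP/T ratio at or above `member_threshold` (default 2,
#' inclusive).
#'
#' @param averaged A [average_dye_replicates()] output (carries a `groups`
#'   attribute pairing IP and T columns).
#' @param member_threshold Targetome membership threshold on the IP/T ratio.
#' @param t_floor Linear-scale floor applied to the T denominator.
#' @return A data.frame of class `targetome_table` with columns `probe_id`,
#'   `cell_line`, `construct`, `ip_signal`, `t_signal`, `ip_t_ratio`,
#'   `targetome_member`.
#' @export
compute_ratios <- function(averaged, member_threshold = 2, t_floor = 1.0) {
  stopifnot(inherits(averaged, "signal_matrix"))
  groups <- attr(averaged, "groups")
  if (is.null(groups)) {
    stop("averaged matrix lacks its sample-group attribute; use average_dye_replicates()",
         call. = FALSE)
  }
  pairs <- unique(groups[c("cell_line", "construct")])
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    cl <- pairs$cell_line[i]; con <- pairs$construct[i]
    ip_id <- groups$sample_id[groups$cell_line == cl & groups$construct == con &
                              groups$fraction == "IP"]
    t_id <- groups$sample_id[groups$cell_line == cl & groups$construct == con &
                             groups$fraction == "T"]
    if (length(ip_id) != 1L || length(t_id) != 1L) {
      stop(sprintf("group (%s, %s) lacks a paired IP and T sample", cl, con),
           call. = FALSE)
    }
    ip <- averaged$signals[, ip_id]
    tt <- averaged$signals[, t_id]
    ratio <- ip / pmax(tt, t_floor)
    out[[i]] <- data.frame(probe_id = rownames(averaged$signals),
                           cell_line = cl, construct = con,
                           ip_signal = ip, t_signal = tt, ip_t_ratio = ratio,
                           targetome_member = ratio >= member_threshold,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("targetome_table", "data.frame")
  attr(res, "member_threshold") <- member_threshold
  res
}

#' Call miRNA-specific targets between two constructs
#'
#' A probe is a miRNA-specific target when its IP/T ratio reaches
#' `min_ratio` in the test construct and is at least `min_ratio_fold`-fold
#' lower in the reference construct
#' (`ratio_test / ratio_ref >= min_ratio_fold`). For overexpression designs
#' the test construct is the miRNA-transduced one; for sponge designs the
#' same rule is applied with roles swapped (test = control, reference =
#' sponge), so "specific" means enriched in control and depleted under the
#' sponge.
#'
#' @param table A [compute_ratios()] table.
#' @param test_construct,ref_construct Construct labels to contrast.
#' @param cell_line Cell line to use; defaults to the only one present.
#' @param min_ratio Minimum IP/T ratio in the test construct (inclusive).
#' @param min_ratio_fold Minimum fold by which the reference ratio must be
#'   lower (inclusive).
#' @param require_ref_expressed When `TRUE` (default) a probe absent from the
#'   reference construct's table can never be specific; when `FALSE` such
#'   probes are called on the test criterion alone.
#' @return Character vector of specific probe ids.
#' @export
call_specific_targets <- function(table, test_construct, ref_construct,
                                  cell_line = NULL, min_ratio = 2.0,
                                  min_ratio_fold = 2.0,
                                  require_ref_expressed = TRUE) {
  stopifnot(inherits(table, "targetome_table"))
  if (identical(test_construct, ref_construct)) {
    stop("test and reference constructs must differ", call. = FALSE)
  }
  if (is.null(cell_line)) {
    cls <- unique(table$cell_line)
    if (length(cls) != 1L) {
      stop("multiple cell lines present; specify cell_line", call. = FALSE)
    }
    cell_line <- cls
  }
  tst <- table[table$cell_line == cell_line & table$construct == test_construct, ]
  ref <- table[table$cell_line == cell_line & table$construct == ref_construct, ]
  if (!nrow(tst)) stop("test construct absent from table: ", test_construct,
                       call. = FALSE)
  if (!nrow(ref)) stop("reference construct absent from table: ", ref_construct,
                       call. = FALSE)
  ref_ratio <- setNames(ref$ip_t_ratio, ref$probe_id)[tst$probe_id]
  pass_test <- tst$ip_t_ratio >= min_ratio
  has_ref <- !is.na(ref_ratio)
  pass_fold <- has_ref & (tst$ip_t_ratio / ref_ratio >= min_ratio_fold)
  specific <- if (require_ref_expressed) pass_test & pass_fold
              else pass_test & (pass_fold | !has_ref)
  tst$probe_id[specific]
}

#' Collapse probe-level calls to genes
#'
#' Maps probes to genes through the annotation, keeping for each gene the
#' probe with the highest IP fold enrichment as its representative
#' (`gene_ratio` = max probe ratio, the value later used for ranking and
#' gene-set enrichment). Probes without an annotated gene are reported
#' separately, never silently dropped.
#'
#' @param table A [compute_ratios()] table.
#' @param annotation data.frame `probe_id`, `gene` (`NA`/"" = unannotated) or
#'   a named character vector probe -> gene.
#' @param cell_line,construct Sample whose ratios are collapsed; default to
#'   the only ones present.
#' @param specific_probes Optional character vector of specific probe ids
#'   (from [call_specific_targets()]) to collapse to a gene-level set.
#' @return A list of class `gene_collapse`: `genes` (data.frame `gene`,
#'   `probe_id`, `gene_ratio`), `specific_genes`, `unannotated_specific`
#'   (specific probes with no gene) and `unannotated_probes`.
#' @export
collapse_to_genes <- function(table, annotation, cell_line = NULL,
                              construct = NULL, specific_probes = NULL) {
  stopifnot(inherits(table, "targetome_table"))
  if (is.data.frame(annotation)) {
    ann <- setNames(as.character(annotation$gene), annotation$probe_id)
  } else {
    ann <- annotation
  }
  ann[!is.na(ann) & ann == ""] <- NA_character_
  if (is.null(cell_line)) cell_line <- unique(table$cell_line)
  if (is.null(construct)) construct <- unique(table$construct)
  if (length(cell_line) != 1L || length(construct) != 1L) {
    stop("specify a single cell_line and construct to collapse", call. = FALSE)
  }
  sub <- table[table$cell_line == cell_line & table$construct == construct, ]
  gene <- ann[sub$probe_id]
  annotated <- !is.na(gene)
  ord <- order(-sub$ip_t_ratio[annotated], sub$probe_id[annotated])
  sel <- sub[annotated, ][ord, ]
  gsel <- gene[annotated][ord]
  first <- !duplicated(gsel)
  genes <- data.frame(gene = gsel[first], probe_id = sel$probe_id[first],
                      gene_ratio = sel$ip_t_ratio[first],
                      stringsAsFactors = FALSE, row.names = NULL)
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  specific_genes <- character(0)
  unannotated_specific <- character(0)
  if (!is.null(specific_probes)) {
    sg <- ann[specific_probes]
    specific_genes <- sort(unique(sg[!is.na(sg)]))
    unannotated_specific <- specific_probes[is.na(sg)]
  }
  structure(list(genes = genes, specific_genes = unname(specific_genes),
                 unannotated_specific = unannotated_specific,
                 unannotated_probes = sub$probe_id[!annotated]),
            class = "gene_collapse")
}

#' Assign cross-sample enrichment categories to genes
#'
#' Classifies each queried gene in one sample as `Enriched`
#' (gene ratio >= 2), `MildlyEnriched` (1.5 <= ratio < 2), `NotEnriched`
#' (ratio < 1.5), or `NotExpressed` (no retained/detected probe for the
#' gene). The half-open bins resolve the boundary overlap of the published
#' category descriptions so the categories are mutually exclusive.
#'
#' @param collapse A [collapse_to_genes()] result for the queried sample.
#' @param genes Character vector of gene ids to classify.
#' @param enriched_min,mild_min Category boundaries on the gene ratio.
#' @return A named factor with levels `Enriched`, `MildlyEnriched`,
#'   `NotEnriched`, `NotExpressed`.
#' @export
categorize_enrichment <- function(collapse, genes, enriched_min = 2,
                                  mild_min = 1.5) {
  stopifnot(inherits(collapse, "gene_collapse"))
  ratio <- setNames(collapse$genes$gene_ratio, collapse$genes$gene)[genes]
  cat <- ifelse(is.na(ratio), "NotExpressed",
         ifelse(ratio >= enriched_min, "Enriched",
         ifelse(ratio >= mild_min, "MildlyEnriched", "NotEnriched")))
  out <- factor(cat, levels = c("Enriched", "MildlyEnriched", "NotEnriched",
                                "NotExpressed"))
  names(out) <- genes
  out
}
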