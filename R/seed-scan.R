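#' Mature miRNA sequence
#'
#' @param name miRNA name, e.g. `"hsa-miR-155-5p"`.
#' @param sequence Mature sequence written 5'->3'. T is auto-converted to U;
#'   must be at least 8 nt of unambiguous ACGU.
#' @return An object of class `mature_mirna`.
#' @export
mature_mirna <- function(name, sequence) {
  seq <- chartr("t", "u", toupper(as.character(sequence)))
  seq <- chartr("T", "U", seq)
  if (nchar(seq) < 8) {
    stop("mature miRNA must be at least 8 nt to derive seed sites", call. = FALSE)
  }
  if (grepl("[^ACGU]", seq)) {
    stop("miRNA sequence contains non-ACGU characters", call. = FALSE)
  }
  structure(list(name = as.character(name), sequence = seq),
            class = "mature_mirna")
}

#' Derive canonical seed-match site sequences from a mature miRNA
#'
#' Builds the four canonical site types on the target (mRNA sense) strand,
#' written 5'->3' in the DNA alphabet:
#' * `6mer`: reverse complement of miRNA positions 2-7,
#' * `7mer-m8`: reverse complement of positions 2-8,
#' * `7mer-A1`: the 6mer followed by an A (opposite miRNA position 1),
#' * `8mer`: the 7mer-m8 followed by an A.
#'
#' For hsa-miR-155-5p these are GCATTA (6mer) and AGCATTAA (8mer).
#'
#' @param mirna A [mature_mirna()] (or a character sequence, converted).
#' @return A named character vector of class `seed_site_catalog`.
#' @export
derive_sites <- function(mirna) {
  if (is.character(mirna)) mirna <- mature_mirna("miRNA", mirna)
  stopifnot(inherits(mirna, "mature_mirna"))
  dna <- chartr("U", "T", mirna$sequence)
  rc <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  six <- rc(substr(dna, 2, 7))
  sevenm8 <- rc(substr(dna, 2, 8))
  sites <- c("6mer" = six,
             "7mer-A1" = paste0(six, "A"),
             "7mer-m8" = sevenm8,
             "8mer" = paste0(sevenm8, "A"))
  structure(sites, class = "seed_site_catalog", mirna = mirna$name)
}

normalize_seq_input <- function(sequences) {
  if (length(sequences) == 1L && is.character(sequences) &&
      file.exists(sequences)) {
    set <- Biostrings::readDNAStringSet(sequences)
    sequences <- as.character(set)
    names(sequences) <- sub("\\s.*$", "", names(set))
  } else if (methods::is(sequences, "XStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- sub("\\s.*$", "", nm)
  }
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop("no sequences to scan (empty FASTA or vector)", call. = FALSE)
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by gene id", call. = FALSE)
  }
  dup <- unique(names(sequences)[duplicated(names(sequences))])
  if (length(dup)) {
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  s <- toupper(sequences)
  chartr("U", "T", s)
}

#' Scan sequences for miRNA seed-match sites
#'
#' Slides each site over each sequence with step 1 (overlapping occurrences
#' all count), case-insensitively, with U read as T. Scanning is on the given
#' strand only: miRNA sites live on the transcript, so no reverse-complement
#' scan is performed. Ambiguity codes never match. By default counting is
#' inclusive — a genomic 8mer site also counts as the 6mer/7mer it contains;
#' `inclusive = FALSE` counts, for each type, only occurrences not contained
#' inside an occurrence of a longer site type.
#'
#' @param sequences A FASTA path, a named character vector, or a
#'   `DNAStringSet` (names = gene ids).
#' @param catalog A [derive_sites()] catalog.
#' @param site_types Which site types to scan (default: all in the catalog).
#' @param inclusive Count contained shorter-type occurrences (default TRUE).
#' @return A list of class `site_hit_table`: `counts` (data.frame `gene`,
#'   `site_type`, `count`, `has_site`) and `positions` (per gene, per type,
#'   1-based start positions).
#' @export
scan_sequences <- function(sequences, catalog, site_types = names(catalog),
                           inclusive = TRUE) {
  stopifnot(inherits(catalog, "seed_site_catalog"))
  seqs <- normalize_seq_input(sequences)
  site_types <- match.arg(site_types, names(catalog), several.ok = TRUE)
  all_types <- names(catalog)  # containment is judged against every type
  subject <- Biostrings::DNAStringSet(seqs)
  # overlapping starts for every type across all sequences at once
  pos_all <- lapply(all_types, function(t) {
    idx <- Biostrings::startIndex(
      Biostrings::vmatchPattern(catalog[[t]], subject, fixed = TRUE))
    lapply(idx, function(p) if (is.null(p)) integer(0) else sort(p))
  })
  names(pos_all) <- all_types
  positions <- lapply(seq_along(seqs), function(i) {
    pos <- lapply(pos_all[site_types], `[[`, i)
    if (!inclusive) {
      for (t in site_types) {
        len_t <- nchar(catalog[[t]])
        keep <- vapply(pos[[t]], function(p) {
          for (u in all_types) {
            len_u <- nchar(catalog[[u]])
            if (len_u <= len_t) next
            pu <- pos_all[[u]][[i]]
            if (any(pu <= p & pu + len_u >= p + len_t)) return(FALSE)
          }
          TRUE
        }, logical(1))
        pos[[t]] <- pos[[t]][keep]
      }
    }
    pos
  })
  names(positions) <- names(seqs)
  counts <- data.frame(
    gene = rep(names(seqs), each = length(site_types)),
    site_type = rep(site_types, length(seqs)),
    count = unlist(lapply(positions, function(pos) {
      vapply(pos, length, integer(1))
    }), use.names = FALSE),
    stringsAsFactors = FALSE)
  counts$has_site <- counts$count >= 1L
  rownames(counts) <- NULL
  structure(list(counts = counts, positions = positions),
            class = "site_hit_table")
}

#' Summarize seed-site content of a gene list
#'
#' For each site type reports how many genes of the list carry at least one
#' site (`k`), how many listed genes had a scanned sequence (`n`), and the
#' fraction `k/n`. Genes without a scanned sequence are reported in the
#' `missing` attribute and excluded from `n`.
#'
#' @param hits A [scan_sequences()] result.
#' @param gene_list Character vector of gene ids.
#' @return data.frame `site_type`, `k`, `n`, `fraction` with a `missing`
#'   attribute.
#' @export
summarize_site_content <- function(hits, gene_list) {
  stopifnot(inherits(hits, "site_hit_table"))
  gene_list <- unique(as.character(gene_list))
  if (!length(gene_list)) stop("gene list is empty", call. = FALSE)
  scanned <- unique(hits$counts$gene)
  missing <- setdiff(gene_list, scanned)
  present <- setdiff(gene_list, missing)
  if (!length(present)) stop("none of the listed genes were scanned", call. = FALSE)
  types <- unique(hits$counts$site_type)
  out <- do.call(rbind, lapply(types, function(t) {
    sub <- hits$counts[hits$counts$site_type == t & hits$counts$gene %in% present, ]
    data.frame(site_type = t, k = sum(sub$has_site), n = length(present),
               fraction = sum(sub$has_site) / length(present),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

#' Chi-square test for overlap with an external prediction list
#'
#' Pearson chi-square (1 df) on the 2x2 table contrasting how often genes of
#' an identified list are externally predicted targets versus the background
#' rate among all expressed genes. No continuity correction by default
#' (Yates available via `correct = TRUE`).
#'
#' @param list_pred Length-2 counts for the gene list:
#'   `c(predicted, not predicted)`.
#' @param background_pred Length-2 counts for the background genes.
#' @param correct Apply the Yates continuity correction.
#' @return A list of class `overlap_test`: `table` (2x2 matrix),
#'   `statistic`, `df` (1), `p_value`.
#' @export
overlap_chi_square <- function(list_pred, background_pred, correct = FALSE) {
  stopifnot(length(list_pred) == 2L, length(background_pred) == 2L)
  counts <- rbind(`in_list` = as.numeric(list_pred),
                  `background` = as.numeric(background_pred))
  colnames(counts) <- c("predicted", "not_predicted")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  structure(list(table = counts, statistic = unname(ct$statistic),
                 df = 1L, p_value = unname(ct$p.value)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("2x2 overlap chi-square: X^2 = %.4g, df = 1, p = %.3g\n",
              x$statistic, x$p_value))
  print(x$table)
  invisible(x)
}
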