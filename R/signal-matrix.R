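#' Signal matrix container
#'
#' A light container for probe-by-channel fluorescence values on the linear
#' scale, together with per-cell detection flags and a raw/normalized state
#' marker. Rows are probes, columns are individual sample channels (one dye
#' channel of one fraction of one construct).
#'
#' @param signals Numeric matrix, probes in rows (rownames are probe ids),
#'   sample channels in columns (colnames are channel ids). Must be
#'   non-negative.
#' @param detected Optional logical matrix with the same dimensions giving
#'   per-cell detection calls, or `NULL` when the platform export carried no
#'   flags (they can be derived later with [detect_calls()]).
#' @param state Either `"raw"` or `"normalized"`.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(signals, detected = NULL, state = "raw") {
  stopifnot(is.matrix(signals), is.numeric(signals))
  if (is.null(rownames(signals)) || is.null(colnames(signals))) {
    stop("signal matrix needs probe rownames and channel colnames", call. = FALSE)
  }
  if (anyNA(signals) || any(signals < 0)) {
    stop("signal values must be non-negative and non-missing", call. = FALSE)
  }
  if (anyDuplicated(rownames(signals))) {
    stop("duplicate probe ids in signal matrix", call. = FALSE)
  }
  if (!is.null(detected)) {
    stopifnot(is.matrix(detected), is.logical(detected),
              identical(dim(detected), dim(signals)))
    dimnames(detected) <- dimnames(signals)
  }
  state <- match.arg(state, c("raw", "normalized"))
  structure(list(signals = signals, detected = detected, state = state),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d probes x %d channels (%s, flags %s)\n",
              nrow(x$signals), ncol(x$signals), x$state,
              if (is.null(x$detected)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$signals)

DESIGN_COLS <- c("sample_channel_id", "cell_line", "construct", "fraction",
                 "dye", "replicate")

#' Validate an experiment design table
#'
#' The design describes each array channel: cell line, construct
#' (control / overexpression / sponge), fraction (T for total RNA, IP for the
#' Ago2-immunoprecipitated fraction), dye (Cy3/Cy5) and replicate label.
#' Each (cell line, construct, fraction) group must carry exactly one Cy3 and
#' one Cy5 channel — the dye-replicate design — unless
#' `allow_single_channel = TRUE`.
#'
#' @param design A data.frame with columns `sample_channel_id`, `cell_line`,
#'   `construct`, `fraction`, `dye`, `replicate`.
#' @param allow_single_channel Permit groups with a single dye channel.
#' @return The design, invisibly, with a `experiment_design` class.
#' @export
experiment_design <- function(design, allow_single_channel = FALSE) {
  stopifnot(is.data.frame(design))
  missing_cols <- setdiff(DESIGN_COLS, names(design))
  if (length(missing_cols)) {
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  design <- design[DESIGN_COLS]
  for (col in DESIGN_COLS) design[[col]] <- as.character(design[[col]])
  if (anyDuplicated(design$sample_channel_id)) {
    stop("duplicate sample_channel_id in design", call. = FALSE)
  }
  bad_frac <- setdiff(unique(design$fraction), c("T", "IP"))
  if (length(bad_frac)) stop("unknown fraction: ", paste(bad_frac, collapse = ", "),
                             call. = FALSE)
  bad_con <- setdiff(unique(design$construct),
                     c("control", "overexpression", "sponge"))
  if (length(bad_con)) stop("unknown construct: ", paste(bad_con, collapse = ", "),
                            call. = FALSE)
  grp <- interaction(design$cell_line, design$construct, design$fraction,
                     drop = TRUE)
  for (g in levels(grp)) {
    dyes <- sort(design$dye[grp == g])
    ok <- identical(dyes, c("Cy3", "Cy5")) ||
      (allow_single_channel && length(dyes) == 1L)
    if (!ok) {
      stop(sprintf("group %s must have exactly one Cy3 and one Cy5 channel", g),
           call. = FALSE)
    }
  }
  class(design) <- c("experiment_design", "data.frame")
  design
}

design_group <- function(design) {
  paste(design$cell_line, design$construct, design$fraction, sep = ".")
}

#' Read a signal table and its design
#'
#' Reads the tab-separated formats written by [write_signal_table()] (and
#' mirroring plain-text feature-extraction exports): a signal table whose
#' first column is `probe_id` followed by one numeric column per sample
#' channel, optionally accompanied by `<channel>.flag` columns of 0/1
#' detection calls, plus a five-field design table.
#'
#' @param path Path to the signal TSV.
#' @param design_path Path to the design TSV.
#' @param allow_single_channel Passed to [experiment_design()].
#' @return A list with elements `matrix` (a [signal_matrix()]) and `design`.
#' @export
read_signal_table <- function(path, design_path, allow_single_channel = FALSE) {
  if (!file.exists(path)) stop("signal table not found: ", path, call. = FALSE)
  if (!file.exists(design_path)) stop("design table not found: ", design_path,
                                      call. = FALSE)
  design <- experiment_design(
    read.delim(design_path, stringsAsFactors = FALSE, check.names = FALSE),
    allow_single_channel = allow_single_channel)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "probe_id") {
    stop("signal table must have 'probe_id' as its first column", call. = FALSE)
  }
  ids <- design$sample_channel_id
  flag_cols <- paste0(ids, ".flag")
  extra <- setdiff(names(tab)[-1], c(ids, flag_cols))
  if (length(extra)) {
    stop("signal table has columns not in the design: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing_ch <- setdiff(ids, names(tab))
  if (length(missing_ch)) {
    stop("design channels missing from signal table: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  for (id in ids) {
    if (!is.numeric(tab[[id]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[id]]))))[1]
      stop(sprintf("non-numeric signal in column '%s', row %d", id, bad),
           call. = FALSE)
    }
  }
  sig <- as.matrix(tab[ids])
  rownames(sig) <- tab$probe_id
  present_flags <- intersect(flag_cols, names(tab))
  detected <- NULL
  if (length(present_flags)) {
    if (!setequal(present_flags, flag_cols)) {
      stop("detection flag columns present for only some channels: have ",
           paste(present_flags, collapse = ", "), call. = FALSE)
    }
    detected <- as.matrix(tab[paste0(ids, ".flag")]) != 0
    colnames(detected) <- ids
    rownames(detected) <- tab$probe_id
  }
  list(matrix = signal_matrix(sig, detected = detected, state = "raw"),
       design = design)
}

#' Write a signal table and design to TSV
#'
#' @param x A [signal_matrix()].
#' @param design The matching [experiment_design()].
#' @param path,design_path Output TSV paths.
#' @return Invisibly, `path`.
#' @export
write_signal_table <- function(x, design, path, design_path) {
  stopifnot(inherits(x, "signal_matrix"))
  tab <- data.frame(probe_id = rownames(x$signals), x$signals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$detected)) {
    flags <- x$detected * 1L
    colnames(flags) <- paste0(colnames(x$signals), ".flag")
    tab <- cbind(tab, flags)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(design), design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
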