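#' Quantile normalization across all channels
#'
#' Forces every channel to share the same signal distribution: each column's
#' sorted values are replaced by the cross-column mean of order statistics,
#' with ties within a column receiving the mean of the normalized values of
#' the tied ranks. Applied jointly across all channels (both fractions, all
#' constructs), as in a single analysis session. Detection flags are carried
#' through unchanged. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x A raw-state [signal_matrix()] with at least two channels.
#' @return The normalized [signal_matrix()].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "signal_matrix"))
  if (x$state != "raw") stop("matrix is already normalized", call. = FALSE)
  if (ncol(x$signals) < 2) {
    stop("quantile normalization needs at least 2 channels", call. = FALSE)
  }
  norm <- limma::normalizeQuantiles(x$signals, ties = TRUE)
  dimnames(norm) <- dimnames(x$signals)
  signal_matrix(norm, detected = x$detected, state = "normalized")
}

#' Resolve detection calls for flag-free inputs
#'
#' When the platform export carried no detection flags, a probe is called
#' detected in a channel iff its signal strictly exceeds the
#' `threshold_quantile` of that channel's signal distribution (a transparent
#' quantile-floor stand-in for proprietary feature-extraction calls).
#' Existing flags are never overwritten: if the matrix already has flags the
#' input is returned unchanged.
#'
#' @param x A [signal_matrix()] (raw or normalized).
#' @param threshold_quantile Detection floor quantile, strictly in (0, 1).
#' @return The [signal_matrix()] with `detected` populated.
#' @export
detect_calls <- function(x, threshold_quantile = 0.10) {
  stopifnot(inherits(x, "signal_matrix"))
  if (!is_prob(threshold_quantile) || threshold_quantile <= 0 ||
      threshold_quantile >= 1) {
    stop_config("threshold_quantile", "must lie strictly in (0, 1)")
  }
  if (!is.null(x$detected)) return(x)
  thr <- apply(x$signals, 2, quantile, probs = threshold_quantile, names = FALSE)
  detected <- sweep(x$signals, 2, thr, `>`)
  signal_matrix(x$signals, detected = detected, state = x$state)
}

#' Filter probes on detection and dye-replicate consistency
#'
#' Implements the two published quality rules: probes not detected in more
#' than half of the sample channels are removed (`detected_fraction < 0.5`;
#' exactly half is retained), and probes whose Cy3 and Cy5 signals differ by
#' more than `max_dye_fold` in any (cell line, construct, fraction) dye pair
#' are removed. Removal reasons are assigned in fixed order: detection first,
#' then consistency. A floor of 1.0 fluorescence unit is applied inside the
#' dye ratio to avoid division by zero.
#'
#' @param x A [signal_matrix()] with detection flags resolved.
#' @param design The matching [experiment_design()].
#' @param max_dye_fold Maximum tolerated Cy3/Cy5 fold difference.
#' @param min_detected_fraction Minimum fraction of channels in which a probe
#'   must be detected (inclusive).
#' @return A list with `matrix` (retained probes) and `report`
#'   (class `filter_report`: counts plus per-probe removal reasons).
#' @export
filter_probes <- function(x, design, max_dye_fold = 2.0,
                          min_detected_fraction = 0.5) {
  stopifnot(inherits(x, "signal_matrix"))
  if (is.null(x$detected)) {
    stop("detection flags unresolved; run detect_calls() first", call. = FALSE)
  }
  design <- experiment_design(as.data.frame(design), allow_single_channel = TRUE)
  sig <- x$signals[, design$sample_channel_id, drop = FALSE]
  det <- x$detected[, design$sample_channel_id, drop = FALSE]

  det_frac <- rowMeans(det)
  fail_detection <- det_frac < min_detected_fraction

  grp <- split(seq_len(nrow(design)), design_group(design))
  fail_consistency <- rep(FALSE, nrow(sig))
  eps <- 1.0  # fluorescence-unit floor inside the dye ratio
  for (cols in grp) {
    if (length(cols) != 2L) next  # single-channel fallback: no pair to compare
    a <- pmax(sig[, cols[1]], eps)
    b <- pmax(sig[, cols[2]], eps)
    fail_consistency <- fail_consistency | (pmax(a, b) / pmin(a, b) > max_dye_fold)
  }

  reason <- rep(NA_character_, nrow(sig))
  reason[fail_consistency] <- "dye_inconsistent"
  reason[fail_detection] <- "not_detected"  # detection takes precedence
  keep <- is.na(reason)

  report <- structure(list(
    n_probes_input = nrow(sig),
    n_removed_detection = sum(reason == "not_detected", na.rm = TRUE),
    n_removed_consistency = sum(reason == "dye_inconsistent", na.rm = TRUE),
    n_probes_retained = sum(keep),
    removed = data.frame(probe_id = rownames(sig)[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)),
    class = "filter_report")

  list(matrix = signal_matrix(sig[keep, , drop = FALSE],
                              detected = det[keep, , drop = FALSE],
                              state = x$state),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("probe filter: %d in, %d removed (detection %d, dye consistency %d), %d retained\n",
              x$n_probes_input,
              x$n_removed_detection + x$n_removed_consistency,
              x$n_removed_detection, x$n_removed_consistency,
              x$n_probes_retained))
  invisible(x)
}

#' Average Cy3/Cy5 dye replicates into per-sample signals
#'
#' Collapses each (cell line, construct, fraction) dye pair to its arithmetic
#' mean on the linear scale (the scale on which IP/T ratios are subsequently
#' formed); single-channel groups pass through. A geometric mean is available
#' for log-symmetric averaging.
#'
#' @param x A filtered [signal_matrix()].
#' @param design The matching [experiment_design()].
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return A [signal_matrix()] with one column per sample group and an
#'   attached `groups` attribute (data.frame `sample_id`, `cell_line`,
#'   `construct`, `fraction`).
#' @export
average_dye_replicates <- function(x, design, method = c("arithmetic", "geometric")) {
  stopifnot(inherits(x, "signal_matrix"))
  method <- match.arg(method)
  design <- experiment_design(as.data.frame(design), allow_single_channel = TRUE)
  gid <- design_group(design)
  groups <- unique(data.frame(sample_id = gid, cell_line = design$cell_line,
                              construct = design$construct,
                              fraction = design$fraction,
                              stringsAsFactors = FALSE))
  avg <- sapply(groups$sample_id, function(g) {
    cols <- design$sample_channel_id[gid == g]
    m <- x$signals[, cols, drop = FALSE]
    if (method == "arithmetic") rowMeans(m) else exp(rowMeans(log(pmax(m, 1e-300))))
  })
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1, dimnames = list(rownames(x$signals), groups$sample_id))
  out <- signal_matrix(avg, detected = NULL, state = x$state)
  attr(out, "groups") <- groups
  out
}
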