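# shared fixture builders; everything is generated in code, nothing on disk

mir155 <- function() mature_mirna("hsa-miR-155-5p", "UUAAUGCUAAUCGUGAUAGGGGU")

# a dye-averaged signal matrix (with its sample-group attribute) built
# directly from the IP/T ratios we want each construct to show
averaged_from_ratios <- function(ratio_test, ratio_ref, t_signal = 100,
                                 cell_line = "CL") {
  n <- length(ratio_test)
  probes <- sprintf("P%03d", seq_len(n))
  ids <- paste(cell_line, rep(c("control", "overexpression"), each = 2),
               rep(c("T", "IP"), 2), sep = ".")
  sig <- cbind(rep(t_signal, n), t_signal * ratio_ref,
               rep(t_signal, n), t_signal * ratio_test)
  dimnames(sig) <- list(probes, ids)
  m <- signal_matrix(sig, state = "normalized")
  attr(m, "groups") <- data.frame(
    sample_id = ids, cell_line = cell_line,
    construct = rep(c("control", "overexpression"), each = 2),
    fraction = rep(c("T", "IP"), 2), stringsAsFactors = FALSE)
  m
}

# small raw two-construct experiment with hand-set signals
tiny_design <- function(cell_line = "CL",
                        constructs = c("control", "overexpression")) {
  g <- expand.grid(dye = c("Cy3", "Cy5"), fraction = c("T", "IP"),
                   construct = constructs, stringsAsFactors = FALSE)
  experiment_design(data.frame(
    sample_channel_id = paste(cell_line, g$construct, g$fraction, g$dye, sep = "."),
    cell_line = cell_line, construct = g$construct, fraction = g$fraction,
    dye = g$dye, replicate = "r1", stringsAsFactors = FALSE))
}

random_signal_matrix <- function(n_probes, design, seed = 1, detected = TRUE) {
  set.seed(seed)
  sig <- matrix(2^rnorm(n_probes * nrow(design), 10, 1.5), n_probes,
                dimnames = list(sprintf("P%04d", seq_len(n_probes)),
                                design$sample_channel_id))
  det <- if (detected) {
    matrix(TRUE, n_probes, nrow(design), dimnames = dimnames(sig))
  } else NULL
  signal_matrix(sig, detected = det)
}

# exact Mann-Whitney p by enumerating every rank assignment
mw_enum_p <- function(a, b, alternative) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  p_ge <- mean(us >= u_obs)
  p_le <- mean(us <= u_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# closed-form quantile-normalization oracle for tie-free columns
qn_oracle <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) target[rank(col)])
}
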