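test_that("signal tables round-trip through TSV bit-identically", {
  design <- tiny_design()
  m <- random_signal_matrix(100, design, seed = 4)
  sig_path <- withr::local_tempfile(fileext = ".tsv")
  des_path <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(m, design, sig_path, des_path)
  back <- read_signal_table(sig_path, des_path)
  expect_equal(back$matrix$signals, m$signals)
  expect_identical(back$matrix$detected, m$detected)
  expect_identical(as.data.frame(back$design), as.data.frame(design))
})

test_that("malformed signal tables are rejected with the offending ids", {
  design <- tiny_design()
  m <- random_signal_matrix(10, design, detected = FALSE)
  sig_path <- withr::local_tempfile(fileext = ".tsv")
  des_path <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(m, design, sig_path, des_path)
  # flags absent in the file => provisional (NULL) flags
  expect_null(read_signal_table(sig_path, des_path)$matrix$detected)

  tab <- read.delim(sig_path, check.names = FALSE)
  tab$mystery <- 1
  write.table(tab, sig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signal_table(sig_path, des_path), "mystery")

  tab$mystery <- NULL
  tab[[2]] <- as.character(tab[[2]])
  tab[3, 2] <- "oops"
  write.table(tab, sig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signal_table(sig_path, des_path), "non-numeric")
})

test_that("quantile normalization matches the mean-of-order-statistics form", {
  m <- signal_matrix(matrix(c(1, 2, 3, 6, 4, 5), 3,
                            dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$signals[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$signals[, "s2"]), c(4.5, 2.5, 3.5))

  # identical columns are a fixed point
  same <- matrix(rep(c(5, 1, 9, 3), 2), 4,
                 dimnames = list(letters[1:4], c("x", "y")))
  expect_equal(quantile_normalize(signal_matrix(same))$signals, same)

  # postcondition: all columns share sorted values; ranks preserved
  design <- tiny_design()
  r <- random_signal_matrix(200, design, seed = 8)
  qn2 <- quantile_normalize(r)
  sorted <- apply(qn2$signals, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
  for (j in seq_len(ncol(r$signals))) {
    expect_equal(rank(qn2$signals[, j]), rank(r$signals[, j]))
  }
  expect_identical(qn2$detected, r$detected)

  expect_error(quantile_normalize(signal_matrix(
    matrix(1:3, 3, dimnames = list(letters[1:3], "only")))), "2 channels")
})

test_that("quantile normalization is idempotent", {
  design <- tiny_design()
  r <- random_signal_matrix(150, design, seed = 10)
  q1 <- quantile_normalize(r)
  q1_raw <- signal_matrix(q1$signals, detected = q1$detected, state = "raw")
  q2 <- quantile_normalize(q1_raw)
  expect_equal(q2$signals, q1$signals, tolerance = 1e-12)
})

test_that("ties receive the mean of the tied ranks' normalized values", {
  m <- signal_matrix(matrix(c(1, 1, 4, 2, 6, 10), 3,
                            dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  qn <- quantile_normalize(m)
  # target distribution: rowMeans(sort) = c(1.5, 3.5, 7); the s1 tie at
  # ranks 1-2 gets mean(1.5, 3.5) = 2.5
  expect_equal(unname(qn$signals[, "s1"]), c(2.5, 2.5, 7))
  expect_equal(unname(qn$signals[, "s2"]), c(1.5, 3.5, 7))
})

test_that("detection calls use a strict per-channel quantile threshold", {
  design <- tiny_design()
  m <- random_signal_matrix(1000, design, seed = 3, detected = FALSE)
  d <- detect_calls(m, threshold_quantile = 0.10)
  # distinct values: exactly 900 exceed the 10th percentile
  expect_true(all(colSums(d$detected) == 900))

  # existing flags are never overwritten
  d2 <- detect_calls(d, threshold_quantile = 0.5)
  expect_identical(d2$detected, d$detected)

  # constant column: strict inequality leaves nothing detected
  cm <- signal_matrix(matrix(5, 4, 2, dimnames = list(letters[1:4], c("x", "y"))))
  expect_true(all(!detect_calls(cm)$detected))

  expect_error(detect_calls(m, threshold_quantile = 0), "threshold_quantile")
  expect_error(detect_calls(m, threshold_quantile = 1), "threshold_quantile")
})

test_that("probe filtering applies the detection and dye-consistency rules", {
  design <- tiny_design()
  sig <- matrix(100, 4, 8, dimnames = list(paste0("P", 1:4),
                                           design$sample_channel_id))
  # P2: Cy5 just over 2-fold different from Cy3 in one pair
  sig[2, "CL.control.T.Cy5"] <- 201
  # P3: exactly 2-fold different -> retained (strict >)
  sig[3, "CL.control.T.Cy5"] <- 200
  det <- matrix(TRUE, 4, 8, dimnames = dimnames(sig))
  det[4, 1:4] <- FALSE  # P4 detected in exactly half the channels
  det[1, 1:5] <- FALSE  # P1 detected in 3/8 channels -> removed
  f <- filter_probes(signal_matrix(sig, detected = det), design)
  expect_setequal(rownames(f$matrix$signals), c("P3", "P4"))
  expect_equal(f$report$n_removed_detection, 1)
  expect_equal(f$report$n_removed_consistency, 1)
  expect_equal(f$report$n_probes_input,
               f$report$n_removed_detection + f$report$n_removed_consistency +
                 f$report$n_probes_retained)
  expect_setequal(f$report$removed$reason[f$report$removed$probe_id == "P1"],
                  "not_detected")
})

test_that("filtering equals a brute-force probe-by-probe oracle", {
  design <- tiny_design()
  set.seed(21)
  n <- 500
  sig <- matrix(2^rnorm(n * 8, 10, 1), n,
                dimnames = list(sprintf("P%03d", 1:n), design$sample_channel_id))
  det <- matrix(runif(n * 8) > 0.3, n, dimnames = dimnames(sig))
  m <- signal_matrix(sig, detected = det)
  f <- filter_probes(m, design, max_dye_fold = 2, min_detected_fraction = 0.5)

  groups <- split(design$sample_channel_id,
                  paste(design$cell_line, design$construct, design$fraction))
  keep_oracle <- vapply(seq_len(n), function(i) {
    if (mean(det[i, ]) < 0.5) return(FALSE)
    for (ids in groups) {
      a <- max(sig[i, ids[1]], 1); b <- max(sig[i, ids[2]], 1)
      if (max(a, b) / min(a, b) > 2) return(FALSE)
    }
    TRUE
  }, logical(1))
  expect_setequal(rownames(f$matrix$signals), rownames(sig)[keep_oracle])
})

test_that("filtering is invariant to probe ordering", {
  design <- tiny_design()
  m <- random_signal_matrix(300, design, seed = 33)
  m$detected[sample(length(m$detected), 500)] <- FALSE
  f1 <- filter_probes(m, design)
  perm <- sample(nrow(m$signals))
  m2 <- signal_matrix(m$signals[perm, ], detected = m$detected[perm, ])
  f2 <- filter_probes(m2, design)
  expect_setequal(rownames(f1$matrix$signals), rownames(f2$matrix$signals))
})

test_that("dye averaging collapses each sample pair to its mean", {
  design <- tiny_design()
  sig <- matrix(100, 2, 8, dimnames = list(c("P1", "P2"),
                                           design$sample_channel_id))
  sig[1, "CL.control.T.Cy3"] <- 100
  sig[1, "CL.control.T.Cy5"] <- 300
  m <- signal_matrix(sig)
  avg <- average_dye_replicates(m, design)
  expect_equal(ncol(avg$signals), 4)  # one column per (cell line, construct, fraction)
  expect_equal(avg$signals["P1", "CL.control.T"], 200)
  expect_equal(avg$signals["P2", "CL.control.T"], 100)
  groups <- attr(avg, "groups")
  expect_setequal(groups$sample_id,
                  unique(paste(design$cell_line, design$construct,
                               design$fraction, sep = ".")))
})

test_that("zero-noise synthetic data passes through preprocessing exactly", {
  cfg <- ripchip_sim_config(n_genes = 200, probes_per_gene = 1,
                            n_planted_targets = 0, noise_sd_log2 = 0,
                            dye_effect_sd_log2 = 0, detection_dropout_rate = 0,
                            rng_seed = 6)
  e <- generate_ripchip(cfg)
  # all channels identical => quantile normalization is a fixed point and
  # averaging returns the planted signals
  q <- detect_calls(quantile_normalize(e$matrix))
  f <- filter_probes(q, e$design)
  avg <- average_dye_replicates(f$matrix, e$design)
  expect_equal(avg$signals[, "SIM1.control.T"],
               e$matrix$signals[, "SIM1.control.T.Cy3"], tolerance = 1e-12)
})
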