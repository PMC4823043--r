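test_that("IP/T ratios and targetome membership honour the inclusive threshold", {
  avg <- averaged_from_ratios(ratio_test = c(2, 1, 3.99), ratio_ref = c(1, 1, 1))
  tab <- compute_ratios(avg)
  over <- tab[tab$construct == "overexpression", ]
  expect_equal(over$ip_t_ratio, c(2, 1, 3.99))
  # ratio exactly 2 is a member; 1 is not
  expect_equal(over$targetome_member, c(TRUE, FALSE, TRUE))
})

test_that("the denominator floor prevents infinite ratios", {
  avg <- averaged_from_ratios(ratio_test = c(4), ratio_ref = c(1), t_signal = 100)
  avg$signals[1, "CL.overexpression.T"] <- 0  # dropout-level total
  tab <- compute_ratios(avg, t_floor = 1)
  over <- tab[tab$construct == "overexpression", ]
  expect_true(is.finite(over$ip_t_ratio))
  expect_equal(over$ip_t_ratio, 400)  # ip 400 over floored denominator 1
})

test_that("specific-target calling applies both printed rules", {
  avg <- averaged_from_ratios(ratio_test = c(4.0, 4.0, 1.9, 2.0),
                              ratio_ref = c(1.5, 2.5, 0.5, 1.0))
  tab <- compute_ratios(avg)
  sp <- call_specific_targets(tab, "overexpression", "control")
  # P1: 4 >= 2 and 4/1.5 = 2.67 >= 2 -> specific
  # P2: fold 1.6 < 2 -> no; P3: ratio 1.9 < 2 -> no; P4: 2/1 = 2 -> yes
  expect_setequal(sp, c("P001", "P004"))
  expect_error(call_specific_targets(tab, "control", "control"), "differ")
})

test_that("targetome and specific calls equal a brute-force oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    rt <- 2^rnorm(n, 0.5, 1)
    rr <- 2^rnorm(n, 0, 1)
    tab <- compute_ratios(averaged_from_ratios(rt, rr))
    over <- tab[tab$construct == "overexpression", ]
    expect_equal(over$targetome_member, rt >= 2)
    sp <- call_specific_targets(tab, "overexpression", "control")
    oracle <- over$probe_id[rt >= 2 & rt / rr >= 2]
    expect_setequal(sp, oracle)
  }
})

test_that("tightening thresholds never enlarges the specific set", {
  set.seed(99)
  tab <- compute_ratios(averaged_from_ratios(2^rnorm(300, 0.5, 1),
                                             2^rnorm(300, 0, 1)))
  base <- call_specific_targets(tab, "overexpression", "control",
                                min_ratio = 2, min_ratio_fold = 2)
  for (mr in c(2.5, 3, 4)) {
    expect_true(all(call_specific_targets(tab, "overexpression", "control",
                                          min_ratio = mr) %in% base))
    expect_true(all(call_specific_targets(tab, "overexpression", "control",
                                          min_ratio_fold = mr) %in% base))
  }
  # specific set is always inside the test-construct targetome
  over <- tab[tab$construct == "overexpression", ]
  expect_true(all(base %in% over$probe_id[over$targetome_member]))
})

test_that("ratios and calls are invariant to per-sample rescaling", {
  set.seed(7)
  rt <- 2^rnorm(100, 0.5, 1); rr <- 2^rnorm(100, 0, 1)
  avg1 <- averaged_from_ratios(rt, rr)
  avg2 <- avg1
  # scale both fractions of the overexpression sample pair by a constant
  cols <- c("CL.overexpression.T", "CL.overexpression.IP")
  avg2$signals[, cols] <- avg2$signals[, cols] * 37.5
  t1 <- compute_ratios(avg1); t2 <- compute_ratios(avg2)
  expect_equal(t1$ip_t_ratio, t2$ip_t_ratio, tolerance = 1e-12)
  expect_identical(call_specific_targets(t1, "overexpression", "control"),
                   call_specific_targets(t2, "overexpression", "control"))
})

test_that("probe-to-gene collapse keeps the max-ratio probe and reports unannotated probes", {
  # the published multiplicity structure: 64 specific probes, 3 with no
  # known gene, the rest detecting 54 distinct genes
  set.seed(123)
  genes <- sprintf("GENE%02d", 1:54)
  gene_of_probe <- c(genes, sample(genes, 7, replace = FALSE), rep(NA, 3))
  n <- length(gene_of_probe)  # 64 probes
  ann <- data.frame(probe_id = sprintf("P%03d", seq_len(n)), gene = gene_of_probe)
  rt <- runif(n, 2.5, 12); rr <- rep(1, n)
  tab <- compute_ratios(averaged_from_ratios(rt, rr))
  sp <- call_specific_targets(tab, "overexpression", "control")
  expect_length(sp, 64)
  col <- collapse_to_genes(tab, ann, construct = "overexpression",
                           specific_probes = sp)
  expect_length(col$specific_genes, 54)
  expect_length(col$unannotated_specific, 3)
  # gene_ratio is the max over the gene's probes
  for (g in sample(genes, 5)) {
    probes <- ann$probe_id[!is.na(ann$gene) & ann$gene == g]
    expect_equal(col$genes$gene_ratio[col$genes$gene == g],
                 max(rt[match(probes, ann$probe_id)]))
  }
})

test_that("gene collapse equals a brute-force grouping oracle", {
  set.seed(55)
  n <- 120
  ann <- data.frame(probe_id = sprintf("P%03d", 1:n),
                    gene = sample(sprintf("g%02d", 1:40), n, replace = TRUE))
  rt <- 2^rnorm(n, 0.5, 1)
  tab <- compute_ratios(averaged_from_ratios(rt, rep(1, n)))
  col <- collapse_to_genes(tab, ann, construct = "overexpression")
  oracle <- tapply(rt[match(ann$probe_id, sprintf("P%03d", 1:n))], ann$gene, max)
  expect_equal(col$genes$gene_ratio,
               unname(as.vector(oracle[col$genes$gene])))
  expect_setequal(col$genes$gene, unique(ann$gene))
})

test_that("enrichment categories use mutually exclusive half-open bins", {
  ratios <- c(a = 1.75, b = 2, c = 1.5, d = 1.49, e = 5)
  tab <- compute_ratios(averaged_from_ratios(unname(ratios), rep(1, 5)))
  ann <- data.frame(probe_id = sprintf("P%03d", 1:5), gene = names(ratios))
  col <- collapse_to_genes(tab, ann, construct = "overexpression")
  cats <- categorize_enrichment(col, c(names(ratios), "absent_gene"))
  # 1.75-fold: mildly enriched (the borderline case seen on real arrays)
  expect_equal(as.character(cats[["a"]]), "MildlyEnriched")
  expect_equal(as.character(cats[["b"]]), "Enriched")       # exactly 2
  expect_equal(as.character(cats[["c"]]), "MildlyEnriched") # exactly 1.5
  expect_equal(as.character(cats[["d"]]), "NotEnriched")
  expect_equal(as.character(cats[["e"]]), "Enriched")
  expect_equal(as.character(cats[["absent_gene"]]), "NotExpressed")
})

test_that("category counts equal a brute-force binning oracle", {
  set.seed(77)
  n <- 100
  rt <- 2^rnorm(n, 0.3, 0.8)
  tab <- compute_ratios(averaged_from_ratios(rt, rep(1, n)))
  ann <- data.frame(probe_id = sprintf("P%03d", 1:n), gene = sprintf("g%03d", 1:n))
  col <- collapse_to_genes(tab, ann, construct = "overexpression")
  cats <- categorize_enrichment(col, ann$gene)
  oracle <- ifelse(rt >= 2, "Enriched",
            ifelse(rt >= 1.5, "MildlyEnriched", "NotEnriched"))
  expect_equal(unname(table(cats)[c("Enriched", "MildlyEnriched", "NotEnriched")]),
               unname(table(factor(oracle, c("Enriched", "MildlyEnriched",
                                             "NotEnriched")))))
})

test_that("zero-noise end-to-end recovery of planted targets is exact", {
  cfg <- ripchip_sim_config(n_genes = 300, probes_per_gene = 2,
                            n_planted_targets = 25,
                            ip_enrichment_fold_targets = 4,
                            noise_sd_log2 = 0, dye_effect_sd_log2 = 0,
                            detection_dropout_rate = 0, rng_seed = 13)
  e <- generate_ripchip(cfg)
  q <- detect_calls(quantile_normalize(e$matrix))
  f <- filter_probes(q, e$design)
  avg <- average_dye_replicates(f$matrix, e$design)
  tab <- compute_ratios(avg)
  sp <- call_specific_targets(tab, "overexpression", "control")
  col <- collapse_to_genes(tab, e$annotation, construct = "overexpression",
                           specific_probes = sp)
  expect_setequal(col$specific_genes, e$truth_targets)
})

test_that("sponge designs are called with the roles swapped", {
  # the role-swapped rule on a constructed ratio table: specific means
  # enriched in the control (miRNA-high) sample and >= 2-fold lower under
  # the sponge
  n <- 6
  ids <- paste("HL", rep(c("sponge", "control"), each = 2),
               rep(c("T", "IP"), 2), sep = ".")
  ratio_control <- c(4, 4, 2, 1.9, 4, 3)
  ratio_sponge <- c(1, 2.5, 1, 1, 2, 1.5)
  sig <- cbind(100, 100 * ratio_sponge, 100, 100 * ratio_control)
  dimnames(sig) <- list(sprintf("P%03d", 1:n), ids)
  m <- signal_matrix(sig, state = "normalized")
  attr(m, "groups") <- data.frame(
    sample_id = ids, cell_line = "HL",
    construct = rep(c("sponge", "control"), each = 2),
    fraction = rep(c("T", "IP"), 2), stringsAsFactors = FALSE)
  tab <- compute_ratios(m)
  sp <- call_specific_targets(tab, test_construct = "control",
                              ref_construct = "sponge")
  # P1: 4 vs 1 -> yes; P2: fold 1.6 -> no; P3: 2 vs 1 -> yes;
  # P4: control 1.9 < 2 -> no; P5: fold 2 -> yes; P6: fold 2 -> yes
  expect_setequal(sp, c("P001", "P003", "P005", "P006"))

  # an effective sponge releases the enrichment, a weak one (fold shrunk
  # only 20% toward 1) barely does: far fewer specific probes
  cfg <- ripchip_sim_config(n_genes = 1000, probes_per_gene = 1,
                            n_planted_targets = 20,
                            ip_enrichment_fold_targets = 4,
                            design_type = "sponge", sponge_shrink = 0.2,
                            rng_seed = 17)
  e2 <- generate_ripchip(cfg)
  avg2 <- average_dye_replicates(
    filter_probes(detect_calls(quantile_normalize(e2$matrix)), e2$design)$matrix,
    e2$design)
  sp2 <- call_specific_targets(compute_ratios(avg2), "control", "sponge")
  expect_lt(length(sp2), length(e2$truth_targets) / 2)
})
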