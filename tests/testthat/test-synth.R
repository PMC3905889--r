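test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 99, n_activated = 10, n_repressed = 5,
                      n_background = 8, flank_len = 40,
                      exon_len_range = c(20, 60),
                      spikes = list(list(motif = "UCUCU", set = "activated",
                                         region = "downstream_intron",
                                         rate = 0.5, copies = 1)))
  a <- gen_context_set(cfg); b <- gen_context_set(cfg)
  expect_identical(a, b)
  expect_identical(gen_event_table(cfg), gen_event_table(cfg))
  expect_identical(gen_isoform_measurements(cfg),
                   gen_isoform_measurements(cfg))
  expect_identical(gen_expression_table(cfg, n_genes = 100),
                   gen_expression_table(cfg, n_genes = 100))

  # FASTA serialisation is byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_contexts_fasta(a$activated, f1)
  write_contexts_fasta(b$activated, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a different seed changes the draw
  expect_false(identical(
    a, gen_context_set(synth_config(seed = 100, n_activated = 10,
                                    n_repressed = 5, n_background = 8,
                                    flank_len = 40,
                                    exon_len_range = c(20, 60)))))
})

test_that("config validation enforces threshold clearance and alphabet", {
  expect_error(synth_config(), "seed")
  expect_error(synth_config(seed = 1, bf_regulated_range = c(9, 100)),
               "strictly above 10")
  expect_error(synth_config(seed = 1, bf_background_range = c(0.01, 0.1)),
               "inside")
  expect_error(synth_config(seed = 1,
                            base_composition = c(A = .5, C = .5, G = 0, U = .1)),
               "sum to 1")
  expect_error(synth_config(seed = 1,
                            spikes = list(list(motif = "UCTCU",
                                               set = "activated",
                                               region = "exon", rate = 1))),
               "A,C,G,U")
  expect_error(synth_config(seed = 1, psi_noise_sd = -1), "non-negative")
})

test_that("truth records locate every planted motif instance", {
  cfg <- synth_config(seed = 7, n_activated = 20, n_repressed = 4,
                      n_background = 10, flank_len = 60,
                      exon_len_range = c(30, 50),
                      spikes = list(list(motif = "UAAAA", set = "repressed",
                                         region = "exon", rate = 1.0,
                                         copies = 2)))
  cs <- gen_context_set(cfg)
  expect_equal(nrow(cs$truth), 8)  # 4 sequences x 2 copies
  for (r in seq_len(nrow(cs$truth))) {
    tr <- cs$truth[r, ]
    seq <- cs$repressed[[tr$region]][cs$repressed$event_id == tr$event_id]
    expect_equal(substr(seq, tr$offset + 1, tr$offset + nchar(tr$motif)),
                 tr$motif)
  }
  # guaranteed-rate PTB spike is always found by the scanner downstream
  cfg2 <- synth_config(seed = 8, n_activated = 30, n_repressed = 2,
                       n_background = 2, flank_len = 60,
                       exon_len_range = c(30, 50),
                       spikes = list(list(motif = "UCUACUAUCU",
                                          set = "activated",
                                          region = "downstream_intron",
                                          rate = 1.0)))
  cs2 <- gen_context_set(cfg2)
  hits <- scan_context_set(cs2$activated, ptb_pattern("high"))
  expect_true(all(hits$n_downstream >= 1))
})

test_that("spike-free sequences match the i.i.d. composition expectation", {
  cfg <- synth_config(seed = 15, n_activated = 400, n_repressed = 2,
                      n_background = 2, flank_len = 80,
                      exon_len_range = c(40, 40))
  cs <- gen_context_set(cfg)
  # count a fixed 5-mer in the downstream introns: expectation N * (1/4)^5
  counts <- vapply(cs$activated$downstream_intron, function(s) {
    cnt <- count_kmers(s, 5)$counts
    if ("GCAUG" %in% names(cnt)) as.integer(cnt[["GCAUG"]]) else 0L
  }, integer(1), USE.NAMES = FALSE)
  n_windows <- 80 - 4
  expected <- n_windows * 0.25^5
  se <- sqrt(stats::var(counts) / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("the planted event partition is recovered by classification", {
  cfg <- synth_config(seed = 23)
  ge <- gen_event_table(cfg)
  out <- classify_events(ge$events)
  merged <- merge(out[, c("event_id", "regulation")], ge$truth)
  expect_equal(sum(merged$regulation == "activated"), 159)
  expect_equal(sum(merged$regulation == "repressed"), 92)
  expect_equal(sum(merged$regulation == "background"), 276)
  expect_true(all(merged$regulation[merged$true_class == "decoy"] ==
                    "unassigned"))
  expect_true(all(merged$regulation[merged$regulation != "unassigned"] ==
                    merged$true_class[merged$regulation != "unassigned"]))

  # no decoys, no background: nothing is left unassigned
  cfg0 <- synth_config(seed = 24, n_activated = 12, n_repressed = 8,
                       n_background = 0, n_long_decoys = 0)
  out0 <- classify_events(gen_event_table(cfg0)$events)
  expect_true(all(out0$regulation %in% c("activated", "repressed")))
})

test_that("generated event tables round-trip through the parser", {
  cfg <- synth_config(seed = 31, n_activated = 15, n_repressed = 10,
                      n_background = 12, n_long_decoys = 2)
  ge <- gen_event_table(cfg)
  f <- tempfile(fileext = ".tsv")
  write_event_table(ge$events, f)
  back <- parse_event_table(f)
  expect_equal(nrow(back), nrow(ge$events))
  expect_equal(nrow(attr(back, "bad_rows")), 0)
  expect_equal(back$event_id, ge$events$event_id)
  expect_equal(back$bayes_factor, ge$events$bayes_factor, tolerance = 1e-6)
  expect_equal(classify_events(back)$regulation,
               classify_events(ge$events)$regulation)
})

test_that("isoform measurements reproduce true PSI within the noise model", {
  truth <- matrix(c(0, 25, 50, 75, 100, 33), 2, 3,
                  dimnames = list(c("e1", "e2"), c("s1", "s2", "s3")))
  cfg0 <- synth_config(seed = 41, psi_noise_sd = 0, psi_truth = truth)
  gm <- gen_isoform_measurements(cfg0)
  m <- build_psi_matrix(gm$measurements)
  expect_equal(m[rownames(truth), colnames(truth)], truth, tolerance = 1e-9)

  # noisy replicates: mean error within the CLT bound 3 * sd / sqrt(n)
  truth_rep <- matrix(60, 1, 50,
                      dimnames = list("e1", sprintf("rep%02d", 1:50)))
  cfg5 <- synth_config(seed = 42, psi_noise_sd = 5, psi_truth = truth_rep)
  m5 <- build_psi_matrix(gen_isoform_measurements(cfg5)$measurements)
  expect_lt(abs(mean(m5) - 60), 3 * 5 / sqrt(50))

  expect_error(gen_isoform_measurements(
    synth_config(seed = 43, psi_truth = truth * 2)), "0, 100")
})

test_that("planted PSI row groups come out contiguous after clustering", {
  cfg <- synth_config(seed = 55)          # default 10 x 6 two-group truth
  gm <- gen_isoform_measurements(cfg)
  cl <- cluster_psi_matrix(build_psi_matrix(gm$measurements))
  groups <- ifelse(gm$truth[cl$row_order, 1] > 50, "hi", "lo")
  expect_equal(length(rle(groups)$values), 2)  # two contiguous blocks
})

test_that("expression generator plants recoverable flags and caller overlaps", {
  cfg <- synth_config(seed = 61)
  gx <- gen_expression_table(cfg, n_genes = 300)
  out <- flag_expression_change(gx$records)
  expect_equal(out$flag, gx$truth$true_flag)
  expect_true(any(is.infinite(out$fold_change)))

  gl <- gen_caller_gene_lists(cfg, n_a = 120, n_b = 150, n_common = 80)
  common <- intersect_gene_sets(gl$set_a, gl$set_b)
  expect_equal(length(common), 80)
  expect_setequal(common, gl$common)
})
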