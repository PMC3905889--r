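make_events <- function(bf, len, psi_a = NA, psi_b = NA) {
  n <- length(bf)
  data.frame(
    event_id = sprintf("e%02d", seq_len(n)), gene = "g", chrom = "chr1",
    exon_start = 1000L, exon_end = 1000L + as.integer(len), strand = "+",
    event_class = "cassette", bayes_factor = bf,
    psi_stage_a = rep_len(psi_a, n), psi_stage_b = rep_len(psi_b, n),
    regulation = "unassigned", stringsAsFactors = FALSE)
}

test_that("event tables parse, validate rows, and normalise coordinates", {
  df <- data.frame(event_id = c("a", "b", "c"), chrom = "chr1",
                   start = c(100, 200, 300), end = c(150, 260, 360),
                   strand = "+", event_class = "cassette",
                   bayes_factor = c("12", "0.05", "1.2"),
                   stringsAsFactors = FALSE)
  ev <- parse_event_table(write_tsv_tmp(df))
  expect_equal(nrow(ev), 3)
  expect_equal(nrow(attr(ev, "bad_rows")), 0)
  expect_equal(ev$exon_start, c(100L, 200L, 300L))

  # bad Bayes factor is reported with its line number, not dropped silently
  df$bayes_factor[2] <- "NA"
  expect_message(ev <- parse_event_table(write_tsv_tmp(df)), "failed")
  expect_equal(nrow(ev), 2)
  bad <- attr(ev, "bad_rows")
  expect_equal(bad$line, 3L)  # header is line 1
  expect_match(bad$reason, "bayes_factor")

  # 1-based inclusive dialect: exon 100-150 stored as (99, 150)
  df$bayes_factor[2] <- "2"
  ev1 <- parse_event_table(write_tsv_tmp(df),
                           event_dialect(coordinates = "one_based_inclusive"))
  expect_equal(ev1$exon_start[1], 99L)
  expect_equal(ev1$exon_end[1], 150L)

  # missing mandatory column is a configuration error
  expect_error(parse_event_table(write_tsv_tmp(df[, -2])), "mandatory")
})

test_that("classification applies BF and length filters with strict cutoffs", {
  ev <- make_events(bf = c(15, 0.05, 12), len = c(100, 120, 600),
                    psi_a = c(20, NA, 20), psi_b = c(60, NA, 60))
  out <- classify_events(ev)
  expect_equal(out$regulation, c("activated", "background", "unassigned"))

  # between thresholds: everything unassigned
  mid <- classify_events(make_events(bf = rep(1, 4), len = 100))
  expect_true(all(mid$regulation == "unassigned"))

  # values exactly at a threshold stay unassigned (strict inequalities)
  edge <- classify_events(make_events(bf = c(10, 0.1), len = 100,
                                      psi_a = 10, psi_b = 90))
  expect_true(all(edge$regulation == "unassigned"))

  # regulated-tier event without stage PSIs warns and stays unassigned
  expect_warning(
    noPsi <- classify_events(make_events(bf = 50, len = 100)),
    "unassigned")
  expect_equal(noPsi$regulation, "unassigned")

  # PSI tie gives no direction
  tie <- suppressWarnings(
    classify_events(make_events(bf = 50, len = 100, psi_a = 40, psi_b = 40)))
  expect_equal(tie$regulation, "unassigned")

  # repressed direction
  dn <- classify_events(make_events(bf = 50, len = 100, psi_a = 80,
                                    psi_b = 30))
  expect_equal(dn$regulation, "repressed")
})

test_that("classification partition is disjoint, exhaustive and monotone in the BF cutoff", {
  set.seed(42)
  for (i in 1:20) {
    n <- 50
    ev <- make_events(bf = 10^stats::runif(n, -3, 3),
                      len = sample(c(50:550), n, replace = TRUE),
                      psi_a = stats::runif(n, 0, 100),
                      psi_b = stats::runif(n, 0, 100))
    out <- suppressWarnings(classify_events(ev))
    expect_true(all(out$regulation %in%
                      c("activated", "repressed", "background", "unassigned")))
    expect_equal(nrow(out), n)  # exhaustive, one label per event

    # raising bf_regulated never increases the regulated count
    n_reg <- function(cut) {
      o <- suppressWarnings(classify_events(ev, bf_regulated = cut))
      sum(o$regulation %in% c("activated", "repressed"))
    }
    counts <- vapply(c(2, 10, 50, 200), n_reg, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("PSI follows the inclusion/(inclusion+exclusion) formula", {
  expect_equal(compute_psi(50, 50), 50)
  expect_equal(compute_psi(0, 80), 0)
  expect_equal(compute_psi(75, 25), 75)
  expect_equal(compute_psi(3, 0), 100)     # exclusive isoform absent
  expect_true(is.na(compute_psi(0, 0)))    # no signal carries no PSI
  expect_error(compute_psi(-1, 5), "non-negative")
  x <- stats::runif(100, 0, 50)
  y <- stats::runif(100, 0, 50)
  psi <- compute_psi(x, y)
  expect_true(all(psi >= 0 & psi <= 100))
})

test_that("PSI matrices assemble from measurements with missing pairs as NA", {
  meas <- expand.grid(event_id = c("e1", "e2"),
                      sample = c("s1", "s2", "s3"),
                      stringsAsFactors = FALSE)
  meas$inclusion_signal <- c(10, 20, 30, 40, 50, 60)
  meas$exclusion_signal <- 10
  m <- build_psi_matrix(meas)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["e1", "s1"], compute_psi(10, 10))
  expect_false(anyNA(m))

  m2 <- build_psi_matrix(meas[-4, ])
  expect_true(is.na(m2["e2", "s2"]))
  expect_equal(sum(is.na(m2)), 1)

  expect_error(build_psi_matrix(rbind(meas, meas[1, ])), "duplicate")
})

test_that("PSI clustering is deterministic, permutation-invariant, and groups identical rows", {
  m <- rbind(e1 = c(90, 92, 10), e2 = c(90, 92, 10), e3 = c(5, 8, 95))
  colnames(m) <- c("s1", "s2", "s3")
  cl <- cluster_psi_matrix(m)
  ord <- cl$row_order
  expect_equal(abs(which(ord == "e1") - which(ord == "e2")), 1)

  # permuting the input rows/columns leaves the result unchanged
  cl2 <- cluster_psi_matrix(m[c(3, 1, 2), c(2, 3, 1)])
  expect_equal(cl2$row_order, cl$row_order)
  expect_equal(cl2$col_order, cl$col_order)
  expect_equal(cl2$values, cl$values)

  # degenerate matrices are returned unchanged with a notice
  expect_message(small <- cluster_psi_matrix(m[1, , drop = FALSE]),
                 "fewer than 2")
  expect_equal(small$row_order, "e1")

  # NA handling: drop removes the incomplete row; impute keeps it
  mna <- m; mna["e3", "s2"] <- NA
  dropped <- cluster_psi_matrix(mna, na_action = "drop")
  expect_false("e3" %in% rownames(dropped$values))
  imp <- cluster_psi_matrix(mna, na_action = "impute_mean")
  expect_equal(imp$values["e3", "s2"], mean(c(5, 95)))
})

test_that("expression fold changes are length-normalised and flagged", {
  rec <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    raw_count_a = c(10, 10, 0, 8),
                    raw_count_b = c(25, 15, 7, 2),
                    feature_length = 1000)
  out <- flag_expression_change(rec)
  expect_equal(out$fold_change, c(2.5, 1.5, Inf, 4))
  expect_equal(out$flag, c("up", "unchanged", "up", "down"))
  expect_equal(out$norm_b, c(25, 15, 7, 2) / 1000)
  expect_error(flag_expression_change(transform(rec, feature_length = 0)),
               "positive")

  # flagged set is monotone non-increasing in the threshold
  set.seed(7)
  big <- data.frame(gene = sprintf("g%03d", 1:200),
                    raw_count_a = sample(10:1000, 200, TRUE),
                    raw_count_b = sample(10:1000, 200, TRUE),
                    feature_length = sample(500:5000, 200, TRUE))
  flagged <- function(t) {
    o <- flag_expression_change(big, fold_threshold = t)
    o$gene[o$flag != "unchanged"]
  }
  sets <- lapply(c(1.5, 2, 3, 5), flagged)
  for (i in 2:length(sets)) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("gene-set intersection is exact and preserves first-list order", {
  expect_equal(intersect_gene_sets(c("a", "b", "c"), c("b", "c", "d")),
               c("b", "c"))
  expect_equal(intersect_gene_sets(c("a", "b"), c("x", "y")), character(0))
  expect_equal(intersect_gene_sets(c("c", "a", "b", "a"), c("a", "c")),
               c("c", "a"))
})
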