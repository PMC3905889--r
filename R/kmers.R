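#' Enumerate all k-mers over the RNA alphabet
#'
#' @param k word length.
#' @return character vector of the 4^k k-mers in lexicographic order.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  g <- do.call(expand.grid,
               c(rep(list(.RNA_BASES), k),
                 KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  sort(do.call(paste0, g[, rev(seq_len(k)), drop = FALSE]))
}

#' Count overlapping k-mers in one sequence
#'
#' Slides a window of width `k` with stride 1. Windows containing `N` are
#' skipped and do not count towards the window total, so frequencies are
#' always relative to informative windows only.
#'
#' @param seq RNA-sense sequence (T accepted, mapped to U).
#' @param k word length (default 5).
#' @return list with `counts` (named integer vector of observed k-mers) and
#'   `windows` (number of N-free windows counted).
#' @examples
#' count_kmers("AAAAAA", k = 5)  # AAAAA x2, windows 2
#' @export
count_kmers <- function(seq, k = 5) {
  stopifnot(k >= 1)
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n < k) return(list(counts = integer(0), windows = 0L))
  starts <- seq_len(n - k + 1)
  words <- substring(seq, starts, starts + k - 1)
  words <- words[!grepl("N", words, fixed = TRUE)]
  tab <- table(words)
  list(counts = stats::setNames(as.integer(tab), names(tab)),
       windows = length(words))
}

# Per-sequence k-mer count matrix over all 4^k words for a set of contexts;
# region "all" sums the three regions (words never span a region boundary).
.region_count_matrix <- function(contexts, region, k, kmers) {
  regions <- if (region == "all") {
    c("upstream_intron", "exon", "downstream_intron")
  } else region
  n <- nrow(contexts)
  counts <- matrix(0L, n, length(kmers), dimnames = list(NULL, kmers))
  windows <- integer(n)
  for (i in seq_len(n)) {
    for (rg in regions) {
      s <- contexts[[rg]][i]
      if (!nzchar(s)) next
      cnt <- count_kmers(s, k)
      windows[i] <- windows[i] + cnt$windows
      if (length(cnt$counts)) {
        counts[i, names(cnt$counts)] <- counts[i, names(cnt$counts)] +
          cnt$counts
      }
    }
  }
  list(counts = counts, windows = windows)
}

#' Background-controlled k-mer enrichment table
#'
#' Counts every k-mer in the chosen region of a test context set (activated
#' or repressed exons with their flanking introns) and of the shared
#' background set, normalises the counts to each data-set size (pooled
#' frequency over all counted windows), and ranks k-mers by their difference
#' to the background. Significance is assessed by a Welch two-sample t-test
#' comparing per-sequence k-mer frequencies between the two sets (two-sided);
#' when both per-sequence frequency samples are constant the statistic is
#' undefined and reported as `NA` with p = 1. A frequency ratio is reported
#' for reference but ranking always follows the difference.
#'
#' @param test_contexts,bg_contexts context data frames
#'   ([extract_context()] layout); both must contain at least one counted
#'   window in `region`.
#' @param region one of `"upstream_intron"`, `"exon"`,
#'   `"downstream_intron"`, or `"all"` (the three regions pooled, words never
#'   spanning a boundary).
#' @param k word length (default 5).
#' @param test_set label for the test set, `"activated"` or `"repressed"`.
#' @param p_adjust if `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column (off by default; the ranked list itself is not corrected).
#' @return data frame with one row per k-mer, sorted by `delta` descending
#'   (ties broken lexicographically): `kmer`, `region`, `test_set`,
#'   `count_test`, `count_bg`, `freq_test`, `freq_bg`, `delta`, `ratio`,
#'   `t_stat`, `p_value`, `rank` (dense over distinct `delta` values).
#' @export
enrichment_table <- function(test_contexts, bg_contexts,
                             region = c("downstream_intron",
                                        "upstream_intron", "exon", "all"),
                             k = 5,
                             test_set = c("activated", "repressed"),
                             p_adjust = FALSE) {
  region <- match.arg(region)
  test_set <- match.arg(test_set)
  if (!nrow(test_contexts) || !nrow(bg_contexts)) {
    stop_validation("both context sets must be non-empty")
  }
  kmers <- all_kmers(k)
  tm <- .region_count_matrix(test_contexts, region, k, kmers)
  bm <- .region_count_matrix(bg_contexts, region, k, kmers)
  if (sum(tm$windows) == 0 || sum(bm$windows) == 0) {
    stop_validation("a context set has no countable windows in region ", region)
  }

  count_test <- colSums(tm$counts)
  count_bg <- colSums(bm$counts)
  freq_test <- count_test / sum(tm$windows)
  freq_bg <- count_bg / sum(bm$windows)
  delta <- freq_test - freq_bg
  ratio <- ifelse(freq_bg > 0, freq_test / freq_bg,
                  ifelse(freq_test > 0, Inf, NA_real_))

  # per-sequence frequencies for the t-test; sequences without windows carry
  # no frequency and are excluded
  ft <- tm$counts[tm$windows > 0, , drop = FALSE] / tm$windows[tm$windows > 0]
  fb <- bm$counts[bm$windows > 0, , drop = FALSE] / bm$windows[bm$windows > 0]
  t_stat <- p_value <- numeric(length(kmers))
  for (j in seq_along(kmers)) {
    a <- ft[, j]; b <- fb[, j]
    va <- stats::var(a); vb <- stats::var(b)
    degenerate <- (is.na(va) || va == 0) && (is.na(vb) || vb == 0)
    tt <- if (degenerate) NULL else {
      tryCatch(stats::t.test(a, b), error = function(e) NULL)
    }
    if (is.null(tt)) {
      t_stat[j] <- NA_real_
      p_value[j] <- 1
    } else {
      t_stat[j] <- unname(tt$statistic)
      p_value[j] <- tt$p.value
    }
  }

  out <- data.frame(
    kmer = kmers, region = region, test_set = test_set,
    count_test = as.integer(count_test), count_bg = as.integer(count_bg),
    freq_test = unname(freq_test), freq_bg = unname(freq_bg),
    delta = unname(delta), ratio = unname(ratio),
    t_stat = t_stat, p_value = p_value,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$delta, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- match(out$delta, unique(out$delta))  # dense, delta descending
  if (p_adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Default heuristic k-mer to RNA-binding-protein map
#'
#' Pattern lists (regular expressions over the RNA alphabet; the IUPAC code
#' `Y` may be used for \[CU\]) linking motif families to the proteins that
#' plausibly read them: pyrimidine CU-rich elements to PTB, GAA-core purine
#' motifs to Tra2-beta, UAAA-like motifs to Sam68/T-STAR, UG repeats to CELF
#' and YGCY to MBNL. These labels are heuristic annotations only.
#'
#' @return named list: label -> character vector of patterns.
#' @export
default_motif_map <- function() {
  list(
    "PTB" = c("^[CU]*UCU[CU]*$", "^[CU]*CUC[CU]*$"),
    "Tra2beta" = c("GAA"),
    "Sam68/T-STAR" = c("UAAA", "AUAA"),
    "CELF" = c("UGUG", "GUGU"),
    "MBNL" = c("YGCY")
  )
}

#' Annotate enriched k-mers with candidate RNA-binding proteins
#'
#' Attaches a comma-separated label set to every k-mer matching any pattern
#' of the map. Purely heuristic; no statistics are altered.
#'
#' @param rows data frame from [enrichment_table()].
#' @param motif_map named list of pattern vectors, see
#'   [default_motif_map()].
#' @return `rows` with an `annotation` column (`NA` where nothing matches).
#' @export
annotate_kmers <- function(rows, motif_map = default_motif_map()) {
  if (!length(motif_map) || is.null(names(motif_map))) {
    stop("motif_map must be a non-empty named list (configuration error)",
         call. = FALSE)
  }
  compiled <- lapply(motif_map, function(pats) {
    vapply(pats, function(p) {
      p2 <- gsub("Y", "[CU]", p, fixed = TRUE)
      ok <- tryCatch({grepl(p2, "ACGU"); TRUE},
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) {
        stop("malformed pattern in motif_map: ", p, " (configuration error)",
             call. = FALSE)
      }
      p2
    }, "")
  })
  ann <- vapply(rows$kmer, function(km) {
    hits <- names(compiled)[vapply(compiled, function(pats) {
      any(vapply(pats, grepl, NA, x = km)) }, NA)]
    if (length(hits)) paste(hits, collapse = ",") else NA_character_
  }, "", USE.NAMES = FALSE)
  rows$annotation <- ann
  rows
}

#' Write an enrichment table to TSV
#'
#' @param rows data frame from [enrichment_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_enrichment_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
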