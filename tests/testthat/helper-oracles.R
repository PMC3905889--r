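# Independent oracles used by unit and acceptance tests. These deliberately
# use different mechanisms from the package implementation: the PTB oracle
# enumerates arrangements with fixed-length lookahead regular expressions,
# and the spike oracle computes the expected excess k-mer frequency in
# closed form under the i.i.d. base model.

# Enumerate PTB arrangements by regex. For each (s1, s2) pair an exact
# regular expression detects 0-mismatch starts; for a mismatch budget of 1,
# eight further variants each relax one specified position to ".". The
# mismatch count of a recovered (start, s1, s2) triple is 0 when the exact
# regex fires at that start, else 1.
oracle_scan_ptb <- function(seq, pattern) {
  seq <- chartr("T", "U", toupper(seq))
  n <- nchar(seq)
  stopifnot(pattern$max_mismatches <= 1)  # oracle supports budgets 0 and 1
  res <- list()
  for (s1 in pattern$spacer1_range[1]:pattern$spacer1_range[2]) {
    for (s2 in pattern$spacer2_range[1]:pattern$spacer2_range[2]) {
      if (8 + s1 + s2 > n) next
      parts <- c("[CU]", "C", "U", rep(".", s1), "C", "U", rep(".", s2),
                 "[CU]", "C", "U")
      spec_idx <- c(1, 2, 3, 3 + s1 + 1, 3 + s1 + 2,
                    5 + s1 + s2 + 1, 5 + s1 + s2 + 2, 5 + s1 + s2 + 3)
      find <- function(p) {
        m <- gregexpr(paste0("(?=", paste(p, collapse = ""), ")"), seq,
                      perl = TRUE)[[1]]
        if (m[1] == -1) integer(0) else as.integer(m) - 1L  # 0-based
      }
      exact <- find(parts)
      starts <- exact
      if (pattern$max_mismatches == 1) {
        for (i in spec_idx) {
          relaxed <- parts
          relaxed[i] <- "."
          starts <- union(starts, find(relaxed))
        }
      }
      if (length(starts)) {
        res[[length(res) + 1L]] <- data.frame(
          start = sort(starts), spacer1_len = s1, spacer2_len = s2,
          mismatch_count = as.integer(!(sort(starts) %in% exact)))
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), spacer1_len = integer(0),
                      spacer2_len = integer(0), mismatch_count = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$spacer1_len, out$spacer2_len), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical tuple form for set-equality comparison of scanner outputs
ptb_tuples <- function(df) {
  t <- df[, c("start", "spacer1_len", "spacer2_len", "mismatch_count")]
  t <- t[order(t$start, t$spacer1_len, t$spacer2_len), , drop = FALSE]
  rownames(t) <- NULL
  data.frame(lapply(t, as.integer))
}

# Expected excess count (per spiked sequence, relative to an unspiked one)
# of `motif` occurrences after planting one copy at a uniform position in an
# i.i.d. sequence of length L: exact enumeration over spike positions and
# overlapping windows.
spike_excess_expectation <- function(motif, L, comp = c(A = .25, C = .25,
                                                        G = .25, U = .25)) {
  m <- strsplit(motif, "")[[1]]
  k <- length(m)
  N <- L - k + 1
  stopifnot(N >= 1)
  p0 <- prod(comp[m])
  total <- 0
  for (j in seq_len(N)) {                 # spike start, 1-based
    s <- 1 - p0                           # window at the spike itself
    for (w in max(1, j - k + 1):min(N, j + k - 1)) {
      if (w == j) next
      p <- 1
      for (t in 0:(k - 1)) {
        pos <- w + t
        p <- p * if (pos >= j && pos <= j + k - 1) {
          as.numeric(m[pos - j + 1] == m[t + 1])
        } else comp[[m[t + 1]]]
      }
      s <- s + (p - p0)
    }
    total <- total + s
  }
  total / N
}

# random RNA sequence, optionally salted with N
random_rna <- function(len, n_rate = 0) {
  pool <- c("A", "C", "G", "U")
  s <- sample(pool, len, replace = TRUE)
  if (n_rate > 0) {
    idx <- which(stats::runif(len) < n_rate)
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

# small helper: write a data frame to a temp TSV and return the path
write_tsv_tmp <- function(df, ...) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  f
}
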