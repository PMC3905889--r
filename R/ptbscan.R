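#' PTB binding-site pattern
#'
#' PTB (polypyrimidine-tract-binding protein) engages RNA through several
#' RRM domains, each contacting a short pyrimidine element, with flexible
#' spacing between the contacts. The scanner models this as three specified
#' blocks — `YCU`, `CU`, `YCU` (`Y` = C or U; 8 specified nucleotides in
#' total) — separated by two spacers of variable length:
#' \describe{
#'   \item{high}{`YCU N(1-6) CU N(1-8) YCU`, no mismatches.}
#'   \item{low}{`YCU N(1-6) CU N(3-8) YCU`, a match required at only 7 of
#'     the 8 specified nucleotides (global budget of 1 mismatch). Note the
#'     second spacer range deliberately differs from the high-stringency
#'     preset; both are kept exactly as defined.}
#' }
#'
#' @param preset `"high"` or `"low"`.
#' @param spacer1_range,spacer2_range optional length-2 integer vectors
#'   overriding the preset spacer ranges (inclusive, nt).
#' @param max_mismatches optional override of the mismatch budget over the 8
#'   specified positions.
#' @return list of class `"ptb_pattern"` with elements `blocks`,
#'   `spacer1_range`, `spacer2_range`, `max_mismatches`, `tier`.
#' @export
ptb_pattern <- function(preset = c("high", "low"), spacer1_range = NULL,
                        spacer2_range = NULL, max_mismatches = NULL) {
  preset <- match.arg(preset)
  p <- if (preset == "high") {
    list(spacer1_range = c(1L, 6L), spacer2_range = c(1L, 8L),
         max_mismatches = 0L)
  } else {
    list(spacer1_range = c(1L, 6L), spacer2_range = c(3L, 8L),
         max_mismatches = 1L)
  }
  if (!is.null(spacer1_range)) p$spacer1_range <- as.integer(spacer1_range)
  if (!is.null(spacer2_range)) p$spacer2_range <- as.integer(spacer2_range)
  if (!is.null(max_mismatches)) p$max_mismatches <- as.integer(max_mismatches)
  if (p$spacer1_range[1] < 1 || p$spacer2_range[1] < 1 ||
      p$spacer1_range[2] < p$spacer1_range[1] ||
      p$spacer2_range[2] < p$spacer2_range[1] || p$max_mismatches < 0) {
    stop_validation("spacer ranges must be non-empty and positive; ",
                    "mismatch budget non-negative")
  }
  structure(c(list(blocks = c("YCU", "CU", "YCU")), p, list(tier = preset)),
            class = "ptb_pattern")
}

# specified-position offsets and wanted bases for one (s1, s2) arrangement;
# offsets are 0-based within the arrangement footprint
.ptb_spec <- function(s1, s2) {
  data.frame(
    offset = c(0L, 1L, 2L, 3L + s1, 4L + s1,
               5L + s1 + s2, 6L + s1 + s2, 7L + s1 + s2),
    want = c("Y", "C", "U", "C", "U", "Y", "C", "U"),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for combinatorial PTB binding-site arrangements
#'
#' Enumerates every distinct arrangement — a (start, spacer1, spacer2)
#' triple — whose specified positions mismatch the pattern at no more than
#' the pattern's budget. Each triple is one "binding possibility":
#' arrangements may overlap, and several arrangements can share a start.
#' `N` at a specified position always counts as a mismatch (never a free
#' match); `N` inside a spacer is allowed. Scanning is single-strand,
#' transcript-sense.
#'
#' @param seq RNA-sense sequence (T accepted and normalised to U).
#' @param pattern a [ptb_pattern()].
#' @return data frame sorted by (start, spacer1_len, spacer2_len) with
#'   columns `start`, `end` (0-based half-open), `spacer1_len`,
#'   `spacer2_len`, `mismatch_count`, `tier`; zero rows when nothing
#'   matches. Always `end - start == 8 + spacer1_len + spacer2_len`.
#' @export
scan_ptb <- function(seq, pattern = ptb_pattern("high")) {
  stopifnot(inherits(pattern, "ptb_pattern"))
  seq <- normalize_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- list()
  for (s1 in pattern$spacer1_range[1]:pattern$spacer1_range[2]) {
    for (s2 in pattern$spacer2_range[1]:pattern$spacer2_range[2]) {
      L <- 8L + s1 + s2
      if (L > n) next
      starts <- 0:(n - L)                       # 0-based
      spec <- .ptb_spec(s1, s2)
      mism <- integer(length(starts))
      for (i in seq_len(nrow(spec))) {
        got <- chars[starts + 1L + spec$offset[i]]
        ok <- if (spec$want[i] == "Y") got == "C" | got == "U"
              else got == spec$want[i]
        mism <- mism + !ok
      }
      keep <- mism <= pattern$max_mismatches
      if (any(keep)) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = starts[keep], end = starts[keep] + L,
          spacer1_len = s1, spacer2_len = s2,
          mismatch_count = mism[keep], tier = pattern$tier,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      spacer1_len = integer(0), spacer2_len = integer(0),
                      mismatch_count = integer(0), tier = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$spacer1_len, out$spacer2_len), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position binding-possibility profile
#'
#' Collapses a match list into a positional vector along the scanned
#' sequence: in `"starts"` mode, the number of arrangements starting at each
#' position (summing to the number of matches); in `"coverage"` mode (the
#' default, used for figure-like output), the number of arrangements whose
#' footprint covers each position.
#'
#' @param matches data frame from [scan_ptb()].
#' @param seq_len length of the scanned sequence (nt).
#' @param mode `"coverage"` or `"starts"`.
#' @return integer vector of length `seq_len`.
#' @export
ptb_profile <- function(matches, seq_len, mode = c("coverage", "starts")) {
  mode <- match.arg(mode)
  stopifnot(seq_len >= 0)
  if (nrow(matches) &&
      (any(matches$start < 0) || any(matches$end > seq_len))) {
    stop_validation("match outside [0, seq_len)")
  }
  v <- integer(seq_len)
  if (!nrow(matches)) return(v)
  if (mode == "starts") {
    t <- tabulate(matches$start + 1L, nbins = seq_len)
    return(as.integer(t))
  }
  # coverage via difference array
  d <- integer(seq_len + 1L)
  for (r in seq_len(nrow(matches))) {
    d[matches$start[r] + 1L] <- d[matches$start[r] + 1L] + 1L
    d[matches$end[r] + 1L] <- d[matches$end[r] + 1L] - 1L
  }
  as.integer(cumsum(d[seq_len(seq_len)]))
}

#' Scan an exon context for PTB arrangements, by region
#'
#' Scans the concatenation upstream + exon + downstream so that
#' arrangements spanning a region boundary are still found; each match is
#' labelled by the region its start falls in, and reported once.
#'
#' @param ctx one context: a one-row data frame (or list) with
#'   `upstream_intron`, `exon`, `downstream_intron`.
#' @param pattern a [ptb_pattern()].
#' @param profile_mode `"coverage"` or `"starts"`.
#' @return list with `matches` (as [scan_ptb()] plus a `region` column),
#'   `profile` (positional vector over the concatenated coordinates),
#'   `region_counts` (named integer vector), and `boundaries`
#'   (0-based starts of exon and downstream within the concatenation).
#' @export
scan_context <- function(ctx, pattern = ptb_pattern("high"),
                         profile_mode = c("coverage", "starts")) {
  profile_mode <- match.arg(profile_mode)
  up <- ctx$upstream_intron; ex <- ctx$exon; dn <- ctx$downstream_intron
  if (is.null(ex) || !nzchar(ex)) stop_validation("context exon is empty")
  if (is.null(up)) up <- ""
  if (is.null(dn)) dn <- ""
  full <- paste0(up, ex, dn)
  b_exon <- nchar(up)
  b_down <- b_exon + nchar(ex)
  m <- scan_ptb(full, pattern)
  region <- character(nrow(m))
  if (nrow(m)) {
    region <- ifelse(m$start < b_exon, "upstream_intron",
                     ifelse(m$start < b_down, "exon", "downstream_intron"))
  }
  m$region <- region
  counts <- c(upstream_intron = sum(region == "upstream_intron"),
              exon = sum(region == "exon"),
              downstream_intron = sum(region == "downstream_intron"))
  list(matches = m,
       profile = ptb_profile(m, nchar(full), mode = profile_mode),
       region_counts = counts,
       boundaries = c(exon = b_exon, downstream_intron = b_down))
}

#' Summarise PTB arrangements across a context set
#'
#' @param contexts context data frame ([extract_context()] layout).
#' @param pattern a [ptb_pattern()].
#' @return data frame with one row per context: `event_id`, per-region
#'   arrangement counts, and `n_total`.
#' @export
scan_context_set <- function(contexts, pattern = ptb_pattern("high")) {
  rows <- lapply(seq_len(nrow(contexts)), function(i) {
    sc <- scan_context(contexts[i, ], pattern)
    data.frame(event_id = contexts$event_id[i],
               n_upstream = unname(sc$region_counts["upstream_intron"]),
               n_exon = unname(sc$region_counts["exon"]),
               n_downstream = unname(sc$region_counts["downstream_intron"]),
               n_total = nrow(sc$matches),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
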