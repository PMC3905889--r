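#' Extract transcript-sense exon and flanking-intron sequences
#'
#' For each event, pulls the exon plus up to `flank_len` nt of intron on each
#' side out of the genome and returns all three pieces in transcript
#' orientation: for minus-strand events the genomic windows are mirrored and
#' every sequence reverse-complemented, so "upstream" is always 5' of the
#' exon in the pre-mRNA. DNA is converted to the RNA alphabet (T to U);
#' soft-masked lower-case bases are uppercased and retained. Flanks that run
#' off the chromosome end — or into a neighbouring exon when
#' `neighbor_bounds` is supplied — are truncated, never padded, and the
#' truncation is flagged.
#'
#' @param events data frame with columns `event_id`, `chrom`, `exon_start`,
#'   `exon_end` (0-based half-open), `strand`.
#' @param genome a named [Biostrings::DNAStringSet] or a path to a FASTA
#'   file; names are truncated at the first whitespace.
#' @param flank_len maximum intron flank length in nt (default 250).
#' @param neighbor_bounds optional data frame with columns `event_id`,
#'   `prev_exon_end`, `next_exon_start` (genomic 0-based coordinates of the
#'   adjacent exon edges); flanks are clipped so they do not reach into the
#'   neighbouring exons. `NA` bounds leave the corresponding side unclipped.
#' @return data frame with one row per event: `event_id`,
#'   `upstream_intron`, `exon`, `downstream_intron` (RNA-sense strings),
#'   `upstream_truncated`, `downstream_truncated` (logical), `flank_len`.
#' @export
extract_context <- function(events, genome, flank_len = 250,
                            neighbor_bounds = NULL) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  stopifnot(flank_len >= 0)

  nb_up <- nb_dn <- rep(NA_real_, nrow(events))
  if (!is.null(neighbor_bounds)) {
    i <- match(events$event_id, neighbor_bounds$event_id)
    nb_up <- neighbor_bounds$prev_exon_end[i]
    nb_dn <- neighbor_bounds$next_exon_start[i]
  }

  out <- vector("list", nrow(events))
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    if (!ev$chrom %in% names(genome)) {
      stop_validation("chromosome not in genome: ", ev$chrom,
                      " (event ", ev$event_id, ")")
    }
    chrom_seq <- genome[[ev$chrom]]
    clen <- length(chrom_seq)
    if (ev$exon_start < 0 || ev$exon_end > clen) {
      stop_validation("exon outside chromosome bounds for event ", ev$event_id)
    }
    if (ev$exon_end <= ev$exon_start) {
      stop_validation("exon_end must exceed exon_start for event ", ev$event_id)
    }
    # genomic windows, 0-based half-open
    left_lo <- max(0, ev$exon_start - flank_len,
                   if (!is.na(nb_up[r])) nb_up[r] else 0)
    right_hi <- min(clen, ev$exon_end + flank_len,
                    if (!is.na(nb_dn[r])) nb_dn[r] else clen)
    cut <- function(lo, hi) {
      if (hi <= lo) return("")
      toupper(as.character(Biostrings::subseq(chrom_seq, lo + 1, hi)))
    }
    left <- cut(left_lo, ev$exon_start)
    exon <- cut(ev$exon_start, ev$exon_end)
    right <- cut(ev$exon_end, right_hi)

    if (ev$strand == "+") {
      up <- left; dn <- right
    } else if (ev$strand == "-") {
      up <- revcomp_dna(right); dn <- revcomp_dna(left)
      exon <- revcomp_dna(exon)
    } else {
      stop_validation("invalid strand '", ev$strand, "' for event ", ev$event_id)
    }
    out[[r]] <- data.frame(
      event_id = ev$event_id,
      upstream_intron = dna_to_rna(up),
      exon = dna_to_rna(exon),
      downstream_intron = dna_to_rna(dn),
      upstream_truncated = nchar(up) < flank_len,
      downstream_truncated = nchar(dn) < flank_len,
      flank_len = flank_len,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Write a context set to FASTA
#'
#' Each context yields up to three records named `<event_id>|up`,
#' `<event_id>|exon`, `<event_id>|down`; empty (fully truncated) flanks are
#' skipped.
#'
#' @param contexts data frame from [extract_context()] or
#'   [gen_context_set()].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_contexts_fasta <- function(contexts, path) {
  seqs <- character(0)
  for (r in seq_len(nrow(contexts))) {
    cx <- contexts[r, ]
    rec <- c(up = cx$upstream_intron, exon = cx$exon,
             down = cx$downstream_intron)
    rec <- rec[nzchar(rec)]
    names(rec) <- paste(cx$event_id, names(rec), sep = "|")
    seqs <- c(seqs, rec)
  }
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Load pre-cut exon/flank regions from FASTA
#'
#' Accepts FASTA records named `<event_id>|<region>` with region one of
#' `up`, `exon`, `down`, and reassembles them into a context table. The exon
#' record is mandatory; a missing flank becomes an empty sequence with its
#' truncation flag set.
#'
#' @param path FASTA path.
#' @param flank_len nominal flank length used to set truncation flags
#'   (default 250).
#' @return data frame in the [extract_context()] layout.
#' @export
load_contexts_from_fasta <- function(path, flank_len = 250) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  parts <- strsplit(nm, "|", fixed = TRUE)
  bad <- lengths(parts) != 2 |
    !vapply(parts, function(p) p[length(p)], "") %in% c("up", "exon", "down")
  if (any(bad)) {
    stop_validation("malformed FASTA record name(s): ",
                    paste(utils::head(nm[bad], 3), collapse = ", "))
  }
  ev <- vapply(parts, `[`, "", 1)
  region <- vapply(parts, `[`, "", 2)
  key <- paste(ev, region)
  if (anyDuplicated(key)) {
    stop_validation("duplicate record(s): ",
                    paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  }
  seqs <- normalize_rna(as.character(x))
  ids <- unique(ev)
  grab <- function(id, reg) {
    i <- which(ev == id & region == reg)
    if (length(i)) seqs[i] else ""
  }
  out <- data.frame(
    event_id = ids,
    upstream_intron = vapply(ids, grab, "", reg = "up"),
    exon = vapply(ids, grab, "", reg = "exon"),
    downstream_intron = vapply(ids, grab, "", reg = "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(!nzchar(out$exon))) {
    stop_validation("exon record missing for event(s): ",
                    paste(utils::head(out$event_id[!nzchar(out$exon)], 3),
                          collapse = ", "))
  }
  out$upstream_truncated <- nchar(out$upstream_intron) < flank_len
  out$downstream_truncated <- nchar(out$downstream_intron) < flank_len
  out$flank_len <- flank_len
  out
}
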