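#' Default column dialect for splice-event tables
#'
#' A dialect maps the canonical field names used internally to the column
#' headers found in a particular file, and records the coordinate convention
#' of the file. The default matches the package's own TSV layout: 0-based
#' half-open coordinates (BED-style) and headers named after the fields.
#'
#' @param columns named character vector mapping canonical names
#'   (`event_id`, `gene`, `chrom`, `start`, `end`, `strand`, `event_class`,
#'   `bayes_factor`, `psi_stage_a`, `psi_stage_b`) to file headers.
#' @param coordinates `"bed"` for 0-based half-open input, or
#'   `"one_based_inclusive"` for 1-based fully-closed input (converted on
#'   parse so that everything downstream is 0-based half-open).
#' @return a list with elements `columns` and `coordinates`.
#' @export
event_dialect <- function(columns = NULL,
                          coordinates = c("bed", "one_based_inclusive")) {
  coordinates <- match.arg(coordinates)
  default <- c(event_id = "event_id", gene = "gene", chrom = "chrom",
               start = "start", end = "end", strand = "strand",
               event_class = "event_class", bayes_factor = "bayes_factor",
               psi_stage_a = "psi_6dpp", psi_stage_b = "psi_21dpp")
  if (!is.null(columns)) {
    unknown <- setdiff(names(columns), names(default))
    if (length(unknown)) {
      stop_validation("unknown dialect field(s): ", paste(unknown, collapse = ", "))
    }
    default[names(columns)] <- columns
  }
  list(columns = default, coordinates = coordinates)
}

.EVENT_CLASSES <- c("cassette", "alt5ss", "alt3ss", "mutually_exclusive",
                    "retained_intron", "unannotated")

#' Parse a splice-event table
#'
#' Reads a tab-delimited table of alternative-splicing events (one row per
#' event, e.g. a summarised MISO comparison), validates each row, and returns
#' the well-formed events with coordinates normalised to 0-based half-open.
#' Rows failing validation are collected with their line numbers and reasons
#' and attached as the `"bad_rows"` attribute — they are reported, never
#' silently dropped.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect column-map configuration from [event_dialect()].
#' @return a data frame of events with columns `event_id`, `gene`, `chrom`,
#'   `exon_start`, `exon_end`, `strand`, `event_class`, `bayes_factor`,
#'   `psi_stage_a`, `psi_stage_b`, `regulation` (initially `"unassigned"`);
#'   attribute `bad_rows` holds a data frame with `line` and `reason`.
#' @export
parse_event_table <- function(path, dialect = event_dialect()) {
  if (!file.exists(path)) stop_validation("event table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  cols <- dialect$columns
  mandatory <- c("event_id", "chrom", "start", "end", "strand",
                 "event_class", "bayes_factor")
  missing <- mandatory[!cols[mandatory] %in% names(raw)]
  if (length(missing)) {
    stop("mandatory column(s) not found in ", path, ": ",
         paste(cols[missing], collapse = ", "), " (configuration error)",
         call. = FALSE)
  }
  get_col <- function(field) {
    h <- cols[[field]]
    if (h %in% names(raw)) raw[[h]] else rep(NA_character_, nrow(raw))
  }

  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  start <- num(get_col("start"))
  end <- num(get_col("end"))
  bf <- num(get_col("bayes_factor"))
  strand <- get_col("strand")
  klass <- get_col("event_class")
  psi_a <- num(get_col("psi_stage_a"))
  psi_b <- num(get_col("psi_stage_b"))
  event_id <- get_col("event_id")
  psi_a_raw <- get_col("psi_stage_a")
  psi_b_raw <- get_col("psi_stage_b")

  reason <- character(n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond & !nzchar(reason), why, reason)
  }
  reason <- flag(!nzchar(event_id), "empty event_id")
  reason <- flag(is.na(start) | is.na(end) | start != floor(start) |
                   end != floor(end), "unparseable coordinates")
  reason <- flag(!strand %in% c("+", "-"), "invalid strand")
  reason <- flag(!klass %in% .EVENT_CLASSES, "unknown event_class")
  reason <- flag(is.na(bf) | bf < 0, "unparseable or negative bayes_factor")
  psi_bad <- (nzchar(psi_a_raw) & !is.na(psi_a_raw) & psi_a_raw != "NA" &
                (is.na(psi_a) | psi_a < 0 | psi_a > 100)) |
             (nzchar(psi_b_raw) & !is.na(psi_b_raw) & psi_b_raw != "NA" &
                (is.na(psi_b) | psi_b < 0 | psi_b > 100))
  reason <- flag(psi_bad, "PSI outside [0,100] or unparseable")

  if (dialect$coordinates == "one_based_inclusive") start <- start - 1
  reason <- flag(end <= start, "exon_end not greater than exon_start")

  ok <- !nzchar(reason)
  events <- data.frame(
    event_id = event_id[ok],
    gene = get_col("gene")[ok],
    chrom = get_col("chrom")[ok],
    exon_start = as.integer(start[ok]),
    exon_end = as.integer(end[ok]),
    strand = strand[ok],
    event_class = klass[ok],
    bayes_factor = bf[ok],
    psi_stage_a = psi_a[ok],
    psi_stage_b = psi_b[ok],
    regulation = "unassigned",
    stringsAsFactors = FALSE
  )
  bad <- data.frame(line = which(!ok) + 1L, reason = reason[!ok],
                    stringsAsFactors = FALSE)
  if (nrow(bad)) {
    message(nrow(bad), " row(s) failed validation in ", basename(path),
            "; see attr(, 'bad_rows')")
  }
  attr(events, "bad_rows") <- bad
  events
}

#' Partition splice events into regulated and background sets
#'
#' Applies the study's filtering rules: events whose exon exceeds
#' `max_exon_len` are excluded from both regulated and background sets
#' (`unassigned`); remaining events with Bayes factor strictly above
#' `bf_regulated` are split by PSI direction into `activated`
#' (stage-b inclusion higher than stage-a) and `repressed` (lower); events
#' with Bayes factor strictly below `bf_background` form the `background`
#' (expressed but not differentially spliced); everything else — including
#' events sitting exactly on a threshold, PSI ties, and regulated-tier events
#' missing a stage PSI — is `unassigned`. The partition is disjoint and
#' exhaustive.
#'
#' @param events data frame as returned by [parse_event_table()].
#' @param bf_regulated Bayes-factor cut-off for differential splicing
#'   (default 10, strict inequality).
#' @param bf_background Bayes-factor ceiling for the background set
#'   (default 0.1, strict inequality).
#' @param max_exon_len maximum exon length in nt retained in either set
#'   (default 500).
#' @return `events` with the `regulation` column filled in.
#' @export
classify_events <- function(events, bf_regulated = 10, bf_background = 0.1,
                            max_exon_len = 500) {
  stopifnot(is.data.frame(events))
  if (any(is.na(events$bayes_factor))) {
    stop_validation("every event must carry a Bayes factor")
  }
  len <- events$exon_end - events$exon_start
  reg <- rep("unassigned", nrow(events))
  len_ok <- len <= max_exon_len

  reg[len_ok & events$bayes_factor < bf_background] <- "background"

  hi <- len_ok & events$bayes_factor > bf_regulated
  have_psi <- !is.na(events$psi_stage_a) & !is.na(events$psi_stage_b)
  if (any(hi & !have_psi)) {
    warning(sum(hi & !have_psi), " regulated-tier event(s) lack stage PSIs; ",
            "left unassigned", call. = FALSE)
  }
  up <- hi & have_psi & events$psi_stage_b > events$psi_stage_a
  dn <- hi & have_psi & events$psi_stage_b < events$psi_stage_a
  reg[up] <- "activated"
  reg[dn] <- "repressed"

  events$regulation <- reg
  events
}

#' Write a splice-event table to TSV
#'
#' @param events event data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_event_table <- function(events, path) {
  out <- events
  names(out)[names(out) == "exon_start"] <- "start"
  names(out)[names(out) == "exon_end"] <- "end"
  names(out)[names(out) == "psi_stage_a"] <- "psi_6dpp"
  names(out)[names(out) == "psi_stage_b"] <- "psi_21dpp"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
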