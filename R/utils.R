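# Internal helpers shared across modules.

.RNA_BASES <- c("A", "C", "G", "U")

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U, and validates that only A, C, G, U, N remain.
#' Used at every sequence-facing entry point so downstream code can assume a
#' clean transcript-sense alphabet.
#'
#' @param x character vector of sequences (DNA or RNA, any case).
#' @return character vector over \{A,C,G,U,N\}.
#' @keywords internal
normalize_rna <- function(x) {
  x <- chartr("T", "U", toupper(x))
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("invalid characters after DNA/RNA normalisation in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  x
}

# Reverse complement of DNA strings (character in, character out).
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# Derive a sub-stream seed from the config seed; keeps the value a valid
# 32-bit integer so small user seeds plus fixed offsets never overflow.
stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

stop_validation <- function(...) stop(..., call. = FALSE)
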