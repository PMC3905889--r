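#' Flag fold changes in gene expression between two stages
#'
#' Raw counts are normalised by feature length (count per nt), mirroring
#' length normalisation of read counts over gene features, and the fold
#' change between the two stages is taken as the ratio of the larger to the
#' smaller normalised value. Genes whose fold change reaches the threshold
#' are flagged `up` (stage b higher) or `down` (stage b lower); a gene
#' detected at only one stage has an infinite fold change and is flagged by
#' the direction of its non-zero stage, never treated as an error. Genes
#' absent at both stages are `unchanged` with fold change 1.
#'
#' @param records data frame with columns `gene`, `raw_count_a`,
#'   `raw_count_b` (non-negative), `feature_length` (positive, nt).
#' @param fold_threshold minimum fold change to flag (default 2).
#' @return `records` with added columns `norm_a`, `norm_b` (counts per nt),
#'   `fold_change`, and `flag` in \{`up`, `down`, `unchanged`\}.
#' @export
flag_expression_change <- function(records, fold_threshold = 2) {
  req <- c("gene", "raw_count_a", "raw_count_b", "feature_length")
  if (!all(req %in% names(records))) {
    stop_validation("records need columns: ", paste(req, collapse = ", "))
  }
  if (any(records$feature_length <= 0)) {
    stop_validation("feature_length must be positive")
  }
  if (any(records$raw_count_a < 0) || any(records$raw_count_b < 0)) {
    stop_validation("raw counts must be non-negative")
  }
  records$norm_a <- records$raw_count_a / records$feature_length
  records$norm_b <- records$raw_count_b / records$feature_length
  hi <- pmax(records$norm_a, records$norm_b)
  lo <- pmin(records$norm_a, records$norm_b)
  fold <- hi / lo
  fold[hi == 0] <- 1          # absent at both stages
  records$fold_change <- fold
  flag <- rep("unchanged", nrow(records))
  flag[fold >= fold_threshold & records$norm_b > records$norm_a] <- "up"
  flag[fold >= fold_threshold & records$norm_b < records$norm_a] <- "down"
  records$flag <- flag
  records
}

#' Intersect two differentially-expressed gene lists
#'
#' The consensus differential-expression call is the exact set intersection
#' of the gene lists produced by two independent callers; the order of the
#' first list is preserved.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @return character vector of genes present in both lists, deduplicated, in
#'   `set_a` order.
#' @export
intersect_gene_sets <- function(set_a, set_b) {
  a <- unique(set_a)
  a[a %in% set_b]
}
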