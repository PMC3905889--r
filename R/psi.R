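#' Percent spliced in (PSI) from isoform signals
#'
#' PSI is the concentration of the isoform including the alternative event
#' divided by the summed concentrations of the including and excluding
#' isoforms, times 100. A measurement where both signals are zero carries no
#' information and yields `NA`.
#'
#' @param inclusion_signal,exclusion_signal non-negative numeric vectors
#'   (arbitrary but identical concentration units).
#' @return numeric vector of PSI percentages in \[0, 100\], `NA` where both
#'   signals are zero.
#' @examples
#' compute_psi(75, 25)  # 75
#' compute_psi(0, 80)   # 0
#' @export
compute_psi <- function(inclusion_signal, exclusion_signal) {
  if (any(inclusion_signal < 0, na.rm = TRUE) ||
      any(exclusion_signal < 0, na.rm = TRUE)) {
    stop_validation("isoform signals must be non-negative")
  }
  total <- inclusion_signal + exclusion_signal
  psi <- 100 * inclusion_signal / total
  psi[total == 0] <- NA_real_
  psi
}

#' Build an events-by-samples PSI matrix from isoform measurements
#'
#' @param measurements data frame with columns `event_id`, `sample`,
#'   `inclusion_signal`, `exclusion_signal`; (event, sample) pairs must be
#'   unique. Row/column order follows first appearance in the input.
#' @return numeric matrix (events x samples) of PSI percentages; pairs absent
#'   from the input are `NA`.
#' @export
build_psi_matrix <- function(measurements) {
  req <- c("event_id", "sample", "inclusion_signal", "exclusion_signal")
  if (!all(req %in% names(measurements))) {
    stop_validation("measurements need columns: ", paste(req, collapse = ", "))
  }
  key <- paste(measurements$event_id, measurements$sample, sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation("duplicate (event, sample) measurement(s): ",
                    paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
                          collapse = "; "))
  }
  events <- unique(measurements$event_id)
  samples <- unique(measurements$sample)
  m <- matrix(NA_real_, length(events), length(samples),
              dimnames = list(events, samples))
  psi <- compute_psi(measurements$inclusion_signal,
                     measurements$exclusion_signal)
  m[cbind(match(measurements$event_id, events),
          match(measurements$sample, samples))] <- psi
  m
}

#' Hierarchically cluster a PSI matrix
#'
#' Rows (events) and columns (samples/tissues) are clustered independently by
#' agglomerative hierarchical clustering with Euclidean distance and average
#' linkage. To make leaf order deterministic and invariant to the order in
#' which rows arrive, row and column names are sorted lexicographically
#' before distances are computed; ties in the dendrogram are thereby broken
#' by the first event id.
#'
#' Clustering requires a complete matrix. Missing cells are handled first,
#' per `na_action`: `"drop"` removes rows containing any `NA` (the default —
#' no imputation model is assumed), `"impute_mean"` replaces each `NA` by the
#' mean of the non-missing values in its row (that event's mean PSI).
#'
#' @param m numeric matrix from [build_psi_matrix()].
#' @param na_action `"drop"` or `"impute_mean"`.
#' @return a list of class `"psi_clustering"`: `values` (the complete matrix
#'   actually clustered, rows/cols in lexicographic order), `row_order` and
#'   `col_order` (dendrogram leaf orders as name vectors), `row_hclust`,
#'   `col_hclust` (or `NULL` when the matrix was too small to cluster).
#' @export
cluster_psi_matrix <- function(m, na_action = c("drop", "impute_mean")) {
  na_action <- match.arg(na_action)
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_validation("PSI matrix must carry event and sample names")
  }
  if (anyNA(m)) {
    if (na_action == "drop") {
      m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
    } else {
      rm_ <- rowMeans(m, na.rm = TRUE)
      idx <- which(is.na(m), arr.ind = TRUE)
      m[idx] <- rm_[idx[, 1]]
      if (anyNA(m)) stop_validation("row(s) entirely missing cannot be imputed")
    }
  }
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    message("PSI matrix has fewer than 2 rows or columns after NA handling; ",
            "returned unclustered")
    return(structure(list(values = m, row_order = rownames(m),
                          col_order = colnames(m),
                          row_hclust = NULL, col_hclust = NULL),
                     class = "psi_clustering"))
  }
  rh <- stats::hclust(stats::dist(m), method = "average")
  ch <- stats::hclust(stats::dist(t(m)), method = "average")
  structure(list(values = m,
                 row_order = rownames(m)[rh$order],
                 col_order = colnames(m)[ch$order],
                 row_hclust = rh, col_hclust = ch),
            class = "psi_clustering")
}

#' @export
print.psi_clustering <- function(x, ...) {
  cat("PSI clustering:", nrow(x$values), "events x", ncol(x$values),
      "samples\n")
  cat("row order:", paste(utils::head(x$row_order, 8), collapse = ", "),
      if (length(x$row_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Write a PSI matrix (and optional cluster orders) to TSV
#'
#' Missing cells are written as `NA`. When `x` is a `"psi_clustering"`
#' object and `orders_path` is given, the leaf orders are written as a
#' two-column sidecar TSV (`axis`, `id`, in leaf order).
#'
#' @param x numeric matrix or `"psi_clustering"` object.
#' @param path output TSV for the matrix.
#' @param orders_path optional output TSV for the cluster orders.
#' @return invisibly, `path`.
#' @export
write_psi_matrix <- function(x, path, orders_path = NULL) {
  m <- if (inherits(x, "psi_clustering")) x$values else x
  df <- data.frame(event_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(orders_path)) {
    if (!inherits(x, "psi_clustering")) {
      stop_validation("orders_path requires a psi_clustering object")
    }
    ord <- rbind(
      data.frame(axis = "row", id = x$row_order, stringsAsFactors = FALSE),
      data.frame(axis = "col", id = x$col_order, stringsAsFactors = FALSE))
    utils::write.table(ord, orders_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
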