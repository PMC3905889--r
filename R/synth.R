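#' Configuration for the synthetic-data generator
#'
#' Captures the study conditions the generator emulates: 159 activated, 92
#' repressed and 276 background cassette-exon contexts (exon plus up to
#' 250 nt of flanking intron), a handful of over-length decoy exons removed
#' by the length filter, Bayes-factor distributions strictly clear of the
#' 10 / 0.1 classification thresholds, and isoform signals with known true
#' PSI plus Gaussian noise on the inclusion fraction.
#'
#' @param seed mandatory integer seed; one global seed drives independent
#'   per-stream sub-generators (contexts, events, measurements, expression)
#'   so each artifact can be regenerated on its own.
#' @param n_activated,n_repressed,n_background set sizes (defaults 159, 92,
#'   276).
#' @param n_long_decoys number of regulated-tier events with exons longer
#'   than the 500 nt filter (default 9); these must end up unassigned.
#' @param exon_len_range inclusive exon length range in nt (default
#'   60-300, cassette-exon scale, safely below the length filter).
#' @param decoy_len_range exon length range for decoys (default 501-800).
#' @param flank_len flanking-intron length in nt (default 250).
#' @param base_composition named probability vector over A, C, G, U
#'   (default uniform).
#' @param spikes list of motif spikes, each a list with elements `motif`
#'   (string over A/C/G/U), `set` (`"activated"`, `"repressed"` or
#'   `"background"`), `region` (`"upstream_intron"`, `"exon"`,
#'   `"downstream_intron"`), `rate` (per-sequence probability) and `copies`
#'   (default 1).
#' @param bf_regulated_range,bf_background_range Bayes factors are drawn
#'   log-uniformly from these ranges; they must be strictly clear of the
#'   10 and 0.1 thresholds (defaults \[12, 1000\] and \[0.001, 0.08\]).
#' @param psi_noise_sd standard deviation of the Gaussian noise on the
#'   inclusion fraction, in PSI percent (default 5).
#' @param psi_truth optional events-by-samples matrix of true PSI percents
#'   for [gen_isoform_measurements()]; a planted two-group 10 x 6 matrix is
#'   used when omitted.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(seed,
                         n_activated = 159, n_repressed = 92,
                         n_background = 276, n_long_decoys = 9,
                         exon_len_range = c(60, 300),
                         decoy_len_range = c(501, 800),
                         flank_len = 250,
                         base_composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, U = 0.25),
                         spikes = list(),
                         bf_regulated_range = c(12, 1000),
                         bf_background_range = c(0.001, 0.08),
                         psi_noise_sd = 5,
                         psi_truth = NULL) {
  if (missing(seed)) stop_validation("seed is mandatory")
  if (abs(sum(base_composition) - 1) > 1e-9 ||
      !setequal(names(base_composition), .RNA_BASES)) {
    stop_validation("base_composition must be named over A,C,G,U and sum to 1")
  }
  if (bf_regulated_range[1] <= 10) {
    stop_validation("bf_regulated_range must stay strictly above 10")
  }
  if (bf_background_range[2] >= 0.1 || bf_background_range[1] <= 0) {
    stop_validation("bf_background_range must stay strictly inside (0, 0.1)")
  }
  if (psi_noise_sd < 0) stop_validation("psi_noise_sd must be non-negative")
  for (sp in spikes) {
    if (grepl("[^ACGU]", sp$motif)) {
      stop_validation("spike motifs must be over A,C,G,U: ", sp$motif)
    }
    if (!sp$set %in% c("activated", "repressed", "background") ||
        !sp$region %in% c("upstream_intron", "exon", "downstream_intron")) {
      stop_validation("spike set/region invalid for motif ", sp$motif)
    }
  }
  structure(list(
    seed = as.integer(seed), n_activated = n_activated,
    n_repressed = n_repressed, n_background = n_background,
    n_long_decoys = n_long_decoys, exon_len_range = exon_len_range,
    decoy_len_range = decoy_len_range, flank_len = flank_len,
    base_composition = base_composition[.RNA_BASES], spikes = spikes,
    bf_regulated_range = bf_regulated_range,
    bf_background_range = bf_background_range,
    psi_noise_sd = psi_noise_sd, psi_truth = psi_truth
  ), class = "synth_config")
}

.rand_seq <- function(len, comp) {
  if (len <= 0) return("")
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

# Replace bases with a motif at a random position in `seq`, avoiding the
# already-occupied intervals (0-based [start, end) pairs in `occupied`).
# Returns list(seq, offset) or raises after `tries` rejections.
.spike_once <- function(seq, motif, occupied, tries = 100) {
  L <- nchar(seq); k <- nchar(motif)
  if (k > L) stop_validation("spike motif longer than target region")
  for (t in seq_len(tries)) {
    off <- sample.int(L - k + 1L, 1L) - 1L      # 0-based
    clash <- any(vapply(occupied, function(iv) {
      off < iv[2] && iv[1] < off + k }, NA))
    if (!clash) {
      substr(seq, off + 1L, off + k) <- motif
      return(list(seq = seq, offset = off))
    }
  }
  stop("spike rejection bound exceeded; region too crowded (generation error)",
       call. = FALSE)
}

#' Generate synthetic exon-context sets with planted motifs
#'
#' Draws i.i.d. bases from the configured composition for every exon and
#' flank, then plants the configured motif spikes at uniform random,
#' non-overlapping positions (replacing bases, so sequence length and the
#' number of k-mer windows are unchanged). Every inserted motif instance is
#' recorded in the truth table. The same seed and config reproduce the
#' output exactly.
#'
#' @param cfg a [synth_config()].
#' @return list with `activated`, `repressed`, `background` context data
#'   frames ([extract_context()] layout) and `truth`, a data frame of
#'   planted instances (`set`, `event_id`, `region`, `offset` 0-based,
#'   `motif`).
#' @export
gen_context_set <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stream_seed(cfg$seed, 101))
  comp <- cfg$base_composition
  sizes <- c(activated = cfg$n_activated, repressed = cfg$n_repressed,
             background = cfg$n_background)
  prefix <- c(activated = "act", repressed = "rep", background = "bg")
  out <- list()
  truth <- list()
  for (nm in names(sizes)) {
    n <- sizes[[nm]]
    exon_len <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], n,
                       replace = TRUE)
    ctx <- data.frame(
      event_id = sprintf("%s_%04d", prefix[[nm]], seq_len(n)),
      upstream_intron = vapply(rep(cfg$flank_len, n), .rand_seq, "",
                               comp = comp),
      exon = vapply(exon_len, .rand_seq, "", comp = comp),
      downstream_intron = vapply(rep(cfg$flank_len, n), .rand_seq, "",
                                 comp = comp),
      upstream_truncated = FALSE, downstream_truncated = FALSE,
      flank_len = cfg$flank_len, stringsAsFactors = FALSE)

    for (sp in cfg$spikes) {
      if (sp$set != nm) next
      copies <- if (is.null(sp$copies)) 1L else sp$copies
      for (i in seq_len(n)) {
        if (stats::runif(1) >= sp$rate) next
        occupied <- list()
        for (cp in seq_len(copies)) {
          res <- .spike_once(ctx[[sp$region]][i], sp$motif, occupied)
          ctx[[sp$region]][i] <- res$seq
          occupied[[length(occupied) + 1L]] <- c(res$offset,
                                                 res$offset + nchar(sp$motif))
          truth[[length(truth) + 1L]] <- data.frame(
            set = nm, event_id = ctx$event_id[i], region = sp$region,
            offset = res$offset, motif = sp$motif, stringsAsFactors = FALSE)
        }
      }
    }
    out[[nm]] <- ctx
  }
  out$truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(set = character(0), event_id = character(0),
               region = character(0), offset = integer(0),
               motif = character(0), stringsAsFactors = FALSE)
  }
  out
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]),
                                                  log(range[2])))

#' Generate a synthetic splice-event table with known partition
#'
#' Regulated events carry Bayes factors drawn strictly above the
#' classification threshold and exons shorter than the length filter;
#' background events carry Bayes factors strictly below the background
#' ceiling; decoys are regulated-tier events with over-length exons, which
#' the classifier must leave unassigned. Stage PSIs are drawn so that
#' activated events strictly gain inclusion and repressed events strictly
#' lose it. Rows are shuffled so recovery cannot rely on input order.
#'
#' @param cfg a [synth_config()].
#' @return list with `events` (parse-ready data frame, `regulation`
#'   unassigned) and `truth` (`event_id`, `true_class` in activated /
#'   repressed / background / decoy).
#' @export
gen_event_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stream_seed(cfg$seed, 202))
  n_act <- cfg$n_activated; n_rep <- cfg$n_repressed
  n_bg <- cfg$n_background; n_dec <- cfg$n_long_decoys
  n <- n_act + n_rep + n_bg + n_dec
  true_class <- rep(c("activated", "repressed", "background", "decoy"),
                    c(n_act, n_rep, n_bg, n_dec))
  len <- integer(n)
  reg <- true_class != "decoy"
  len[reg] <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2],
                     sum(reg), replace = TRUE)
  len[!reg] <- sample(cfg$decoy_len_range[1]:cfg$decoy_len_range[2],
                      sum(!reg), replace = TRUE)
  bf <- numeric(n)
  hi <- true_class %in% c("activated", "repressed", "decoy")
  bf[hi] <- .runif_log(sum(hi), cfg$bf_regulated_range)
  bf[!hi] <- .runif_log(sum(!hi), cfg$bf_background_range)

  psi_a <- psi_b <- numeric(n)
  is_act <- true_class == "activated"
  is_rep <- true_class == "repressed"
  psi_a[is_act] <- stats::runif(sum(is_act), 5, 55)
  psi_b[is_act] <- psi_a[is_act] + stats::runif(sum(is_act), 10, 40)
  psi_a[is_rep] <- stats::runif(sum(is_rep), 45, 95)
  psi_b[is_rep] <- psi_a[is_rep] - stats::runif(sum(is_rep), 10, 40)
  rest <- !(is_act | is_rep)
  psi_a[rest] <- stats::runif(sum(rest), 10, 90)
  psi_b[rest] <- pmin(100, pmax(0, psi_a[rest] +
                                  stats::rnorm(sum(rest), 0, 2)))

  # tile events along one synthetic chromosome, far enough apart that
  # contexts never overlap
  gap <- cfg$flank_len * 2 + 100
  start <- cumsum(c(1000, utils::head(len, -1) + gap))
  ev <- data.frame(
    event_id = sprintf("ev_%04d", seq_len(n)),
    gene = sprintf("gene_%04d", seq_len(n)),
    chrom = "chrS",
    exon_start = start,
    exon_end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    event_class = "cassette",
    bayes_factor = bf,
    psi_stage_a = round(psi_a, 2),
    psi_stage_b = round(psi_b, 2),
    regulation = "unassigned",
    stringsAsFactors = FALSE)
  ord <- sample.int(n)
  list(events = ev[ord, , drop = FALSE],
       truth = data.frame(event_id = ev$event_id[ord],
                          true_class = true_class[ord],
                          stringsAsFactors = FALSE))
}

# default planted two-group PSI truth: 10 events x 6 samples
.default_psi_truth <- function() {
  base_hi <- c(88, 90, 85, 12, 10, 15)
  base_lo <- c(12, 10, 15, 88, 90, 85)
  m <- rbind(
    t(vapply(1:5, function(i) base_hi + (i - 3), numeric(6))),
    t(vapply(1:5, function(i) base_lo + (i - 3), numeric(6))))
  dimnames(m) <- list(sprintf("ev_%02d", 1:10), sprintf("tissue_%d", 1:6))
  m
}

#' Generate isoform measurements with known true PSI
#'
#' For every (event, sample) cell of the truth matrix, draws a total signal
#' and splits it between inclusion and exclusion isoforms so that the
#' expected PSI equals the truth: Gaussian noise with sd `psi_noise_sd`/100
#' is added to the inclusion fraction and truncated to \[0, 1\]. With zero
#' noise the PSI formula recovers the truth exactly.
#'
#' @param cfg a [synth_config()]; `cfg$psi_truth` may supply the truth
#'   matrix (percent, events x samples, dimnames required).
#' @return list with `measurements` (data frame `event_id`, `sample`,
#'   `inclusion_signal`, `exclusion_signal`) and `truth` (the PSI matrix).
#' @export
gen_isoform_measurements <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stream_seed(cfg$seed, 303))
  truth <- if (is.null(cfg$psi_truth)) .default_psi_truth() else cfg$psi_truth
  if (any(truth < 0 | truth > 100)) {
    stop_validation("psi_truth must lie in [0, 100]")
  }
  ev <- rep(rownames(truth), times = ncol(truth))
  sm <- rep(colnames(truth), each = nrow(truth))
  frac <- as.vector(truth) / 100
  nn <- length(frac)
  frac_obs <- pmin(1, pmax(0, frac + stats::rnorm(nn, 0,
                                                  cfg$psi_noise_sd / 100)))
  total <- stats::runif(nn, 50, 150)
  meas <- data.frame(event_id = ev, sample = sm,
                     inclusion_signal = frac_obs * total,
                     exclusion_signal = (1 - frac_obs) * total,
                     stringsAsFactors = FALSE)
  list(measurements = meas, truth = truth)
}

#' Generate synthetic per-gene expression records with known flags
#'
#' Plants genes whose length-normalised expression changes by at least the
#' configured fold range between the two stages (up or down), a few genes
#' detected at one stage only (infinite fold change), and a majority of
#' unchanged genes (fold below 1.5). Raw counts are large enough that
#' integer rounding cannot move a gene across the 2-fold boundary.
#'
#' @param cfg a [synth_config()].
#' @param n_genes total genes (default 1000).
#' @param frac_up,frac_down fractions of truly up-/down-regulated genes
#'   (defaults 0.08 each).
#' @param n_infinite genes expressed at exactly one stage (default 4, split
#'   between directions).
#' @param fold_range true fold-change range for regulated genes (default
#'   2.5-8).
#' @return list with `records` (data frame `gene`, `raw_count_a`,
#'   `raw_count_b`, `feature_length`) and `truth` (`gene`, `true_flag`).
#' @export
gen_expression_table <- function(cfg, n_genes = 1000, frac_up = 0.08,
                                 frac_down = 0.08, n_infinite = 4,
                                 fold_range = c(2.5, 8)) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stream_seed(cfg$seed, 404))
  n_up <- round(n_genes * frac_up)
  n_dn <- round(n_genes * frac_down)
  n_inf_up <- ceiling(n_infinite / 2)
  n_inf_dn <- n_infinite - n_inf_up
  n_flat <- n_genes - n_up - n_dn - n_infinite
  stopifnot(n_flat > 0)
  true_flag <- rep(c("up", "down", "up", "down", "unchanged"),
                   c(n_up, n_dn, n_inf_up, n_inf_dn, n_flat))
  length_ <- sample(500:5000, n_genes, replace = TRUE)
  a <- sample(50:5000, n_genes, replace = TRUE)
  fold <- stats::runif(n_genes, fold_range[1], fold_range[2])
  b <- numeric(n_genes)
  i <- seq_len(n_up)
  b[i] <- round(a[i] * fold[i])
  i <- n_up + seq_len(n_dn)
  b[i] <- pmax(1, round(a[i] / fold[i]))
  i <- n_up + n_dn + seq_len(n_inf_up)
  a[i] <- 0; b[i] <- sample(50:500, n_inf_up, replace = TRUE)
  i <- n_up + n_dn + n_inf_up + seq_len(n_inf_dn)
  b[i] <- 0
  i <- n_up + n_dn + n_infinite + seq_len(n_flat)
  b[i] <- pmax(1, round(a[i] * stats::runif(n_flat, 0.75, 1.35)))
  ord <- sample.int(n_genes)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  list(records = data.frame(gene = genes[ord], raw_count_a = a[ord],
                            raw_count_b = as.numeric(b)[ord],
                            feature_length = length_[ord],
                            stringsAsFactors = FALSE),
       truth = data.frame(gene = genes[ord], true_flag = true_flag[ord],
                          stringsAsFactors = FALSE))
}

#' Generate two overlapping differential-expression caller gene lists
#'
#' Emulates two callers that agree on a planted common core: list sizes and
#' overlap are configurable and default to 5835, 6362 and 5296.
#'
#' @param cfg a [synth_config()].
#' @param n_a,n_b list sizes; `n_common` planted shared genes.
#' @return list with `set_a`, `set_b` (shuffled character vectors) and
#'   `common` (the planted intersection).
#' @export
gen_caller_gene_lists <- function(cfg, n_a = 5835, n_b = 6362,
                                  n_common = 5296) {
  stopifnot(inherits(cfg, "synth_config"))
  stopifnot(n_common <= n_a, n_common <= n_b)
  set.seed(stream_seed(cfg$seed, 505))
  n_total <- n_a + n_b - n_common
  genes <- sprintf("g%06d", sample.int(10 * n_total, n_total))
  common <- genes[seq_len(n_common)]
  only_a <- genes[n_common + seq_len(n_a - n_common)]
  only_b <- genes[n_common + (n_a - n_common) + seq_len(n_b - n_common)]
  list(set_a = sample(c(common, only_a)),
       set_b = sample(c(common, only_b)),
       common = common)
}
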