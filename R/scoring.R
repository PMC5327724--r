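#' Count aligned M-words in a selection-round pool
#'
#' Deduplicates identical oligonucleotides (each counted once, to remove
#' PCR duplicates), scans every retained read with [scan_pool()] and tallies
#' the extracted M-words (core plus `flank_len` bases each side, in motif
#' orientation).
#'
#' @param pool [read_pool()] object or character vector of reads.
#' @param motif IUPAC string or [core_motif()] object.
#' @param flank_len Flank length per side.
#' @param dedupe Count each distinct oligonucleotide once (default TRUE).
#' @return data.frame with columns `mword`, `count`, sorted lexicographically
#'   by `mword`; attribute `scan_summary` tabulates read fates.
#' @export
count_mwords <- function(pool, motif, flank_len, dedupe = TRUE) {
  reads <- if (inherits(pool, "read_pool")) pool$reads else toupper(pool)
  if (dedupe) reads <- unique(reads)
  sc <- scan_pool(reads, motif, flank_len)
  tab <- table(sc$mword[sc$status == "hit"])
  out <- data.frame(mword = names(tab), count = as.numeric(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mword), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scan_summary") <- table(sc$status)
  out
}

#' Aligned M-word dataset with enrichment scores
#'
#' Container for one (TF, round, flank length) combination: the aligned
#' M-words with their counts, round-i frequencies, estimated initial-pool
#' frequencies and enrichment scores.
#'
#' @param records data.frame with columns `mword`, `count`, `freq`,
#'   `est_freq0`, `score`.
#' @param core [core_motif()] object (or IUPAC string).
#' @param flank_len Flank length per side.
#' @param round_index Selection round the counts come from.
#' @param tf_name Optional TF label.
#' @return Object of class `mword_dataset`.
#' @export
mword_dataset <- function(records, core, flank_len, round_index,
                          tf_name = NA_character_) {
  core <- .as_core_motif(core)
  need <- c("mword", "count", "freq", "est_freq0", "score")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  structure(list(records = records, core = core,
                 flank_len = as.integer(flank_len),
                 M = core$literal_length + 2L * as.integer(flank_len),
                 round_index = as.integer(round_index),
                 tf_name = tf_name),
            class = "mword_dataset")
}

#' @export
print.mword_dataset <- function(x, ...) {
  cat("M-word dataset", if (!is.na(x$tf_name)) paste0(" [", x$tf_name, "]"),
      ": core ", x$core$symbols, ", flank ", x$flank_len,
      " (M = ", x$M, "), round ", x$round_index, "\n",
      "  ", nrow(x$records), " distinct M-words, max count ",
      if (nrow(x$records)) max(x$records$count) else 0, "\n", sep = "")
  invisible(x)
}

#' @export
summary.mword_dataset <- function(object, ...) {
  r <- object$records
  out <- list(n_words = nrow(r),
              max_count = if (nrow(r)) max(r$count) else 0,
              score_range = if (nrow(r)) range(r$score) else c(NA, NA),
              score_spread_90_10 = if (nrow(r))
                diff(stats::quantile(r$score, c(.1, .9), names = FALSE)) else NA)
  class(out) <- "summary.mword_dataset"
  out
}

#' @export
print.summary.mword_dataset <- function(x, ...) {
  cat("M-words: ", x$n_words, "; max count ", x$max_count,
      "; p90-p10 score spread ", format(x$score_spread_90_10), "\n", sep = "")
  invisible(x)
}

#' Enrichment scores for counted M-words
#'
#' The score of M-word w observed in selection round i is
#' `(freq_i(w) / est_freq_0(w))^(1/i)`: the i-th root of its frequency
#' enrichment over the (estimated) initial pool, so that under geometric
#' per-round enrichment the score is proportional to relative binding
#' affinity.
#'
#' @param counts data.frame from [count_mwords()] (columns `mword`, `count`).
#' @param background A [fit_markov()] model, or a named numeric vector of
#'   initial-pool frequencies indexed by M-word (e.g. exact simulator
#'   frequencies).
#' @param round_index Selection round i the counts were observed in.
#' @param core,flank_len,tf_name Dataset metadata, stored in the result.
#' @param min_round Scores are only considered meaningful from this round
#'   on (default 3); earlier rounds raise an error.
#' @return An [mword_dataset()].
#' @export
score_mwords <- function(counts, background, round_index, core, flank_len,
                         tf_name = NA_character_, min_round = 3) {
  i <- round_index
  if (i < min_round)
    stop("scores are derived for rounds >= ", min_round,
         " (got round ", i, "); lower min_round to override")
  if (nrow(counts) == 0) stop("no counted M-words")
  freq <- counts$count / sum(counts$count)
  if (inherits(background, "markov_bg")) {
    est0 <- estimate_freq0(counts$mword, background)
  } else {
    est0 <- unname(background[counts$mword])
    if (anyNA(est0)) stop("background vector missing some M-words")
  }
  if (any(est0 <= 0))
    stop("estimated initial frequency is zero for some M-words; ",
         "use a positive pseudocount in fit_markov()")
  rec <- data.frame(mword = counts$mword, count = counts$count,
                    freq = freq, est_freq0 = est0,
                    score = (freq / est0)^(1 / i),
                    stringsAsFactors = FALSE)
  mword_dataset(rec, core, flank_len, i, tf_name)
}

#' Initial flank length for a core motif
#'
#' `max(0, floor((10 - core_literal_length) / 2))`, so that M is at least
#' 10 and DNA shape can be predicted for at least 6 positions.
#'
#' @param core_literal_length Literal (character-count) core length.
#' @return Integer flank length per side.
#' @export
initial_flank_length <- function(core_literal_length) {
  if (core_literal_length < 1) stop("core length must be >= 1")
  max(0L, as.integer(floor((10 - core_literal_length) / 2)))
}

#' Per-flank count summaries for a round pool
#'
#' @param pool Selection-round pool.
#' @param motif Core motif.
#' @param flanks Integer vector of flank lengths to summarize.
#' @param reliable_count Count above which an M-word is called reliable
#'   (default > 8).
#' @return data.frame with `flank`, `n_words`, `n_reliable`, `max_count`.
#' @export
flank_summaries <- function(pool, motif, flanks, reliable_count = 8) {
  rows <- lapply(flanks, function(fl) {
    ct <- count_mwords(pool, motif, fl)
    data.frame(flank = fl, n_words = nrow(ct),
               n_reliable = sum(ct$count > reliable_count),
               max_count = if (nrow(ct)) max(ct$count) else 0)
  })
  do.call(rbind, rows)
}

#' Maximum usable flank length
#'
#' The largest flank length whose dataset has at least `min_reliable`
#' M-words with count above `reliable_count` and a maximum M-word count of
#' at least `min_max_count`. Datasets should then be emitted for every
#' flank length from the initial up to this maximum.
#'
#' @param summaries data.frame from [flank_summaries()].
#' @param min_reliable Minimum number of reliable M-words (default 1000).
#' @param reliable_count Unused here (the summaries already encode it);
#'   kept for interface symmetry.
#' @param min_max_count Minimum maximum M-word count (default 100).
#' @return Largest qualifying flank length, or an `insufficient_depth`
#'   error if none qualifies.
#' @export
max_flank_length <- function(summaries, min_reliable = 1000,
                             reliable_count = 8, min_max_count = 100) {
  ok <- summaries$n_reliable >= min_reliable &
    summaries$max_count >= min_max_count
  if (!any(ok))
    stop("insufficient_depth: no flank length has >= ", min_reliable,
         " reliable M-words with max count >= ", min_max_count)
  max(summaries$flank[ok])
}

#' Build scored M-word datasets for one experiment
#'
#' Runs the full per-round scoring pipeline: fits the Markov background on
#' the round-0 pool, determines the initial and maximum flank lengths from
#' the chosen round's counts, and emits one scored [mword_dataset()] per
#' (round, flank length) combination.
#'
#' @param pools Named list of [read_pool()] objects; must include round 0.
#' @param motif Core motif (IUPAC string or [core_motif()]).
#' @param rounds Selection rounds to score (default: all pool rounds
#'   >= `min_round`).
#' @param order,pseudocount Markov background parameters.
#' @param min_round Earliest scorable round (default 3).
#' @param tf_name Optional TF label.
#' @param min_reliable,reliable_count,min_max_count Depth thresholds for
#'   the maximum flank length rule.
#' @return List of `mword_dataset` objects named `"round<i>_flank<f>"`.
#' @export
build_mword_datasets <- function(pools, motif, rounds = NULL,
                                 order = 5, pseudocount = 1, min_round = 3,
                                 tf_name = NA_character_,
                                 min_reliable = 1000, reliable_count = 8,
                                 min_max_count = 100) {
  motif <- .as_core_motif(motif)
  ridx <- vapply(pools, function(p) p$round_index, integer(1))
  if (!any(ridx == 0)) stop("round 0 pool required for the background model")
  bg <- fit_markov(pools[[which(ridx == 0)[1]]], order, pseudocount)
  if (is.null(rounds)) rounds <- sort(ridx[ridx >= min_round])
  fl0 <- initial_flank_length(motif$literal_length)
  out <- list()
  for (i in rounds) {
    pool <- pools[[which(ridx == i)[1]]]
    read_len <- min(nchar(pool$reads))
    fl_max_possible <- max(fl0, floor((read_len - motif$literal_length) / 2))
    summ <- flank_summaries(pool, motif, fl0:fl_max_possible, reliable_count)
    fl_max <- tryCatch(
      max_flank_length(summ, min_reliable, reliable_count, min_max_count),
      error = function(e) NA_integer_)
    if (is.na(fl_max)) next
    for (fl in fl0:fl_max) {
      ct <- count_mwords(pool, motif, fl)
      ds <- score_mwords(ct, bg, i, motif, fl, tf_name, min_round)
      out[[paste0("round", i, "_flank", fl)]] <- ds
    }
  }
  if (length(out) == 0)
    warning("no dataset passed the depth thresholds (insufficient_depth)")
  out
}

#' Write an M-word dataset as TSV
#'
#' Columns `mword`, `count`, `freq`, `est_freq0`, `score` in deterministic
#' lexicographic M-word order.
#'
#' @param dataset An [mword_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mword_dataset <- function(dataset, path) {
  rec <- dataset$records[order(dataset$records$mword), ]
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
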