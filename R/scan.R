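#' Scan reads for a single core-motif binding site
#'
#' Both strands of every read are scanned for windows matching the IUPAC
#' core motif within its mismatch budget. A read is discarded when two or
#' more distinct genomic intervals (counting an interval once across
#' strands) match at the stricter threshold of one mismatch fewer
#' (`multiple_sites`, to exclude cooperative binding), when no window
#' matches (`no_site`), when equally good best hits occur at different
#' intervals (`ambiguous`) or on both strands of the same interval
#' (`ambiguous_strand`), or when the best hit lacks `flank_len` bases on
#' either side (`short_flank`). Reads containing non-ACGT characters are
#' skipped (`non_acgt`). For retained reads the M-word (core plus flanks,
#' re-oriented so the core reads in motif orientation) is reported.
#'
#' @param reads Character vector of same-length A/C/G/T reads.
#' @param motif IUPAC string or [core_motif()] object.
#' @param flank_len Number of flanking bases required on each side of the
#'   core (>= 0).
#' @return A data.frame with one row per read: `status`, `start` (1-based
#'   core start on the forward strand), `strand` (`"+"`/`"-"`),
#'   `mismatches`, `mword` (NA unless `status == "hit"`).
#' @export
scan_pool <- function(reads, motif, flank_len = 0) {
  motif <- .as_core_motif(motif)
  if (flank_len < 0) stop("flank_len must be >= 0")
  n <- length(reads)
  out <- data.frame(status = rep("no_site", n), start = NA_integer_,
                    strand = NA_character_, mismatches = NA_integer_,
                    mword = NA_character_, stringsAsFactors = FALSE)
  reads <- toupper(reads)
  for (L in unique(nchar(reads))) {
    idx <- which(nchar(reads) == L)
    res <- .scan_same_length(reads[idx], motif, flank_len)
    out[idx, ] <- res
  }
  out
}

.scan_same_length <- function(reads, motif, flank_len) {
  n <- length(reads)
  Lm <- motif$literal_length
  Lr <- unique(nchar(reads))
  blank <- data.frame(status = rep("no_site", n), start = NA_integer_,
                      strand = NA_character_, mismatches = NA_integer_,
                      mword = NA_character_, stringsAsFactors = FALSE)
  if (Lr < Lm) return(blank)
  C <- .code_matrix(reads)
  bad <- rowSums(is.na(C)) > 0
  C[is.na(C)] <- 0L
  W <- Lr - Lm + 1
  allowed <- motif$allowed_mismatches

  # per-strand mismatch count matrices, n x W, aligned by interval start
  mism <- function(symbols) {
    ok <- IUPAC_MATCH[symbols, , drop = FALSE]  # Lm x 4
    m <- matrix(0L, n, W)
    for (s in seq_len(W)) {
      acc <- integer(n)
      for (j in seq_len(Lm)) acc <- acc + !ok[j, C[, s + j - 1] + 1L]
      m[, s] <- acc
    }
    m
  }
  mf <- mism(.chars(motif$symbols))
  mr <- mism(.chars(revcomp(motif$symbols)))

  interval_best <- pmin(mf, mr)
  strict <- allowed - 1L
  n_strict <- if (strict >= 0) rowSums(interval_best <= strict) else integer(n)

  best <- interval_best[cbind(seq_len(n), max.col(-interval_best, "first"))]
  n_best_int <- rowSums(interval_best == best)
  s_best <- max.col(-interval_best, "first")
  f_at_best <- mf[cbind(seq_len(n), s_best)]
  r_at_best <- mr[cbind(seq_len(n), s_best)]

  status <- rep("hit", n)
  status[best > allowed] <- "no_site"
  status[best <= allowed & n_best_int > 1] <- "ambiguous"
  status[best <= allowed & n_best_int == 1 &
           f_at_best == best & r_at_best == best] <- "ambiguous_strand"
  status[n_strict >= 2] <- "multiple_sites"

  ok <- status == "hit"
  short <- ok & (s_best - flank_len < 1 | s_best + Lm - 1 + flank_len > Lr)
  status[short] <- "short_flank"
  ok <- status == "hit"

  status[bad] <- "non_acgt"
  ok <- status == "hit"

  strand <- ifelse(f_at_best <= r_at_best, "+", "-")
  mword <- rep(NA_character_, n)
  if (any(ok)) {
    from <- s_best[ok] - flank_len
    to <- s_best[ok] + Lm - 1 + flank_len
    w <- substr(reads[ok], from, to)
    rev_ <- strand[ok] == "-"
    if (any(rev_)) w[rev_] <- revcomp(w[rev_])
    mword[ok] <- w
  }
  data.frame(status = status,
             start = ifelse(ok, s_best, NA_integer_),
             strand = ifelse(ok, strand, NA_character_),
             mismatches = ifelse(ok, best, NA_integer_),
             mword = mword, stringsAsFactors = FALSE)
}

#' Scan a single read for a core-motif site
#'
#' Single-read convenience wrapper around [scan_pool()].
#'
#' @inheritParams scan_pool
#' @param read One DNA string.
#' @return List with `status` (`"hit"` or a discard reason), and for hits
#'   `start`, `strand`, `mismatches`, `mword`.
#' @export
scan_read <- function(read, motif, flank_len = 0) {
  r <- scan_pool(read, motif, flank_len)
  as.list(r[1, ])
}
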