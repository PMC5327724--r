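# IUPAC nucleotide codes and the base sets they denote.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

BASES <- c("A", "C", "G", "T")

# 15 x 4 logical lookup: does IUPAC code (row) admit base (column)?
IUPAC_MATCH <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_SETS), ncol = 4,
              dimnames = list(names(IUPAC_SETS), BASES))
  for (s in names(IUPAC_SETS)) m[s, IUPAC_SETS[[s]]] <- TRUE
  m
})

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

.check_iupac <- function(symbols) {
  bad <- !(symbols %in% names(IUPAC_SETS))
  if (any(bad))
    stop("invalid IUPAC symbol(s): ", paste(unique(symbols[bad]), collapse = ", "))
  invisible(symbols)
}

.chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' Does an IUPAC code match a nucleotide?
#'
#' `iupac_matches("R", "A")` is `TRUE` because R denotes \{A, G\}.
#' Both arguments are vectorized and recycled.
#'
#' @param symbol IUPAC nucleotide code(s).
#' @param base Concrete nucleotide(s), one of A/C/G/T.
#' @return Logical vector.
#' @export
iupac_matches <- function(symbol, base) {
  symbol <- toupper(symbol); base <- toupper(base)
  .check_iupac(symbol)
  if (any(!(base %in% BASES)))
    stop("invalid base(s): ", paste(unique(base[!(base %in% BASES)]), collapse = ", "))
  IUPAC_MATCH[cbind(symbol, base)]
}

#' Degeneracy weight of an IUPAC symbol
#'
#' The weight of a symbol is 1 / (number of nucleotides it represents):
#' 1 for A/C/G/T, 1/2 for two-fold codes such as R or W, 1/3 for B/D/H/V
#' and 1/4 for N.
#'
#' @param symbol IUPAC code(s).
#' @return Numeric vector of weights in (0, 1].
#' @export
degenerate_weight <- function(symbol) {
  symbol <- toupper(symbol)
  .check_iupac(symbol)
  unname(1 / vapply(IUPAC_SETS[symbol], length, integer(1)))
}

#' Weighted length of an IUPAC core motif
#'
#' Sum of per-symbol degeneracy weights; degenerate positions count less
#' than fully specified ones (e.g. CANNTG has weighted length
#' 4*1 + 2*0.25 = 4.5).
#'
#' @param motif IUPAC string or a [core_motif()] object.
#' @return Scalar weighted length.
#' @export
weighted_core_length <- function(motif) {
  if (inherits(motif, "core_motif")) return(motif$weighted_length)
  if (!nzchar(motif)) stop("empty motif")
  sum(degenerate_weight(.chars(motif)))
}

#' Allowed mismatch budget for a core motif
#'
#' floor((weighted_length - 4) / 2) + 1, clamped to 0 for motifs with
#' weighted length below 4.
#'
#' @param motif IUPAC string or [core_motif()] object.
#' @return Integer mismatch budget.
#' @export
allowed_mismatches <- function(motif) {
  wl <- weighted_core_length(motif)
  if (wl < 4) return(0L)
  as.integer(floor((wl - 4) / 2) + 1)
}

#' IUPAC core motif
#'
#' Bundles an IUPAC consensus string with its literal length, weighted
#' (degeneracy-discounted) length and the mismatch budget derived from the
#' weighted length.
#'
#' @param symbols IUPAC string, e.g. `"CANNTG"`.
#' @return Object of class `core_motif` with fields `symbols`,
#'   `literal_length`, `weighted_length`, `allowed_mismatches`.
#' @examples
#' core_motif("CANNTG")
#' @export
core_motif <- function(symbols) {
  symbols <- toupper(symbols)
  if (!is.character(symbols) || length(symbols) != 1 || !nzchar(symbols))
    stop("empty motif")
  ch <- .chars(symbols)
  .check_iupac(ch)
  structure(list(
    symbols = symbols,
    literal_length = length(ch),
    weighted_length = sum(degenerate_weight(ch)),
    allowed_mismatches = allowed_mismatches(symbols)
  ), class = "core_motif")
}

#' @export
print.core_motif <- function(x, ...) {
  cat("IUPAC core motif: ", x$symbols, "\n",
      "  literal length   ", x$literal_length, "\n",
      "  weighted length  ", format(x$weighted_length), "\n",
      "  mismatch budget  ", x$allowed_mismatches, "\n", sep = "")
  invisible(x)
}

.as_core_motif <- function(motif) {
  if (inherits(motif, "core_motif")) motif else core_motif(motif)
}

#' Count mismatches of a window against a core motif
#'
#' @param window DNA string (A/C/G/T) of the motif's literal length.
#' @param motif IUPAC string or [core_motif()] object.
#' @return Integer number of positions where the window violates the motif.
#' @export
count_mismatches <- function(window, motif) {
  motif <- .as_core_motif(motif)
  w <- .chars(window)
  if (length(w) != motif$literal_length)
    stop("window length ", length(w), " != motif length ", motif$literal_length)
  sum(!iupac_matches(.chars(motif$symbols), w))
}

#' Reverse complement of a DNA/IUPAC string
#'
#' @param x Character vector of sequences (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(IUPAC_COMPLEMENT, collapse = ""), x)
  vapply(comp, function(s) paste(rev(.chars(s)), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' Expand an IUPAC motif into all matching words
#'
#' Intended for small motifs (product of degeneracies bounded).
#'
#' @param motif IUPAC string or [core_motif()] object.
#' @return Character vector of all concrete A/C/G/T words the motif admits.
#' @export
expand_motif <- function(motif) {
  motif <- .as_core_motif(motif)
  sets <- IUPAC_SETS[.chars(motif$symbols)]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = ""))
}

#' Select a core motif from a family catalogue
#'
#' Slides each catalogue motif over the published seed at every offset and
#' scores the alignment: `score1` is the fraction of aligned positions whose
#' IUPAC nucleotide sets agree (the symbols need not be identical, only the
#' sets they denote), and ties on `score1` are broken by `score2`, the
#' fraction of exactly identical IUPAC symbols. The winning substring of the
#' seed becomes the core.
#'
#' @param published_seed IUPAC string (the full published seed with flanks).
#' @param family_motifs Character vector of catalogue IUPAC motifs.
#' @return List of class `seed_selection`: `chosen_core` ([core_motif()]),
#'   `score1`, `score2`, `start`, `end` (positions within the seed),
#'   `catalog_motif`, and `survivors` (all tied candidates).
#' @export
select_core_from_catalog <- function(published_seed, family_motifs) {
  published_seed <- toupper(published_seed)
  if (!nzchar(published_seed) || length(family_motifs) == 0)
    stop("empty seed or catalogue")
  seed_ch <- .chars(published_seed)
  .check_iupac(seed_ch)
  seed_sets <- vapply(IUPAC_SETS[seed_ch],
                      function(s) paste(sort(s), collapse = ""), character(1))
  cands <- list()
  for (m in family_motifs) {
    mc <- .chars(toupper(m))
    .check_iupac(mc)
    if (length(mc) > length(seed_ch)) {
      warning("catalogue motif ", m, " longer than seed; skipped")
      next
    }
    m_sets <- vapply(IUPAC_SETS[mc],
                     function(s) paste(sort(s), collapse = ""), character(1))
    for (off in seq_len(length(seed_ch) - length(mc) + 1)) {
      idx <- off:(off + length(mc) - 1)
      s1 <- mean(seed_sets[idx] == m_sets)
      s2 <- mean(seed_ch[idx] == mc)
      cands[[length(cands) + 1]] <- list(
        motif = toupper(m), start = off, end = off + length(mc) - 1,
        score1 = s1, score2 = s2)
    }
  }
  if (length(cands) == 0) stop("no usable catalogue motif (all skipped)")
  s1 <- vapply(cands, `[[`, numeric(1), "score1")
  s2 <- vapply(cands, `[[`, numeric(1), "score2")
  best1 <- s1 == max(s1)
  best <- best1 & s2 == max(s2[best1])
  survivors <- cands[best]
  top <- survivors[[1]]
  core <- substr(published_seed, top$start, top$end)
  structure(list(
    chosen_core = core_motif(core),
    score1 = top$score1, score2 = top$score2,
    start = top$start, end = top$end,
    catalog_motif = top$motif,
    survivors = survivors
  ), class = "seed_selection")
}

#' @export
print.seed_selection <- function(x, ...) {
  cat("Seed selection: core ", x$chosen_core$symbols,
      " (seed positions ", x$start, "-", x$end, ")\n",
      "  score1 = ", format(x$score1), ", score2 = ", format(x$score2),
      ", catalogue motif ", x$catalog_motif, "\n", sep = "")
  invisible(x)
}
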