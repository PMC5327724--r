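#' Fit a Markov background model of the initial pool
#'
#' Tallies all (order+1)-mers across the reads of the initial (round 0)
#' pool with pseudocount smoothing, and derives (i) the marginal
#' distribution over (order+1)-mers and (ii) the conditional distribution
#' of each base given the preceding `order` bases. With the default order
#' of 5 this is the fifth-order model used to estimate initial-pool M-word
#' frequencies. Counting is on the read strand only.
#'
#' @param initial_pool [read_pool()] object or character vector of reads.
#' @param order Markov order (default 5).
#' @param pseudocount Added to every (order+1)-mer count cell (default 1);
#'   must be > 0 for strictly positive probabilities.
#' @return Object of class `markov_bg` with elements `order`, `pseudocount`,
#'   `marginal` (length 4^(order+1) probability vector over (order+1)-mers,
#'   lexicographic A<C<G<T) and `conditional` (4^order x 4 matrix of
#'   P(base | context)).
#' @export
fit_markov <- function(initial_pool, order = 5, pseudocount = 1) {
  reads <- if (inherits(initial_pool, "read_pool")) initial_pool$reads
           else toupper(initial_pool)
  if (length(reads) == 0) stop("empty pool")
  k <- order + 1
  reads <- reads[nchar(reads) >= k & !grepl("[^ACGT]", reads)]
  if (length(reads) == 0) stop("no reads longer than the model order")
  counts <- .kmer_counts(reads, k)      # lexicographic, index = ctx*4 + base
  marginal <- (counts + pseudocount) / (sum(counts) + pseudocount * 4^k)
  cmat <- matrix(counts, ncol = 4, byrow = TRUE)  # rows: context, cols: base
  conditional <- (cmat + pseudocount) / (rowSums(cmat) + 4 * pseudocount)
  dimnames(conditional) <- list(NULL, BASES)
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 marginal = marginal, conditional = conditional),
            class = "markov_bg")
}

# counts of all k-mers over reads, in lexicographic order (A<C<G<T),
# returned as a length-4^k vector
.kmer_counts <- function(reads, k) {
  tot <- numeric(4^k)
  for (L in unique(nchar(reads))) {
    sub <- reads[nchar(reads) == L]
    C <- .code_matrix(sub)
    if (L < k) next
    idx <- matrix(0, nrow(C), L - k + 1)
    for (j in seq_len(k)) {
      idx <- idx + C[, j:(j + L - k), drop = FALSE] * 4^(k - j)
    }
    tot <- tot + tabulate(as.vector(idx) + 1L, nbins = 4^k)
  }
  tot
}

#' @export
print.markov_bg <- function(x, ...) {
  cat("Markov background model, order ", x$order,
      " (pseudocount ", x$pseudocount, ")\n", sep = "")
  invisible(x)
}

#' Estimate initial-pool frequency of M-words under the background model
#'
#' P(word) = P(first (order+1)-mer) * prod over remaining positions of
#' P(base | preceding `order` bases). Summed over all 4^M words of a given
#' length M this is exactly 1.
#'
#' @param mwords Character vector of A/C/G/T words, each at least
#'   order+1 long.
#' @param background A [fit_markov()] model.
#' @return Numeric vector of estimated frequencies.
#' @export
estimate_freq0 <- function(mwords, background) {
  stopifnot(inherits(background, "markov_bg"))
  k <- background$order + 1
  M <- unique(nchar(mwords))
  if (length(M) != 1) stop("mwords must share one length")
  if (M < k) stop("mwords shorter than the Markov context (", k, ")")
  C <- .code_matrix(mwords)
  if (any(is.na(C))) stop("mwords must be A/C/G/T only")
  idx1 <- rep(0, length(mwords))
  for (j in seq_len(k)) idx1 <- idx1 + C[, j] * 4^(k - j)
  p <- background$marginal[idx1 + 1L]
  if (M > k) {
    for (j in (k + 1):M) {
      ctx <- rep(0, length(mwords))
      for (u in seq_len(background$order)) {
        ctx <- ctx + C[, j - background$order + u - 1L] * 4^(background$order - u)
      }
      p <- p * background$conditional[cbind(ctx + 1L, C[, j] + 1L)]
    }
  }
  p
}
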