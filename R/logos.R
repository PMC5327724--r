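# shape logo letter <-> feature mapping (fixed by convention)
LOGO_LETTERS <- c(HelT = "H", MGW = "M", ProT = "P", Roll = "R")

#' DNA shape logo PSSM from a per-feature delta R-squared matrix
#'
#' Letter heights are the delta R-squared values of the four shape
#' features (H = HelT, M = MGW, P = ProT, R = Roll), floored at 0 for
#' display; the two undefined terminal positions at each end carry empty
#' (zero) stacks. Heights equal the delta matrix entries exactly — no
#' renormalization is applied.
#'
#' @param delta A [feature_delta_matrix()] result.
#' @param floor_zero Floor negative values at 0 (default TRUE).
#' @return Object of class `shape_logo`: `pssm` (M x 4 matrix, columns
#'   H/M/P/R), `M`, `tf_name`.
#' @export
shape_logo <- function(delta, floor_zero = TRUE) {
  m <- delta$delta
  m[is.na(m)] <- 0
  if (floor_zero) m <- pmax(m, 0)
  colnames(m) <- unname(LOGO_LETTERS[colnames(delta$delta)])
  if (all(m == 0)) warning("all-zero delta matrix: empty logo")
  structure(list(pssm = m, M = delta$M, tf_name = delta$tf_name),
            class = "shape_logo")
}

#' @export
print.shape_logo <- function(x, ...) {
  cat("DNA shape logo PSSM (letters H=HelT, M=MGW, P=ProT, R=Roll)\n")
  print(round(x$pssm, 4))
  invisible(x)
}

# stacked-letter rendering shared by shape and sequence logos
.plot_stacks <- function(heights, colors, ylab, main) {
  M <- nrow(heights)
  ymax <- max(colSums(heights), 1e-6)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, M + 0.5), ylim = c(0, ymax * 1.05))
  graphics::axis(1, at = seq_len(M)); graphics::axis(2)
  graphics::title(xlab = "position", ylab = ylab, main = main)
  for (i in seq_len(M)) {
    h <- sort(heights[i, heights[i, ] > 0])
    y0 <- 0
    for (letter in names(h)) {
      graphics::rect(i - 0.45, y0, i + 0.45, y0 + h[letter],
                     col = grDevices::adjustcolor(colors[letter], 0.25),
                     border = NA)
      graphics::text(i, y0 + h[letter] / 2, letter, col = colors[letter],
                     cex = max(0.5, min(3, 3 * h[letter] / ymax)), font = 2)
      y0 <- y0 + h[letter]
    }
  }
}

#' @export
plot.shape_logo <- function(x, ...) {
  cols <- c(H = "#7570B3", M = "#D95F02", P = "#1B9E77", R = "#E7298A")
  .plot_stacks(x$pssm, cols, expression(Delta * R^2),
               if (!is.na(x$tf_name)) paste("shape logo:", x$tf_name)
               else "DNA shape logo")
  invisible(x)
}

#' Sequence PSSM from top-scoring M-words
#'
#' Computes per-position base frequencies over the `top_n`
#' highest-scoring M-words of a dataset and converts them to
#' information-content letter heights (`freq * (2 - entropy)` bits).
#'
#' @param dataset An [mword_dataset()].
#' @param top_n Number of top M-words to use (default 200); if fewer are
#'   available all are used with a warning.
#' @return Object of class `sequence_pssm`: `freq` and `heights`
#'   (M x 4 matrices over A/C/G/T), `ic` (per-position information
#'   content, bits), `n_words`, `tf_name`.
#' @export
sequence_pssm <- function(dataset, top_n = 200) {
  rec <- dataset$records
  if (nrow(rec) == 0) stop("empty dataset")
  if (nrow(rec) < top_n) {
    warning("only ", nrow(rec), " M-words available (requested ", top_n, ")")
    top_n <- nrow(rec)
  }
  top <- rec$mword[order(-rec$score, rec$mword)][seq_len(top_n)]
  C <- .code_matrix(top)
  M <- ncol(C)
  freq <- t(apply(C, 2, function(col) tabulate(col + 1L, 4) / length(col)))
  dimnames(freq) <- list(seq_len(M), BASES)
  ent <- apply(freq, 1, function(p) -sum(ifelse(p > 0, p * log2(p), 0)))
  ic <- 2 - ent
  structure(list(freq = freq, heights = freq * ic, ic = ic,
                 n_words = top_n, tf_name = dataset$tf_name),
            class = "sequence_pssm")
}

#' @export
print.sequence_pssm <- function(x, ...) {
  cat("Sequence PSSM from top ", x$n_words, " M-words; per-position IC:\n",
      sep = "")
  print(round(x$ic, 3))
  invisible(x)
}

#' @export
plot.sequence_pssm <- function(x, ...) {
  cols <- c(A = "#1B9E77", C = "#2166AC", G = "#E6AB02", T = "#D95F02")
  .plot_stacks(x$heights, cols, "bits",
               if (!is.na(x$tf_name)) paste("sequence logo:", x$tf_name)
               else "sequence logo")
  invisible(x)
}

#' Representative binding word for a TF
#'
#' The highest-scoring M-word of the (last-round) dataset; exact ties go
#' to the lexicographically smallest word.
#'
#' @param dataset An [mword_dataset()], or a list of them (the one with
#'   the highest round index is used).
#' @return The representative M-word (character scalar).
#' @export
representative_word <- function(dataset) {
  if (!inherits(dataset, "mword_dataset")) {
    rounds <- vapply(dataset, `[[`, integer(1), "round_index")
    dataset <- dataset[[which.max(rounds)]]
  }
  rec <- dataset$records
  if (nrow(rec) == 0) stop("no scored M-words")
  rec$mword[order(-rec$score, rec$mword)][1]
}

#' PCA of TF binding preferences with family distances
#'
#' Centers the per-TF feature vectors, projects them onto the first two
#' principal components (covariance PCA), classifies all pairwise
#' two-dimensional Euclidean distances as intra- or inter-family, and
#' reports the medians and their difference. A larger inter-minus-intra
#' median difference indicates better family separation.
#'
#' @param x Numeric matrix, one row per TF (feature vectors of equal
#'   length, e.g. 1mer or 1mer+shape encodings of representative words).
#' @param families Character/factor vector of family labels, one per row.
#' @return Object of class `family_pca`: `coords` (n x 2), `distances`
#'   (data.frame with `i`, `j`, `dist`, `type`), `median_intra`,
#'   `median_inter`, `median_diff` (inter - intra), `sdev` (all component
#'   standard deviations).
#' @export
pca_families <- function(x, families) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || length(unique(families)) < 2)
    stop("need at least two TFs from at least two families")
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (sum(keep) < 2) stop("fewer than two informative feature columns")
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2) stop("fewer than two usable principal components")
  coords <- pc$x[, 1:2, drop = FALSE]
  n <- nrow(coords)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((coords[pairs[, 1], 1] - coords[pairs[, 2], 1])^2 +
              (coords[pairs[, 1], 2] - coords[pairs[, 2], 2])^2)
  type <- ifelse(families[pairs[, 1]] == families[pairs[, 2]],
                 "intra", "inter")
  med_intra <- stats::median(d[type == "intra"])
  med_inter <- stats::median(d[type == "inter"])
  structure(list(coords = coords, families = families,
                 distances = data.frame(i = pairs[, 1], j = pairs[, 2],
                                        dist = d, type = type),
                 median_intra = med_intra, median_inter = med_inter,
                 median_diff = med_inter - med_intra,
                 sdev = pc$sdev),
            class = "family_pca")
}

#' @export
print.family_pca <- function(x, ...) {
  cat("Family PCA: ", nrow(x$coords), " TFs, ",
      length(unique(x$families)), " families\n",
      "  median intra-family distance ", format(round(x$median_intra, 3)),
      ", inter ", format(round(x$median_inter, 3)),
      " (difference ", format(round(x$median_diff, 3)), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.family_pca <- function(x, ...) {
  fam <- as.factor(x$families)
  graphics::plot(x$coords, col = as.integer(fam), pch = 19,
                 xlab = "PC1", ylab = "PC2", main = "TF family PCA", ...)
  graphics::legend("topright", legend = levels(fam),
                   col = seq_along(levels(fam)), pch = 19, cex = 0.8)
  invisible(x)
}
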