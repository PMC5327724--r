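SHAPE_KINDS <- c("MGW", "ProT", "Roll", "HelT")

ALL_PENTAMERS <- local({
  g <- expand.grid(b5 = BASES, b4 = BASES, b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3, g$b4, g$b5))
})

.validate_shape_table <- function(df) {
  need <- c("pentamer", "MGW", "ProT", "Roll1", "Roll2", "HelT1", "HelT2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("shape table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) != 1024) stop("shape table must have 1024 rows, got ", nrow(df))
  df$pentamer <- toupper(df$pentamer)
  bad <- grepl("[^ACGT]", df$pentamer) | nchar(df$pentamer) != 5
  if (any(bad)) stop("non-ACGT pentamer at row(s) ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  if (anyDuplicated(df$pentamer))
    stop("duplicate pentamer: ", df$pentamer[duplicated(df$pentamer)][1])
  if (!setequal(df$pentamer, ALL_PENTAMERS))
    stop("shape table missing pentamer(s): ",
         paste(utils::head(setdiff(ALL_PENTAMERS, df$pentamer), 5), collapse = ", "))
  for (cn in need[-1]) {
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column ", cn)
  }
  df <- df[order(df$pentamer), need]
  rownames(df) <- df$pentamer
  class(df) <- c("shape_table", "data.frame")
  df
}

#' Pentamer DNA shape query table
#'
#' A query table maps each of the 1024 DNA pentamers to the shape of its
#' central region: minor groove width (MGW, Angstrom) and propeller twist
#' (ProT, degrees) of the central base pair, and roll / helix twist
#' (degrees) of the two central base-pair steps (`Roll1`/`HelT1` for the
#' step left of the central bp, `Roll2`/`HelT2` for the step to its right).
#'
#' @param df data.frame with columns `pentamer`, `MGW`, `ProT`, `Roll1`,
#'   `Roll2`, `HelT1`, `HelT2` and exactly 1024 rows.
#' @return Validated object of class `shape_table`.
#' @export
shape_table <- function(df) .validate_shape_table(as.data.frame(df))

#' Load / save a pentamer shape table (TSV)
#'
#' @param path TSV file with header
#'   `pentamer, MGW, ProT, Roll1, Roll2, HelT1, HelT2`.
#' @return [shape_table()] object.
#' @export
load_shape_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_shape_table(df)
}

#' @rdname load_shape_table
#' @param table A [shape_table()].
#' @export
save_shape_table <- function(table, path) {
  utils::write.table(as.data.frame(unclass(table)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic pentamer shape table
#'
#' Draws seeded random values per pentamer within physically plausible
#' ranges (MGW 3.0-6.5 Angstrom; ProT -17-0 deg; Roll -8-9 deg; HelT 30-40
#' deg). With `rc_symmetric = TRUE` (default) values are tied across
#' reverse-complement pentamer pairs: MGW and ProT of a pentamer equal
#' those of its reverse complement, and the two step features are swapped
#' (`Roll1(p) = Roll2(rc(p))` etc.), so shape profiles obey strand
#' symmetry. This synthetic table is a stand-in for an experimentally
#' derived query table; any table in the same TSV layout can be dropped in.
#'
#' @param seed Integer seed.
#' @param rc_symmetric Enforce reverse-complement symmetry (default TRUE).
#' @return A [shape_table()].
#' @export
gen_shape_table <- function(seed = 1, rc_symmetric = TRUE) {
  set.seed(seed)
  n <- 1024
  df <- data.frame(pentamer = ALL_PENTAMERS,
                   MGW = stats::runif(n, 3.0, 6.5),
                   ProT = stats::runif(n, -17, 0),
                   Roll1 = stats::runif(n, -8, 9),
                   Roll2 = stats::runif(n, -8, 9),
                   HelT1 = stats::runif(n, 30, 40),
                   HelT2 = stats::runif(n, 30, 40),
                   stringsAsFactors = FALSE)
  if (rc_symmetric) {
    rc <- revcomp(df$pentamer)
    keep <- df$pentamer <= rc    # canonical member of each rc pair
    idx <- match(rc, df$pentamer)
    for (i in which(!keep)) {
      j <- idx[i]
      df$MGW[i] <- df$MGW[j]; df$ProT[i] <- df$ProT[j]
      df$Roll1[i] <- df$Roll2[j]; df$Roll2[i] <- df$Roll1[j]
      df$HelT1[i] <- df$HelT2[j]; df$HelT2[i] <- df$HelT1[j]
    }
    # palindromic pentamers cannot exist (odd length), so every pair is
    # distinct and the assignment above is total
  }
  .validate_shape_table(df)
}

#' Shuffle a pentamer shape table
#'
#' Permutes the pentamer-to-row assignment with a seeded RNG, preserving
#' the value multiset of every column — the negative control for testing
#' whether model gains come from shape information rather than added
#' parameters.
#'
#' @param table A [shape_table()].
#' @param seed Integer seed.
#' @return Shuffled [shape_table()].
#' @export
shuffle_shape_table <- function(table, seed = 1) {
  set.seed(seed)
  perm <- sample.int(1024)
  df <- as.data.frame(unclass(table))
  df[, -1] <- df[perm, -1]
  .validate_shape_table(df)
}

#' Predict DNA shape profiles with the pentamer sliding window
#'
#' Slides a 5-bp window along each sequence. Base-pair features (MGW, ProT)
#' at position i are the table values of the pentamer centered at i,
#' defined for i = 3..L-2. Step features (Roll, HelT) are indexed by the
#' step's right base pair: `Roll[, i]` is the roll of the step between bp
#' i-1 and i, assembled by averaging the central-step values of the
#' overlapping pentamers, defined for i = 3..L-1. The two terminal
#' positions at each end are NA (undefined).
#'
#' @param seqs Character vector of A/C/G/T sequences, all the same length
#'   L >= 5.
#' @param table A [shape_table()].
#' @return List of class `shape_profile` with n x L matrices `MGW`, `ProT`,
#'   `Roll`, `HelT` (NA where undefined) and the sequence length `L`.
#' @export
predict_shape <- function(seqs, table) {
  stopifnot(inherits(table, "shape_table"))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must share one length")
  n <- length(seqs)
  out <- lapply(SHAPE_KINDS, function(k) matrix(NA_real_, n, L))
  names(out) <- SHAPE_KINDS
  if (L < 5) {
    warning("sequences shorter than 5 bp: all shape features undefined")
    return(structure(c(out, list(L = L)), class = "shape_profile"))
  }
  if (any(grepl("[^ACGT]", toupper(seqs)))) stop("sequences must be A/C/G/T")
  # pentamer row indices for each center position c = 3..L-2
  pent_idx <- sapply(3:(L - 2), function(c_)
    match(substr(toupper(seqs), c_ - 2, c_ + 2), ALL_PENTAMERS))
  pent_idx <- matrix(pent_idx, nrow = n)
  centers <- 3:(L - 2)
  for (ci in seq_along(centers)) {
    c_ <- centers[ci]
    out$MGW[, c_] <- table$MGW[pent_idx[, ci]]
    out$ProT[, c_] <- table$ProT[pent_idx[, ci]]
  }
  # step right-indexed i: contributions Roll1 of pentamer centered i,
  # Roll2 of pentamer centered i-1; average the available ones
  for (i in 3:(L - 1)) {
    for (k in c("Roll", "HelT")) {
      acc <- matrix(NA_real_, n, 2)
      if (i %in% centers)
        acc[, 1] <- table[[paste0(k, "1")]][pent_idx[, match(i, centers)]]
      if ((i - 1) %in% centers)
        acc[, 2] <- table[[paste0(k, "2")]][pent_idx[, match(i - 1, centers)]]
      out[[k]][, i] <- rowMeans(acc, na.rm = TRUE)
    }
  }
  structure(c(out, list(L = L)), class = "shape_profile")
}

#' Replace feature columns with matched Gaussian noise
#'
#' Each selected column is replaced by i.i.d. normal draws with the
#' column's mean and standard deviation — the control for testing whether
#' performance gains come from shape information or mere added
#' dimensionality.
#'
#' @param mat Numeric matrix.
#' @param seed Integer seed.
#' @param columns Columns to replace (indices or names); default all.
#' @return Matrix of the same shape.
#' @export
gaussian_random_features <- function(mat, seed = 1, columns = NULL) {
  set.seed(seed)
  if (is.null(columns)) columns <- seq_len(ncol(mat))
  for (j in columns) {
    mu <- mean(mat[, j]); s <- stats::sd(mat[, j])
    mat[, j] <- stats::rnorm(nrow(mat), mu, s)
  }
  mat
}
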