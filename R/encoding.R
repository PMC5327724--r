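#' One-hot k-mer encoding
#'
#' Indicator features for every k-mer at every start position: 4 columns
#' per position for k = 1, 16 per start for k = 2, 64 per start for k = 3,
#' ordered by position then lexicographically (A < C < G < T). Column
#' labels have the form `"<k>mer:<kmer>@<start>"`.
#'
#' @param mwords Character vector of equal-length A/C/G/T words.
#' @param k k-mer size (1, 2 or 3).
#' @return Numeric matrix with a `col_info` attribute (data.frame with
#'   `label`, `group`, `kind`, `pos`).
#' @export
encode_kmers <- function(mwords, k) {
  stopifnot(k %in% 1:3)
  L <- unique(nchar(mwords))
  if (length(L) != 1) stop("words must share one length")
  if (k > L) stop("k exceeds word length")
  C <- .code_matrix(mwords)
  if (any(is.na(C))) stop("words must be A/C/G/T only")
  n <- length(mwords)
  starts <- seq_len(L - k + 1)
  kmers <- ALL_PENTAMERS                       # reuse lexicographic machinery
  kmers <- sort(unique(substr(kmers, 1, k)))
  x <- matrix(0, n, 4^k * length(starts))
  for (si in seq_along(starts)) {
    s <- starts[si]
    idx <- rep(0L, n)
    for (j in seq_len(k)) idx <- idx + C[, s + j - 1] * 4L^(k - j)
    x[cbind(seq_len(n), (si - 1L) * 4^k + idx + 1L)] <- 1
  }
  info <- data.frame(
    label = paste0(k, "mer:", rep(kmers, length(starts)), "@",
                   rep(starts, each = 4^k)),
    group = paste0(k, "mer"),
    kind = rep(kmers, length(starts)),
    pos = rep(starts, each = 4^k),
    stringsAsFactors = FALSE)
  colnames(x) <- info$label
  attr(x, "col_info") <- info
  x
}

#' First- and second-order DNA shape encoding
#'
#' First-order features are normalized per shape kind as
#' `(x - min) / sd`, with the minimum taken over all 1024 pentamers of the
#' query table and the standard deviation over the encoded values in the
#' dataset. Second-order features are products of adjacent first-order
#' features of the same kind, divided by the standard deviation of those
#' products in the dataset. Columns at undefined (terminal) positions are
#' omitted; a second-order product is defined only when both neighbors
#' are. Column labels are `"shape1:<kind>@<pos>"` and
#' `"shape2:<kind>@<pos>"`.
#'
#' @param mwords Character vector of equal-length A/C/G/T words (length
#'   >= 5).
#' @param table A [shape_table()].
#' @param order 1 for first-order only, 2 (default) to add second-order
#'   products.
#' @param params Normalization parameters from a previous call (list with
#'   `min`, `sd`, `sd2`); computed from this dataset when NULL.
#' @return Numeric matrix with attributes `col_info` and `params`.
#' @export
encode_shape <- function(mwords, table, order = 2, params = NULL) {
  stopifnot(inherits(table, "shape_table"), order %in% 1:2)
  prof <- predict_shape(mwords, table)
  L <- prof$L
  mins <- c(MGW = min(table$MGW), ProT = min(table$ProT),
            Roll = min(c(table$Roll1, table$Roll2)),
            HelT = min(c(table$HelT1, table$HelT2)))
  phi <- list(); info <- list()
  sds <- if (is.null(params)) c(MGW = NA, ProT = NA, Roll = NA, HelT = NA)
         else params$sd
  for (kind in SHAPE_KINDS) {
    m <- prof[[kind]]
    vals <- m[, colSums(!is.na(m)) > 0, drop = FALSE]
    if (is.na(sds[[kind]])) sds[[kind]] <- stats::sd(as.vector(vals))
    if (!is.na(sds[[kind]]) && sds[[kind]] > 0) {
      phi[[kind]] <- (m - mins[[kind]]) / sds[[kind]]
    } else {
      warning("constant ", kind, " values: first-order feature dropped")
      phi[[kind]] <- NULL
    }
  }
  blocks <- list(); binfo <- list()
  for (kind in names(phi)) {
    def <- which(colSums(!is.na(phi[[kind]])) > 0)
    blocks[[length(blocks) + 1]] <- phi[[kind]][, def, drop = FALSE]
    binfo[[length(binfo) + 1]] <- data.frame(
      label = paste0("shape1:", kind, "@", def), group = "shape1",
      kind = kind, pos = def, stringsAsFactors = FALSE)
  }
  sd2 <- if (is.null(params)) c(MGW = NA, ProT = NA, Roll = NA, HelT = NA)
         else params$sd2
  if (order >= 2) {
    for (kind in names(phi)) {
      p <- phi[[kind]]
      prods <- p[, -ncol(p), drop = FALSE] * p[, -1, drop = FALSE]
      colnames(prods) <- NULL
      def <- which(colSums(!is.na(prods)) > 0)
      if (length(def) == 0) next
      if (is.na(sd2[[kind]]))
        sd2[[kind]] <- stats::sd(as.vector(prods[, def, drop = FALSE]))
      if (is.na(sd2[[kind]]) || sd2[[kind]] == 0) {
        warning("constant ", kind, " products: second-order feature dropped")
        next
      }
      blocks[[length(blocks) + 1]] <- prods[, def, drop = FALSE] / sd2[[kind]]
      binfo[[length(binfo) + 1]] <- data.frame(
        label = paste0("shape2:", kind, "@", def), group = "shape2",
        kind = kind, pos = def, stringsAsFactors = FALSE)
    }
  }
  x <- do.call(cbind, blocks)
  info <- do.call(rbind, binfo)
  colnames(x) <- info$label
  attr(x, "col_info") <- info
  attr(x, "params") <- list(min = mins, sd = sds, sd2 = sd2)
  x
}

#' Is a core motif palindromic?
#'
#' TRUE when the IUPAC string equals its own reverse complement.
#'
#' @param motif IUPAC string or [core_motif()] object.
#' @return Logical.
#' @export
is_palindromic <- function(motif) {
  s <- if (inherits(motif, "core_motif")) motif$symbols else toupper(motif)
  identical(s, revcomp(s))
}

#' Build a design matrix for a feature-set variant
#'
#' Assembles the named, position-tagged feature columns the model-family
#' comparisons use. `groups` may contain `"1mer"`, `"2mer"`, `"3mer"`,
#' `"shape"` (first- plus second-order shape), `"shape1"` (first-order
#' only), and the end-position k-mer variants `"2merE2"`, `"3merE2"`,
#' `"2merNoE2"`, `"3merNoE2"` (windows overlapping, or excluding, the two
#' terminal positions at each end). With `palindrome = TRUE` every row is
#' averaged with the encoding of its reverse-complement word.
#'
#' @param mwords Character vector of equal-length A/C/G/T words.
#' @param groups Character vector of feature groups.
#' @param table [shape_table()], required when shape groups are requested.
#' @param palindrome Symmetrize rows for a palindromic core (default
#'   FALSE). A warning is issued if requested while the supplied `core`
#'   is not palindromic.
#' @param core Optional core motif, used only to sanity-check `palindrome`.
#' @param params Shape normalization parameters to reuse (else computed
#'   from `mwords`).
#' @return Object of class `design_matrix`: list with `x` (matrix),
#'   `col_info`, `groups`, `params`, `mwords`.
#' @export
design_matrix <- function(mwords, groups = c("1mer", "shape"), table = NULL,
                          palindrome = FALSE, core = NULL, params = NULL) {
  enc <- function(words, params) {
    blocks <- list(); infos <- list(); pout <- params
    for (g in groups) {
      base <- sub("(NoE2|E2)$", "", g)
      mode <- if (grepl("NoE2$", g)) "NoE2" else if (grepl("E2$", g)) "E2" else "all"
      if (base %in% c("1mer", "2mer", "3mer")) {
        k <- as.integer(substr(base, 1, 1))
        b <- encode_kmers(words, k)
        if (mode != "all") b <- .filter_end_windows(b, k, nchar(words[1]), mode)
      } else if (base %in% c("shape", "shape1")) {
        if (is.null(table)) stop("shape groups need a shape table")
        b <- encode_shape(words, table, order = if (base == "shape") 2 else 1,
                          params = pout)
        pout <- attr(b, "params")
      } else stop("unknown feature group: ", g)
      blocks[[g]] <- b
      infos[[g]] <- attr(b, "col_info")
    }
    list(x = do.call(cbind, blocks), info = do.call(rbind, infos),
         params = pout)
  }
  e <- enc(mwords, params)
  if (palindrome) {
    if (!is.null(core) && !is_palindromic(core)) {
      warning("core is not palindromic: symmetrization skipped")
    } else {
      e2 <- enc(revcomp(mwords), e$params)
      e$x <- (e$x + e2$x) / 2
    }
  }
  rownames(e$x) <- NULL
  rownames(e$info) <- NULL
  structure(list(x = e$x, col_info = e$info, groups = groups,
                 params = e$params, mwords = mwords),
            class = "design_matrix")
}

# keep (E2) or drop (NoE2) k-mer columns whose window overlaps the two
# terminal positions at either end
.filter_end_windows <- function(block, k, L, mode) {
  info <- attr(block, "col_info")
  overlaps <- info$pos <= 2 | info$pos + k - 1 >= L - 1
  keep <- if (mode == "E2") overlaps else !overlaps
  out <- block[, keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  info$group <- paste0(info$group, mode)
  info$label <- paste0(info$group, ":", info$kind, "@", info$pos)
  colnames(out) <- info$label
  attr(out, "col_info") <- info
  out
}

#' Restrict a k-mer group of a design matrix to / away from end windows
#'
#' `mode = "E2"` keeps only columns of the group whose k-mer window
#' overlaps the first two or last two sequence positions; `"NoE2"` removes
#' exactly those, so the two modes partition the group's columns.
#'
#' @param dm A [design_matrix()].
#' @param group k-mer group to filter (`"2mer"` or `"3mer"`).
#' @param mode `"E2"` or `"NoE2"`.
#' @return A new `design_matrix`.
#' @export
apply_variant <- function(dm, group, mode = c("E2", "NoE2")) {
  mode <- match.arg(mode)
  L <- unique(nchar(dm$mwords))
  if (L < 5) stop("variant undefined for words shorter than 5")
  k <- as.integer(substr(group, 1, 1))
  info <- dm$col_info
  in_group <- info$group == group
  overlaps <- info$pos <= 2 | info$pos + k - 1 >= L - 1
  drop <- if (mode == "E2") in_group & !overlaps else in_group & overlaps
  dm$x <- dm$x[, !drop, drop = FALSE]
  dm$col_info <- info[!drop, , drop = FALSE]
  sel <- dm$col_info$group == group
  dm$col_info$group[sel] <- paste0(group, mode)
  dm$col_info$label[sel] <- paste0(group, mode, ":", dm$col_info$kind[sel],
                                   "@", dm$col_info$pos[sel])
  colnames(dm$x) <- dm$col_info$label
  dm
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix: ", nrow(x$x), " words x ", ncol(x$x), " features (",
      paste(unique(x$col_info$group), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Column labels of the per-position shape feature group
#'
#' The shape features attributed to nucleotide position i (the shape_i
#' bundle): first-order MGW_i, ProT_i, Roll_i, Roll_(i+1), HelT_i,
#' HelT_(i+1) plus second-order MGW2_i, MGW2_(i+1), ProT2_i, ProT2_(i+1),
#' Roll2_i, HelT2_i — 12 columns at interior positions, clipped to the
#' defined subset near the boundaries.
#'
#' @param dm A [design_matrix()] containing shape columns.
#' @param i Nucleotide position.
#' @return Character vector of column labels present in `dm`.
#' @export
shape_group_columns <- function(dm, i) {
  want <- c(paste0("shape1:", c("MGW", "ProT"), "@", i),
            paste0("shape1:", c("Roll", "HelT"), "@", rep(c(i, i + 1), each = 2)),
            paste0("shape2:", c("MGW", "ProT"), "@", rep(c(i, i + 1), each = 2)),
            paste0("shape2:", c("Roll", "HelT"), "@", i))
  intersect(want, dm$col_info$label)
}

#' Positions with any defined shape feature
#'
#' @param dm A [design_matrix()] with shape columns.
#' @return Integer vector of positions i with non-empty shape_i groups.
#' @export
shape_positions <- function(dm) {
  # a position counts as shape-defined only where its base-pair-centered
  # features exist (the two terminal positions at each end never qualify)
  sort(unique(dm$col_info$pos[dm$col_info$group == "shape1" &
                                dm$col_info$kind %in% c("MGW", "ProT")]))
}

#' Features required per interior nucleotide position
#'
#' The number of distinct feature columns attributable to one interior
#' sequence position for a feature-group combination, counting each step
#' or window column once at its anchor position: 4 for 1mer, 16 for 2mer,
#' 64 for 3mer, 4 for first-order shape, 4 more for second-order shape.
#' A 1mer+shape model thus needs 12 features per position; a
#' 1mer+2mer+3mer model needs 84; a 3mer model 64.
#'
#' @param groups Character vector of feature groups (`"shape"` counts
#'   first- plus second-order).
#' @return Integer count.
#' @export
per_position_feature_count <- function(groups) {
  per <- c("1mer" = 4L, "2mer" = 16L, "3mer" = 64L,
           "shape" = 8L, "shape1" = 4L, "shape2" = 4L)
  bad <- setdiff(groups, names(per))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  sum(per[groups])
}
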