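.fit_cols <- function(dm, y, cols, foldid, lambda, inner_folds, seed,
                      r2_method) {
  fit_ridge(dm$x[, cols, drop = FALSE], y, lambda = lambda,
            foldid = foldid, inner_folds = inner_folds, seed = seed,
            r2_method = r2_method)$cv_r2
}

.shared_foldid <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' Position-wise shape importance by feature addition (red heat map)
#'
#' For each nucleotide position i with defined shape features, fits a
#' 1mer+shape_i model (the 1mer baseline plus the 12-feature shape bundle
#' of position i) and reports the relative performance gain
#' `(R2(1mer+shape_i) - R2(1mer)) / R2(1mer)` — the red heat-map row.
#' Because adjacent positions share pentamer context, a large cell can be
#' a false positive induced by a truly important neighbor.
#'
#' @param dataset An [mword_dataset()].
#' @param table A [shape_table()].
#' @param palindrome Symmetrize encodings (palindromic core).
#' @param seed,folds,lambda,inner_folds,r2_method Passed to [fit_ridge()].
#' @return Object of class `shape_heatmap`: `values` (named by position,
#'   NA where undefined or masked), `kind = "red"`, `r2_ref` (the baseline
#'   R-squared), `M`, `tf_name`.
#' @export
red_heatmap <- function(dataset, table, palindrome = FALSE, seed = 1,
                        folds = 10, lambda = NULL, inner_folds = 5,
                        r2_method = "cor") {
  dm <- design_matrix(dataset$records$mword, c("1mer", "shape"), table,
                      palindrome = palindrome, core = dataset$core)
  y <- dataset$records$score
  foldid <- .shared_foldid(length(y), folds, seed)
  base_cols <- dm$col_info$label[dm$col_info$group == "1mer"]
  r2_base <- .fit_cols(dm, y, base_cols, foldid, lambda, inner_folds, seed,
                       r2_method)
  vals <- rep(NA_real_, dataset$M)
  names(vals) <- seq_len(dataset$M)
  if (r2_base > 0) {
    for (i in shape_positions(dm)) {
      cols <- c(base_cols, shape_group_columns(dm, i))
      r2_i <- .fit_cols(dm, y, cols, foldid, lambda, inner_folds, seed,
                        r2_method)
      vals[as.character(i)] <- (r2_i - r2_base) / r2_base
    }
  }
  structure(list(values = vals, kind = "red", r2_ref = r2_base,
                 M = dataset$M, tf_name = dataset$tf_name),
            class = "shape_heatmap")
}

#' Position-wise shape importance by feature removal (blue heat map)
#'
#' Fits the shape-only model and, per position i, the same model with the
#' shape_i bundle removed; reports
#' `(R2(shape) - R2(shape - shape_i)) / R2(shape)`. Redundancy between
#' adjacent positions can hide truly important positions here (false
#' negatives), which motivates the combined heat map.
#'
#' @inheritParams red_heatmap
#' @return A `shape_heatmap` with `kind = "blue"` and `r2_ref` the
#'   shape-only R-squared.
#' @export
blue_heatmap <- function(dataset, table, palindrome = FALSE, seed = 1,
                         folds = 10, lambda = NULL, inner_folds = 5,
                         r2_method = "cor") {
  dm <- design_matrix(dataset$records$mword, c("1mer", "shape"), table,
                      palindrome = palindrome, core = dataset$core)
  y <- dataset$records$score
  foldid <- .shared_foldid(length(y), folds, seed)
  shape_cols <- dm$col_info$label[dm$col_info$group %in% c("shape1", "shape2")]
  r2_shape <- .fit_cols(dm, y, shape_cols, foldid, lambda, inner_folds, seed,
                        r2_method)
  vals <- rep(NA_real_, dataset$M)
  names(vals) <- seq_len(dataset$M)
  if (r2_shape > 0) {
    for (i in shape_positions(dm)) {
      cols <- setdiff(shape_cols, shape_group_columns(dm, i))
      if (length(cols) == 0) next
      r2_i <- .fit_cols(dm, y, cols, foldid, lambda, inner_folds, seed,
                        r2_method)
      vals[as.character(i)] <- (r2_shape - r2_i) / r2_shape
    }
  }
  structure(list(values = vals, kind = "blue", r2_ref = r2_shape,
                 M = dataset$M, tf_name = dataset$tf_name),
            class = "shape_heatmap")
}

#' Combined heat map (cell-by-cell minimum)
#'
#' The element-wise minimum of the red (addition) and blue (removal) heat
#' maps, which suppresses false positives present in only one of the two.
#'
#' @param red,blue `shape_heatmap` objects over the same positions.
#' @return A `shape_heatmap` with `kind = "combined"`.
#' @export
combined_heatmap <- function(red, blue) {
  if (red$M != blue$M || !identical(names(red$values), names(blue$values)))
    stop("heat maps have different positions")
  structure(list(values = pmin(red$values, blue$values),
                 kind = "combined", r2_ref = NA_real_, M = red$M,
                 tf_name = red$tf_name),
            class = "shape_heatmap")
}

#' @export
print.shape_heatmap <- function(x, ...) {
  cat(x$kind, " heat-map row",
      if (!is.na(x$tf_name)) paste0(" [", x$tf_name, "]"), " (M = ", x$M,
      if (!is.na(x$r2_ref)) paste0(", reference R2 = ", round(x$r2_ref, 3)),
      ")\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
plot.shape_heatmap <- function(x, ...) {
  v <- x$values
  graphics::barplot(v, names.arg = names(v), xlab = "position",
                    ylab = expression(Delta * R^2 / R[ref]^2),
                    main = paste(x$kind, "heat-map row"),
                    col = if (x$kind == "blue") "steelblue" else "firebrick",
                    ...)
  invisible(x)
}

#' Stack heat-map rows of several datasets into a matrix
#'
#' @param heatmaps List of `shape_heatmap` rows with equal M, e.g. one per
#'   TF; list names (or `tf_name`s) become row names.
#' @return Numeric matrix (TFs x positions) suitable for
#'   [write_matrix_tsv()] or image plotting.
#' @export
heatmap_matrix <- function(heatmaps) {
  m <- do.call(rbind, lapply(heatmaps, `[[`, "values"))
  rn <- names(heatmaps)
  if (is.null(rn)) rn <- vapply(heatmaps, `[[`, character(1), "tf_name")
  rownames(m) <- rn
  m
}

#' Per-feature position-wise delta R-squared
#'
#' For every (position, shape-feature-kind) pair, adds only that kind's
#' first-order column(s) attributed to the position (MGW_i; ProT_i; Roll_i
#' and Roll_(i+1); HelT_i and HelT_(i+1)) to the 1mer baseline and records
#' the gain in cross-validated R-squared. This matrix is the PSSM behind
#' DNA shape logos.
#'
#' @inheritParams red_heatmap
#' @return Object of class `feature_delta`: `delta` (M x 4 matrix over
#'   MGW/ProT/Roll/HelT, NA at undefined positions), `r2_base`, `M`,
#'   `tf_name`.
#' @export
feature_delta_matrix <- function(dataset, table, palindrome = FALSE,
                                 seed = 1, folds = 10, lambda = NULL,
                                 inner_folds = 5, r2_method = "cor") {
  dm <- design_matrix(dataset$records$mword, c("1mer", "shape"), table,
                      palindrome = palindrome, core = dataset$core)
  y <- dataset$records$score
  foldid <- .shared_foldid(length(y), folds, seed)
  base_cols <- dm$col_info$label[dm$col_info$group == "1mer"]
  r2_base <- .fit_cols(dm, y, base_cols, foldid, lambda, inner_folds, seed,
                       r2_method)
  delta <- matrix(NA_real_, dataset$M, length(SHAPE_KINDS),
                  dimnames = list(seq_len(dataset$M), SHAPE_KINDS))
  if (r2_base > 0) {
    for (i in shape_positions(dm)) {
      for (kind in SHAPE_KINDS) {
        want <- if (kind %in% c("MGW", "ProT")) paste0("shape1:", kind, "@", i)
                else paste0("shape1:", kind, "@", c(i, i + 1))
        cols <- intersect(want, dm$col_info$label)
        if (length(cols) == 0) next
        r2_i <- .fit_cols(dm, y, c(base_cols, cols), foldid, lambda,
                          inner_folds, seed, r2_method)
        delta[i, kind] <- r2_i - r2_base
      }
    }
  }
  structure(list(delta = delta, r2_base = r2_base, M = dataset$M,
                 tf_name = dataset$tf_name),
            class = "feature_delta")
}

#' @export
print.feature_delta <- function(x, ...) {
  cat("Per-feature delta R2 matrix (baseline 1mer R2 = ",
      round(x$r2_base, 3), ")\n", sep = "")
  print(round(x$delta, 4))
  invisible(x)
}

#' Write a labeled numeric matrix as TSV
#'
#' @param m Matrix (e.g. from [heatmap_matrix()] or a `feature_delta`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
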