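#' Stage-1 dataset quality control
#'
#' Applies the four count/size/variability criteria: (1) M-words with count
#' <= `min_count` are discarded; the dataset then fails if (2) fewer than
#' `min_words` distinct M-words remain, (3) the 90th-percentile score does
#' not exceed the 10th-percentile score by at least `min_spread`, or (4)
#' the maximum M-word count is below `min_max_count`.
#'
#' @param dataset An [mword_dataset()].
#' @param min_count Count threshold below or at which M-words are dropped
#'   (default 8).
#' @param min_words Minimum distinct M-words after filtering (default 1000).
#' @param min_spread Minimum p90 - p10 score spread (default 0.2).
#' @param min_max_count Minimum maximum count (default 100).
#' @param quantile_type Percentile interpolation method passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @return Object of class `qc_report`: `pass`, per-criterion results with
#'   measured values, and `filtered` (the dataset with low-count records
#'   dropped).
#' @export
qc_stage1 <- function(dataset, min_count = 8, min_words = 1000,
                      min_spread = 0.2, min_max_count = 100,
                      quantile_type = 7) {
  rec <- dataset$records[dataset$records$count > min_count, , drop = FALSE]
  n_words <- nrow(rec)
  max_count <- if (n_words) max(rec$count) else 0
  spread <- if (n_words)
    diff(stats::quantile(rec$score, c(.1, .9), names = FALSE,
                         type = quantile_type)) else 0
  crit <- list(
    sample_size = list(pass = n_words >= min_words, value = n_words,
                       threshold = min_words),
    variability = list(pass = n_words > 0 && spread >= min_spread,
                       value = spread, threshold = min_spread),
    max_count = list(pass = max_count >= min_max_count, value = max_count,
                     threshold = min_max_count))
  filtered <- dataset
  filtered$records <- rec
  structure(list(stage = 1, pass = all(vapply(crit, `[[`, TRUE, "pass")),
                 criteria = crit, filtered = filtered),
            class = "qc_report")
}

#' Stage-2 (regression-consistency) dataset quality control
#'
#' A linear model fitted on a superset of features should not perform
#' worse than one fitted on a subset; a dataset where a superset model's
#' cross-validated R-squared falls short of its subset's by more than
#' `tol` (relative to the subset's R-squared by default) is flagged
#' invalid. Datasets whose best model has R-squared below `min_best_r2`
#' are excluded.
#'
#' @param r2 Named numeric vector of cross-validated R-squared values, one
#'   per model spec (e.g. output of [compare_models()]).
#' @param nested List of length-2 character vectors `c(subset, superset)`
#'   naming nested model pairs in `r2`. If `r2` carries a `"columns"`
#'   attribute (as returned by [compare_models()]), nesting is derived
#'   automatically from column-set inclusion and `nested` may be omitted.
#' @param tol Tolerated performance shortfall (default 0.03, i.e. 3%).
#' @param relative Compare the shortfall relative to the subset model's
#'   R-squared (default) or as an absolute difference.
#' @param min_best_r2 Minimum best-model R-squared (default 0.5).
#' @param eps Guard for near-zero R-squared in the relative comparison.
#' @return Object of class `qc_report` with `pass`, `violations` (data.frame
#'   of nested-pair shortfalls), `best_r2`, `excluded_low_r2`.
#' @export
qc_stage2 <- function(r2, nested = NULL, tol = 0.03, relative = TRUE,
                      min_best_r2 = 0.5, eps = 1e-8) {
  if (is.null(nested)) {
    cols <- attr(r2, "columns")
    if (is.null(cols)) stop("supply `nested` pairs or r2 with a columns attribute")
    nested <- list()
    nm <- names(r2)
    for (a in nm) for (b in nm) {
      if (a != b && all(cols[[a]] %in% cols[[b]]) &&
          length(cols[[a]]) < length(cols[[b]]))
        nested[[length(nested) + 1]] <- c(a, b)
    }
  }
  viol <- data.frame(subset = character(), superset = character(),
                     shortfall = numeric(), stringsAsFactors = FALSE)
  for (p in nested) {
    if (!all(p %in% names(r2))) stop("model ", paste(p, collapse = "/"),
                                     " missing from r2")
    d <- r2[[p[1]]] - r2[[p[2]]]
    short <- if (relative) d / max(r2[[p[1]]], eps) else d
    if (short > tol)
      viol <- rbind(viol, data.frame(subset = p[1], superset = p[2],
                                     shortfall = short))
  }
  best <- max(unlist(r2))
  structure(list(stage = 2, violations = viol, best_r2 = best,
                 excluded_low_r2 = best < min_best_r2,
                 pass = nrow(viol) == 0 && best >= min_best_r2),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC stage ", x$stage, ": ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (x$stage == 1) {
    for (nm in names(x$criteria)) {
      c_ <- x$criteria[[nm]]
      cat(sprintf("  %-12s %s (value %s, threshold %s)\n", nm,
                  if (c_$pass) "ok" else "fail",
                  format(c_$value), format(c_$threshold)))
    }
  } else {
    cat("  nested-model violations: ", nrow(x$violations),
        "; best R2 = ", format(x$best_r2),
        if (x$excluded_low_r2) " (below threshold)", "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path Optional output file; if NULL the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
qc_report_json <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$filtered <- NULL
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Select the best dataset per TF
#'
#' Among a TF's passing datasets, keep the one with the highest best-model
#' cross-validated R-squared; exact ties go to the earliest round, then the
#' smallest flank length.
#'
#' @param datasets data.frame with columns `id`, `r2`, `round`, `flank`.
#' @return The `id` of the selected dataset.
#' @export
select_best_dataset <- function(datasets) {
  if (nrow(datasets) == 0) stop("no passing dataset")
  o <- order(-datasets$r2, datasets$round, datasets$flank)
  datasets$id[o[1]]
}
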