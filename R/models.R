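DEFAULT_LAMBDA_GRID <- 10^seq(3, -4, length.out = 8)

.as_matrix_x <- function(x) {
  if (inherits(x, "design_matrix")) x$x else as.matrix(x)
}

.r2 <- function(obs, pred, method = "cor") {
  if (method == "cor") {
    if (stats::sd(pred) == 0) return(0)
    stats::cor(obs, pred)^2
  } else {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
}

#' L2-regularized linear model with 10-fold cross-validation
#'
#' Fits ridge regression (via glmnet, alpha = 0, unpenalized intercept, no
#' re-standardization — the encodings are already one-hot or sd-normalized)
#' of M-word scores on a feature matrix. The regularization strength is
#' chosen per outer training fold by inner cross-validation over a
#' logarithmic grid; model performance `cv_r2` is the R-squared between the
#' pooled held-out predictions of the outer folds and the observed scores.
#'
#' @param x Feature matrix or [design_matrix()].
#' @param y Numeric response (M-word scores).
#' @param lambda Lambda grid (default `10^seq(3, -4, length.out = 8)`), or a
#'   single fixed value to skip the inner search.
#' @param folds Outer cross-validation folds (default 10).
#' @param inner_folds Folds of the inner lambda search (default 5).
#' @param seed Seed controlling fold assignment (default 1).
#' @param foldid Optional explicit outer fold assignment (overrides `seed`),
#'   e.g. to share folds across model specs for paired comparison.
#' @param r2_method `"cor"` (squared Pearson correlation, default) or
#'   `"vexp"` (1 - SSE/SST).
#' @return Object of class `selex_ridge` with elements `coefficients`
#'   (named, including `(Intercept)`, refit on all data), `lambda` (chosen
#'   on the full data), `cv_r2`, `per_fold_r2`, `oof` (pooled out-of-fold
#'   predictions), `foldid`, `y`, `r2_method`, `seed`.
#' @export
fit_ridge <- function(x, y, lambda = NULL, folds = 10, inner_folds = 5,
                      seed = 1, foldid = NULL, r2_method = c("cor", "vexp")) {
  r2_method <- match.arg(r2_method)
  xm <- .as_matrix_x(x)
  n <- nrow(xm)
  if (n < folds) stop("need at least as many rows as folds")
  if (!all(is.finite(y))) stop("response must be finite")
  if (stats::sd(y) == 0) stop("zero-variance response: R2 undefined")
  if (is.null(lambda)) lambda <- DEFAULT_LAMBDA_GRID
  lambda <- sort(lambda, decreasing = TRUE)
  fixed_lambda <- length(lambda) == 1
  if (is.null(foldid)) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(folds), length.out = n))
  }
  folds <- max(foldid)

  fit_at <- function(xtr, ytr, lam_grid, inner_seed) {
    if (fixed_lambda) {
      f <- glmnet::glmnet(xtr, ytr, alpha = 0, lambda = lam_grid,
                          standardize = FALSE)
      list(fit = f, lambda = lam_grid)
    } else {
      set.seed(inner_seed)
      inner_id <- sample(rep(seq_len(inner_folds), length.out = nrow(xtr)))
      cv <- glmnet::cv.glmnet(xtr, ytr, alpha = 0, lambda = lam_grid,
                              foldid = inner_id, standardize = FALSE)
      list(fit = cv$glmnet.fit, lambda = cv$lambda.min)
    }
  }

  oof <- numeric(n)
  per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    m <- fit_at(xm[tr, , drop = FALSE], y[tr], lambda, seed + 1000 * f)
    pred <- as.vector(stats::predict(m$fit, xm[!tr, , drop = FALSE],
                                     s = m$lambda))
    oof[!tr] <- pred
    per_fold[f] <- .r2(y[!tr], pred, r2_method)
  }
  cv_r2 <- .r2(y, oof, r2_method)

  full <- fit_at(xm, y, lambda, seed)
  cf <- as.matrix(stats::coef(full$fit, s = full$lambda))
  coefs <- stats::setNames(as.vector(cf), rownames(cf))

  structure(list(coefficients = coefs, lambda = full$lambda,
                 cv_r2 = cv_r2, per_fold_r2 = per_fold, oof = oof,
                 foldid = foldid, y = y, r2_method = r2_method,
                 seed = seed, n = n, p = ncol(xm),
                 col_labels = colnames(xm)),
            class = "selex_ridge")
}

#' @export
print.selex_ridge <- function(x, ...) {
  cat("Ridge specificity model: ", x$n, " M-words x ", x$p, " features\n",
      "  lambda = ", format(x$lambda), ", cross-validated R2 = ",
      format(round(x$cv_r2, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.selex_ridge <- function(object, ...) {
  cat("Ridge specificity model\n")
  cat("  features:           ", object$p, "\n")
  cat("  observations:       ", object$n, "\n")
  cat("  lambda (full fit):  ", format(object$lambda), "\n")
  cat("  cv R2 (pooled oof): ", format(round(object$cv_r2, 4)), "\n")
  cat("  per-fold R2:        ",
      paste(format(round(object$per_fold_r2, 3)), collapse = " "), "\n")
  top <- utils::head(sort(abs(object$coefficients[-1]), decreasing = TRUE), 5)
  cat("  largest |weights|:  ", paste(names(top), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.selex_ridge <- function(object, ...) object$coefficients

#' @export
predict.selex_ridge <- function(object, newdata, ...) {
  xm <- .as_matrix_x(newdata)
  want <- object$col_labels
  if (!is.null(colnames(xm)) && all(want %in% colnames(xm))) {
    xm <- xm[, want, drop = FALSE]
  } else if (ncol(xm) != length(want)) {
    stop("newdata does not provide the model's feature columns")
  }
  as.vector(object$coefficients[1] + xm %*% object$coefficients[-1])
}

#' @export
residuals.selex_ridge <- function(object, ...) object$y - object$oof

#' @export
plot.selex_ridge <- function(x, ...) {
  graphics::plot(x$oof, x$y, xlab = "held-out prediction",
                 ylab = "observed score",
                 main = sprintf("cv R2 = %.3f", x$cv_r2), pch = 20,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare feature-set variants on one dataset
#'
#' Fits one cross-validated ridge model per feature spec with a shared
#' outer fold assignment (paired comparison) and reports each spec's
#' cross-validated R-squared.
#'
#' @param dataset An [mword_dataset()].
#' @param specs Named list of feature-group vectors (see
#'   [design_matrix()]), e.g.
#'   `list("1mer" = "1mer", "1mer+shape" = c("1mer", "shape"))`.
#' @param table [shape_table()] for specs with shape groups.
#' @param palindrome Symmetrize encodings for a palindromic core.
#' @param seed,folds,lambda,inner_folds,r2_method Passed to [fit_ridge()].
#' @return Named numeric vector of cv R-squared values, with attributes
#'   `columns` (column labels per spec, from which model nesting can be
#'   derived) and `fits` (the `selex_ridge` objects).
#' @export
compare_models <- function(dataset, specs, table = NULL, palindrome = FALSE,
                           seed = 1, folds = 10, lambda = NULL,
                           inner_folds = 5, r2_method = "cor") {
  words <- dataset$records$mword
  y <- dataset$records$score
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  fits <- list(); cols <- list()
  r2 <- stats::setNames(numeric(length(specs)), names(specs))
  for (nm in names(specs)) {
    dm <- design_matrix(words, specs[[nm]], table = table,
                        palindrome = palindrome, core = dataset$core)
    fits[[nm]] <- fit_ridge(dm, y, lambda = lambda, folds = folds,
                            inner_folds = inner_folds, seed = seed,
                            foldid = foldid, r2_method = r2_method)
    cols[[nm]] <- dm$col_info$label
    r2[nm] <- fits[[nm]]$cv_r2
  }
  attr(r2, "columns") <- cols
  attr(r2, "fits") <- fits
  r2
}

#' Map 1mer+2mer+3mer weights onto an equivalent 3mer model
#'
#' In unregularized linear regression a 3mer model spans the same function
#' space as a 1mer+2mer+3mer model. Given a labeled weight vector of the
#' larger model this returns 3mer weights making identical predictions:
#' for start positions i = 1..N-3,
#' `m_xyz(i) = w3_xyz(i) + w2_xy(i) + w1_x(i)`, and at the last start
#' `m_xyz(N-2) = w3_xyz(N-2) + w2_xy(N-2) + w1_x(N-2) + w2_yz(N-1) +
#' w1_y(N-1) + w1_z(N)`. The intercept carries over unchanged.
#'
#' @param weights Named weight vector with labels `"1mer:<b>@<i>"`,
#'   `"2mer:<bb>@<i>"`, `"3mer:<bbb>@<i>"` (and optionally
#'   `"(Intercept)"`), e.g. `coef()` of a [fit_ridge()] model on a
#'   1mer+2mer+3mer design.
#' @param L Word length N.
#' @return Named vector of 3mer weights (labels `"3mer:<bbb>@<i>"`), with
#'   the intercept as attribute `intercept`.
#' @export
map_3mer_equivalence <- function(weights, L) {
  get_w <- function(labels) {
    miss <- setdiff(labels, names(weights))
    if (length(miss)) stop("missing weight label(s): ",
                           paste(utils::head(miss, 3), collapse = ", "))
    unname(weights[labels])
  }
  trip <- expand.grid(z = BASES, y = BASES, x = BASES,
                      stringsAsFactors = FALSE)
  xyz <- paste0(trip$x, trip$y, trip$z)
  o <- order(xyz); trip <- trip[o, ]; xyz <- xyz[o]
  out <- c()
  for (i in seq_len(L - 2)) {
    m <- get_w(paste0("3mer:", xyz, "@", i)) +
      get_w(paste0("2mer:", trip$x, trip$y, "@", i)) +
      get_w(paste0("1mer:", trip$x, "@", i))
    if (i == L - 2) {
      m <- m + get_w(paste0("2mer:", trip$y, trip$z, "@", i + 1)) +
        get_w(paste0("1mer:", trip$y, "@", i + 1)) +
        get_w(paste0("1mer:", trip$z, "@", i + 2))
    }
    out <- c(out, stats::setNames(m, paste0("3mer:", xyz, "@", i)))
  }
  attr(out, "intercept") <- if ("(Intercept)" %in% names(weights))
    unname(weights["(Intercept)"]) else 0
  out
}

#' Predict scores from a labeled weight vector
#'
#' Utility for checking model equivalences: applies a named weight vector
#' (k-mer labels as produced by [encode_kmers()]) plus intercept to a set
#' of words.
#'
#' @param weights Named weight vector (optionally with an `intercept`
#'   attribute or an `"(Intercept)"` entry).
#' @param mwords Character vector of words.
#' @return Numeric predictions.
#' @export
predict_from_weights <- function(weights, mwords) {
  ks <- unique(as.integer(substr(names(weights)[grepl("^[123]mer", names(weights))], 1, 1)))
  x <- do.call(cbind, lapply(sort(ks), function(k) encode_kmers(mwords, k)))
  w <- weights[intersect(names(weights), colnames(x))]
  icpt <- attr(weights, "intercept")
  if (is.null(icpt)) icpt <- if ("(Intercept)" %in% names(weights))
    unname(weights["(Intercept)"]) else 0
  as.vector(icpt + x[, names(w), drop = FALSE] %*% w)
}
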