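test_that("ridge recovers a noiseless linear signal and is deterministic", {
  set.seed(1)
  words <- unique(random_words(800, 8, seed = 1))
  x <- encode_kmers(words, 1)
  beta <- rnorm(ncol(x), 0, 0.5)
  y <- as.vector(x %*% beta) + 1
  f1 <- fit_ridge(x, y, seed = 4)
  expect_gt(f1$cv_r2, 0.98)
  f2 <- fit_ridge(x, y, seed = 4)
  expect_identical(f1$foldid, f2$foldid)
  expect_identical(f1$cv_r2, f2$cv_r2)
  expect_identical(coef(f1), coef(f2))
  # predictions from the refit correlate with truth
  expect_gt(cor(predict(f1, x), y), 0.99)
  expect_error(fit_ridge(x, rep(1, length(y))), "zero-variance")
})

test_that("ridge reports near-zero R2 on pure noise", {
  set.seed(2)
  words <- unique(random_words(3000, 8, seed = 2))
  x <- encode_kmers(words, 1)
  y <- rnorm(nrow(x))
  f <- fit_ridge(x, y, seed = 5)
  expect_lt(f$cv_r2, 0.05)
})

test_that("compare_models shares folds and honors shape signal direction", {
  tab <- test_shape_table()
  ds <- scored_dataset(shape_truth(tab), seed = 51, pool_size = 20000)
  r2 <- compare_models(ds, list("1mer" = "1mer",
                                "1mer+shape" = c("1mer", "shape")),
                       table = tab, seed = 6)
  fits <- attr(r2, "fits")
  expect_identical(fits[["1mer"]]$foldid, fits[["1mer+shape"]]$foldid)
  expect_gt(r2[["1mer+shape"]], r2[["1mer"]])
  cols <- attr(r2, "columns")
  expect_true(all(cols[["1mer"]] %in% cols[["1mer+shape"]]))
})

test_that("weight mapping makes the 3mer model reproduce 1mer+2mer+3mer", {
  set.seed(3)
  L <- 8
  labels <- c(paste0("1mer:", rep(c("A","C","G","T"), L), "@",
                     rep(1:L, each = 4)))
  dimers <- sort(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")),
                       1, function(r) paste0(r[2], r[1])))
  dimers <- sort(unique(dimers))
  trimers <- expand_motif("NNN")
  labels <- c(labels,
              paste0("2mer:", rep(dimers, L - 1), "@",
                     rep(1:(L - 1), each = 16)),
              paste0("3mer:", rep(trimers, L - 2), "@",
                     rep(1:(L - 2), each = 64)))
  w <- setNames(rnorm(length(labels), 0, 1), labels)
  w <- c("(Intercept)" = 0.7, w)
  m <- map_3mer_equivalence(w, L)
  words <- random_words(500, L, seed = 33)
  p_full <- predict_from_weights(w, words)
  p_3mer <- predict_from_weights(m, words)
  expect_lt(max(abs(p_full - p_3mer)), 1e-10)

  # reverse direction: zero-padded lower orders preserve predictions
  w0 <- w
  w0[grepl("^1mer|^2mer", names(w0))] <- 0
  p_rev <- predict_from_weights(w0, words)
  only3 <- c(w["(Intercept)"], w[grepl("^3mer", names(w))])
  expect_lt(max(abs(p_rev - predict_from_weights(only3, words))), 1e-12)

  # all lower-order weights zero -> mapping is the identity on 3mer weights
  m0 <- map_3mer_equivalence(w0, L)
  expect_equal(unname(m0), unname(w0[grepl("^3mer", names(w0))]),
               ignore_attr = TRUE)
  expect_error(map_3mer_equivalence(w[-2], L), "missing weight")
})

test_that("training-set R2 is monotone under feature-set inclusion", {
  # the linear-algebra rationale behind the stage-2 consistency screen
  set.seed(4)
  words <- unique(random_words(400, 6, seed = 4))
  y <- rnorm(length(words))
  x1 <- encode_kmers(words, 1)
  x2 <- cbind(x1, encode_kmers(words, 2))
  r2_of <- function(x) summary(lm(y ~ x))$r.squared
  expect_gte(r2_of(x2) + 1e-12, r2_of(x1))
})

test_that("regularized 3mer and 1mer+2mer+3mer models agree approximately", {
  tab <- test_shape_table()
  ds <- scored_dataset(shape_truth(tab), seed = 52, pool_size = 20000)
  r2 <- compare_models(ds, list(full = c("1mer", "2mer", "3mer"),
                                just3 = "3mer"),
                       table = tab, seed = 7)
  expect_lt(abs(r2[["full"]] - r2[["just3"]]), 0.05)
})

test_that("red heat map localizes a planted shape readout", {
  tab <- test_shape_table()
  ds <- scored_dataset(shape_truth(tab, planted_pos = 3), seed = 53,
                       pool_size = 20000)
  hm <- red_heatmap(ds, tab, seed = 8)
  expect_s3_class(hm, "shape_heatmap")
  # defined exactly at positions 3..8 for M = 10
  expect_equal(unname(which(!is.na(hm$values))), 3:8)
  expect_true(which.max(hm$values) %in% 2:4)
  # blue heat map: removing the planted position hurts most
  bl <- blue_heatmap(ds, tab, seed = 8)
  expect_equal(unname(which(!is.na(bl$values))), 3:8)
  expect_true(which.max(bl$values) %in% 2:4)
  cb <- combined_heatmap(hm, bl)
  expect_true(all(cb$values <= hm$values + 1e-12, na.rm = TRUE))
  expect_true(all(cb$values <= bl$values + 1e-12, na.rm = TRUE))
  expect_equal(unname(cb$values), unname(pmin(hm$values, bl$values)))
})

test_that("heat maps are near zero for pure-sequence binding", {
  tab <- test_shape_table()
  ds <- scored_dataset(seq_truth(tab), seed = 54, pool_size = 20000)
  hm <- red_heatmap(ds, tab, seed = 9)
  expect_true(all(abs(hm$values) < 0.06, na.rm = TRUE))
})

test_that("combined heat map is the cell-by-cell minimum", {
  mk <- function(v, kind) structure(list(values = setNames(v, seq_along(v)),
                                         kind = kind, r2_ref = 0.5, M = 4,
                                         tf_name = NA_character_),
                                    class = "shape_heatmap")
  red <- mk(c(0.1, 0.4, NA, 0.2), "red")
  blue <- mk(c(0.3, 0.1, NA, 0.2), "blue")
  cb <- combined_heatmap(red, blue)
  expect_equal(unname(cb$values), c(0.1, 0.1, NA, 0.2))
  expect_error(combined_heatmap(red, mk(1:5 / 10, "blue")), "positions")
})

test_that("per-feature delta matrix flags the planted feature kind", {
  tab <- test_shape_table()
  ds <- scored_dataset(shape_truth(tab, planted_pos = 3), seed = 55,
                       pool_size = 20000)
  fd <- feature_delta_matrix(ds, tab, seed = 10)
  expect_equal(dim(fd$delta), c(10, 4))
  # terminal two positions each side have no entries
  expect_true(all(is.na(fd$delta[c(1, 2, 9, 10), ])))
  best <- arrayInd(which.max(fd$delta), dim(fd$delta))
  expect_true(best[1] %in% 2:4)
  expect_equal(colnames(fd$delta)[best[2]], "MGW")
})

test_that("heatmap_matrix stacks rows and export writes TSV", {
  mk <- function(v) structure(list(values = setNames(v, seq_along(v)),
                                   kind = "red", r2_ref = 0.5, M = 3,
                                   tf_name = "tf"),
                              class = "shape_heatmap")
  m <- heatmap_matrix(list(a = mk(c(1, 2, 3)), b = mk(c(4, 5, 6))))
  expect_equal(dim(m), c(2, 3))
  expect_equal(rownames(m), c("a", "b"))
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  back <- read.delim(f)
  expect_equal(back$id, c("a", "b"))
  unlink(f)
})
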