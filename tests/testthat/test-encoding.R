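test_that("k-mer one-hot blocks follow the indicator formulas", {
  x <- encode_kmers("ACGT", 1)
  expect_equal(ncol(x), 16)
  on <- colnames(x)[x[1, ] == 1]
  expect_equal(on, c("1mer:A@1", "1mer:C@2", "1mer:G@3", "1mer:T@4"))
  # row sums: one indicator per position / start
  words <- random_words(50, 8, seed = 1)
  for (k in 1:3) {
    b <- encode_kmers(words, k)
    expect_equal(ncol(b), 4^k * (8 - k + 1))
    expect_true(all(rowSums(b) == 8 - k + 1))
  }
  b3 <- encode_kmers("AAAA", 3)
  expect_equal(sum(b3), 2)
  expect_equal(colnames(b3)[b3[1, ] == 1], c("3mer:AAA@1", "3mer:AAA@2"))
  expect_error(encode_kmers(c("AAA", "AAAA"), 1), "length")
})

test_that("3mer indicators marginalize to 1mer and 2mer indicators", {
  words <- expand_motif("NNNNN")   # all 4^5 five-mers
  b3 <- encode_kmers(words, 3)
  b2 <- encode_kmers(words, 2)
  b1 <- encode_kmers(words, 1)
  i3 <- attr(b3, "col_info")
  # summing 3mer columns whose window starts at s and begins with a given
  # 2mer must reproduce the 2mer indicator at s
  for (s in c(1, 3)) {
    for (dimer in c("AC", "TG")) {
      sel <- i3$pos == s & substr(i3$kind, 1, 2) == dimer
      expect_equal(unname(rowSums(b3[, sel, drop = FALSE])),
                   unname(b2[, paste0("2mer:", dimer, "@", s)]))
    }
    sel <- i3$pos == s & substr(i3$kind, 1, 1) == "G"
    expect_equal(unname(rowSums(b3[, sel, drop = FALSE])),
                 unname(b1[, paste0("1mer:G@", s)]))
  }
})

test_that("shape encoding normalizes by table minimum and dataset sd", {
  tab <- gen_shape_table(3)
  words <- random_words(40, 10, seed = 2)
  x <- encode_shape(words, tab)
  info <- attr(x, "col_info")
  prm <- attr(x, "params")
  # spreadsheet check on one cell: (value - min) / sd
  prof <- predict_shape(words, tab)
  v <- prof$MGW[5, 4]
  expect_equal(unname(x[5, "shape1:MGW@4"]),
               (v - min(tab$MGW)) / prm$sd[["MGW"]])
  # a value at the table minimum encodes as zero
  amin <- tab$pentamer[which.min(tab$MGW)]
  w0 <- paste0("AA", amin, "AAA")   # pentamer occupies 3..7, centered at 5
  x0 <- encode_shape(w0, tab, params = prm)
  expect_equal(unname(x0[1, "shape1:MGW@5"]), 0)
  # second-order = product of adjacent first-order, scaled by product sd
  p4 <- (prof$MGW[, 4] - min(tab$MGW)) / prm$sd[["MGW"]]
  p5 <- (prof$MGW[, 5] - min(tab$MGW)) / prm$sd[["MGW"]]
  expect_equal(unname(x[, "shape2:MGW@4"]), p4 * p5 / prm$sd2[["MGW"]])
  # definedness: second-order exists only where both neighbors do
  expect_true("shape2:MGW@7" %in% info$label)   # 7 and 8 defined for L=10
  expect_false("shape2:MGW@8" %in% info$label)  # 9 undefined
})

test_that("constant features are dropped with a warning", {
  tab <- gen_shape_table(3)
  df <- as.data.frame(unclass(tab)); df$ProT <- -8
  tab2 <- shape_table(df)
  expect_warning(x <- encode_shape(random_words(20, 10, seed = 3), tab2),
                 "constant ProT")
  expect_false(any(grepl("ProT", colnames(x))))
})

test_that("the shape_i bundle has 12 features at interior positions", {
  tab <- gen_shape_table(3)
  words <- random_words(30, 12, seed = 4)
  dm <- design_matrix(words, c("1mer", "shape"), tab)
  interior <- 5
  cols <- shape_group_columns(dm, interior)
  expect_length(cols, 12)
  expect_setequal(cols, c("shape1:MGW@5", "shape1:ProT@5", "shape1:Roll@5",
                          "shape1:HelT@5", "shape1:Roll@6", "shape1:HelT@6",
                          "shape2:MGW@5", "shape2:MGW@6", "shape2:ProT@5",
                          "shape2:ProT@6", "shape2:Roll@5", "shape2:HelT@5"))
  # boundary groups are clipped, never invent columns
  expect_lt(length(shape_group_columns(dm, 10)), 12)
  expect_equal(shape_positions(dm), 3:10)
  # L = 10 words give exactly 6 MGW first-order columns
  dm10 <- design_matrix(random_words(30, 10, seed = 5), "shape", tab)
  expect_equal(sum(dm10$col_info$group == "shape1" &
                     dm10$col_info$kind == "MGW"), 6)
})

test_that("E2/NoE2 variants partition k-mer windows by end overlap", {
  tab <- gen_shape_table(3)
  words <- random_words(30, 12, seed = 6)
  dm <- design_matrix(words, c("1mer", "3mer"), tab)
  e2 <- apply_variant(dm, "3mer", "E2")
  noe2 <- apply_variant(dm, "3mer", "NoE2")
  starts_e2 <- sort(unique(e2$col_info$pos[e2$col_info$group == "3merE2"]))
  expect_equal(starts_e2, c(1, 2, 9, 10))
  starts_no <- sort(unique(noe2$col_info$pos[noe2$col_info$group == "3merNoE2"]))
  expect_equal(starts_no, 3:8)
  # complementarity: E2 + NoE2 columns = all 3mer columns
  expect_equal(sum(e2$col_info$group == "3merE2") +
                 sum(noe2$col_info$group == "3merNoE2"),
               sum(dm$col_info$group == "3mer"))
  # groups requested directly give the same column sets
  dm_e2 <- design_matrix(words, c("1mer", "3merE2"), tab)
  expect_setequal(dm_e2$col_info$label, e2$col_info$label)
})

test_that("palindromic symmetrization averages rc-corresponding encodings", {
  tab <- gen_shape_table(11, rc_symmetric = TRUE)
  words <- random_words(30, 8, seed = 7)
  dm_raw <- design_matrix(words, "1mer", tab)
  dm_sym <- design_matrix(words, "1mer", tab, palindrome = TRUE,
                          core = "CACGTG")
  dm_rc <- design_matrix(revcomp(words), "1mer", tab)
  expect_equal(dm_sym$x, (dm_raw$x + dm_rc$x) / 2)
  # symmetrize(w) == symmetrize(revcomp(w))
  dm_sym_rc <- design_matrix(revcomp(words), "1mer", tab, palindrome = TRUE,
                             core = "CACGTG")
  expect_equal(unname(dm_sym$x), unname(dm_sym_rc$x))
  # idempotence on a self-reverse-complement word
  pal_word <- "ACGCGT"
  d1 <- design_matrix(pal_word, "1mer", tab, palindrome = TRUE, core = "CACGTG")
  d0 <- design_matrix(pal_word, "1mer", tab)
  expect_equal(d1$x, d0$x)
  # non-palindromic core: warning and no-op
  expect_warning(dnp <- design_matrix(words, "1mer", tab, palindrome = TRUE,
                                      core = "ACGTAC"), "not palindromic")
  expect_equal(dnp$x, dm_raw$x)
})

test_that("per-position feature counts match the published arithmetic", {
  expect_equal(per_position_feature_count(c("1mer", "shape")), 12L)
  expect_equal(per_position_feature_count(c("1mer", "2mer", "3mer")), 84L)
  expect_equal(per_position_feature_count("3mer"), 64L)
  expect_equal(per_position_feature_count(c("1mer", "shape1")), 8L)
  expect_error(per_position_feature_count("4mer"), "unknown")
})

test_that("column count formulas hold exactly", {
  words <- random_words(10, 9, seed = 8)
  L <- 9
  expect_equal(ncol(encode_kmers(words, 1)), 4 * L)
  expect_equal(ncol(encode_kmers(words, 2)), 16 * (L - 1))
  expect_equal(ncol(encode_kmers(words, 3)), 64 * (L - 2))
})
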