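test_that("IUPAC matching follows the standard code table", {
  # full enumeration against the definition sets
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  for (sym in names(sets)) {
    for (b in c("A", "C", "G", "T")) {
      expect_identical(iupac_matches(sym, b), b %in% sets[[sym]])
    }
  }
  expect_true(iupac_matches("N", "G"))
  expect_false(iupac_matches("R", "C"))
  expect_true(iupac_matches("W", "T"))
  expect_error(iupac_matches("X", "A"), "IUPAC")
  expect_error(iupac_matches("A", "N"), "base")
})

test_that("degeneracy weights and weighted core lengths match the policy", {
  expect_equal(degenerate_weight("A"), 1)
  expect_equal(degenerate_weight("N"), 0.25)
  expect_equal(degenerate_weight("R"), 0.5)
  expect_equal(degenerate_weight("B"), 1 / 3)
  expect_equal(weighted_core_length("CANNTG"), 4.5)
  expect_equal(weighted_core_length("ATAAAA"), 6)
  expect_equal(weighted_core_length("NNNN"), 1.0)
  expect_error(weighted_core_length(""), "empty")
})

test_that("mismatch budget follows floor((weighted-4)/2)+1 and clamps at 0", {
  expect_equal(allowed_mismatches("ATAAAA"), 2L)
  expect_equal(allowed_mismatches("CANNTG"), 1L)
  expect_equal(allowed_mismatches("TAAATTA"), 2L)
  expect_equal(allowed_mismatches("NNNN"), 0L)   # weighted length 1 < 4
  # monotone non-decreasing in weighted length over random motifs
  set.seed(11)
  syms <- names(selexshape:::IUPAC_SETS)
  motifs <- replicate(60, paste(sample(syms, sample(4:9, 1), TRUE),
                                collapse = ""))
  wl <- vapply(motifs, weighted_core_length, numeric(1))
  am <- vapply(motifs, allowed_mismatches, integer(1))
  o <- order(wl)
  expect_true(all(diff(am[o]) >= 0))
})

test_that("count_mismatches agrees with per-position brute force", {
  expect_equal(count_mismatches("TAAT", "TAAT"), 0)
  expect_equal(count_mismatches("CAGGTG", "CANNTG"), 0)
  expect_equal(count_mismatches("CATTTG", "CANNTG"), 0)  # N and T both admit T
  expect_equal(count_mismatches("CATTGG", "CANNTG"), 1)  # G vs T at position 5
  brute <- function(w, m) {
    sum(mapply(function(a, b) !iupac_matches(b, a),
               strsplit(w, "")[[1]], strsplit(m, "")[[1]]))
  }
  set.seed(3)
  for (i in 1:50) {
    m <- paste(sample(names(selexshape:::IUPAC_SETS), 6, TRUE), collapse = "")
    w <- random_words(1, 6, seed = i)
    expect_equal(count_mismatches(w, m), brute(w, m))
  }
  expect_error(count_mismatches("TA", "TAAT"), "length")
})

test_that("every word in a motif's expansion has zero mismatches", {
  for (m in c("CANNTG", "TRAY", "WSNK")) {
    for (w in expand_motif(m)) expect_equal(count_mismatches(w, m), 0)
  }
})

test_that("scan_read finds unique sites and reports discard reasons", {
  m <- core_motif("TACGGT")   # allowed_mismatches = 2, strict threshold 1
  # single exact occurrence, ample flanks
  r <- scan_read("AAAAATACGGTCCCCC", m, flank_len = 2)
  expect_equal(r$status, "hit")
  expect_equal(r$mismatches, 0)
  expect_equal(r$start, 6)
  expect_equal(r$strand, "+")
  expect_equal(r$mword, "AATACGGTCC")
  # two exact occurrences -> multiple sites
  expect_equal(scan_read("TACGGTAAATACGGTA", m, 0)$status, "multiple_sites")
  # core flush at read start with flank requirement -> short flank
  expect_equal(scan_read("TACGGTCCCCCCCCCC", m, 2)$status, "short_flank")
  # no site anywhere
  expect_equal(scan_read("CCCCCCCCCCCCCCCC", m, 0)$status, "no_site")
  # N in read
  expect_equal(scan_read("AAAAATNCGGTCCCCC", m, 0)$status, "non_acgt")
})

test_that("reverse-strand hits are found, oriented, and ties discarded", {
  m <- core_motif("TACGGT")
  read <- "AAAAATACGGTCCCCC"
  rc <- revcomp(read)
  fwd <- scan_read(read, m, 2)
  rev_ <- scan_read(rc, m, 2)
  expect_equal(rev_$status, "hit")
  expect_equal(rev_$strand, "-")
  expect_equal(rev_$mismatches, fwd$mismatches)
  expect_equal(rev_$mword, fwd$mword)  # reported in motif orientation
  # palindrome-like tie: exact site matched equally on both strands
  pal <- core_motif("ACCGGT")
  expect_equal(scan_read("AAAAACCGGTAAAAA", pal, 0)$status,
               "ambiguous_strand")
})

test_that("scanner agrees with Biostrings pattern matching on random pools", {
  skip_if_not_installed("Biostrings")
  m <- core_motif("ACGTAC")
  set.seed(5)
  reads <- random_words(300, 16, seed = 5)
  sc <- scan_pool(reads, m, flank_len = 0)
  am <- m$allowed_mismatches
  for (i in seq_len(60)) {
    s <- Biostrings::DNAString(reads[i])
    inb <- function(v) sum(Biostrings::start(v) >= 1 &
                             Biostrings::end(v) <= length(s))
    nf <- Biostrings::matchPattern(m$symbols, s, max.mismatch = am,
                                   fixed = "subject")
    nr <- Biostrings::matchPattern(revcomp(m$symbols), s, max.mismatch = am,
                                   fixed = "subject")
    any_loose <- inb(nf) + inb(nr) > 0
    expect_equal(sc$status[i] != "no_site", any_loose)
    if (sc$status[i] == "hit") {
      # reported mismatch count is achievable per Biostrings at that start
      w <- substr(reads[i], sc$start[i], sc$start[i] + 5)
      mm <- min(count_mismatches(w, m), count_mismatches(revcomp(w), m))
      expect_equal(sc$mismatches[i], mm)
    }
  }
})

test_that("seed selection scores substrings against the catalogue", {
  s <- select_core_from_catalog("TAAT", list("TAAT"))
  expect_equal(s$chosen_core$symbols, "TAAT")
  expect_equal(s$score1, 1)
  expect_equal(s$score2, 1)

  s <- select_core_from_catalog("NNTAATNN", list("TAAT"))
  expect_equal(s$start, 3)
  expect_equal(s$end, 6)
  expect_equal(s$score1, 1)

  # brute-force oracle over all offsets for score1
  seed <- "TGACGTCA"
  cat <- c("TGACGT", "TTACGT")
  brute_best <- function(seed, motif) {
    n <- nchar(seed); k <- nchar(motif)
    max(vapply(1:(n - k + 1), function(o) {
      mean(substring(seed, o:(o + k - 1), o:(o + k - 1)) ==
             substring(motif, 1:k, 1:k))
    }, numeric(1)))
  }
  s <- select_core_from_catalog(seed, cat)
  expect_equal(s$catalog_motif, "TGACGT")
  expect_equal(s$score1, brute_best(seed, "TGACGT"))
  expect_gt(brute_best(seed, "TGACGT"), brute_best(seed, "TTACGT"))

  # set agreement counts R==R but also A vs A; score2 breaks exact ties
  s <- select_core_from_catalog("ARTT", list("ARTT", "AATT"))
  expect_equal(s$catalog_motif, "ARTT")
  expect_equal(s$score2, 1)
  expect_error(suppressWarnings(
    select_core_from_catalog("ACG", list("ACGTACGT"))), "no usable")
})
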