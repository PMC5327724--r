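# centering/scaling constants used to express shape energies in
# dimensionless units (roughly midrange and sd of the plausible ranges)
SHAPE_CENTER <- c(MGW = 4.75, ProT = -8.5, Roll = 0.5, HelT = 35)
SHAPE_SCALE <- c(MGW = 1.0, ProT = 4.9, Roll = 4.9, HelT = 2.9)

#' Ground-truth binding model for the HT-SELEX simulator
#'
#' Defines relative binding affinity over M-words as
#' `affinity(w) = exp(scale * (sum of per-position sequence energies +
#' sum of shape energies))`, where shape energies are
#' `beta * (feature - center) / unit` with fixed per-kind centering
#' constants. Energies are in natural-log units; affinity is always
#' positive.
#'
#' @param core IUPAC core motif (string or [core_motif()]).
#' @param flank_len Flank length per side; the M-word length is the core's
#'   literal length plus twice this.
#' @param table [shape_table()] used as the true structure (also the table
#'   handed to models when testing recovery).
#' @param seq_energy 4 x M matrix (rows A/C/G/T) of per-position sequence
#'   energies; default all zero.
#' @param shape_beta data.frame with columns `kind` (MGW/ProT/Roll/HelT),
#'   `pos`, `beta`; default none.
#' @param scale Temperature-like global multiplier on energies (default 1).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(core, flank_len, table, seq_energy = NULL,
                         shape_beta = NULL, scale = 1) {
  core <- .as_core_motif(core)
  M <- core$literal_length + 2L * flank_len
  if (is.null(seq_energy)) {
    seq_energy <- matrix(0, 4, M, dimnames = list(BASES, NULL))
  }
  stopifnot(nrow(seq_energy) == 4, ncol(seq_energy) == M)
  rownames(seq_energy) <- BASES
  if (!is.null(shape_beta)) {
    stopifnot(all(c("kind", "pos", "beta") %in% names(shape_beta)),
              all(shape_beta$kind %in% SHAPE_KINDS),
              all(shape_beta$pos >= 1 & shape_beta$pos <= M))
  }
  if (all(seq_energy == 0) && (is.null(shape_beta) || nrow(shape_beta) == 0) )
    warning("flat energy landscape: all affinities equal")
  structure(list(core = core, flank_len = as.integer(flank_len), M = M,
                 table = table, seq_energy = seq_energy,
                 shape_beta = shape_beta, scale = scale),
            class = "ground_truth")
}

#' Relative binding affinity of M-words under a ground-truth model
#'
#' @param truth A [ground_truth()] model.
#' @param mwords Character vector of M-words of the truth's length M.
#' @return Positive numeric affinities (arbitrary relative units).
#' @export
affinity <- function(truth, mwords) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(nchar(mwords) != truth$M)) stop("M-words must have length ", truth$M)
  C <- .code_matrix(mwords)
  E <- numeric(length(mwords))
  for (j in seq_len(truth$M)) E <- E + truth$seq_energy[C[, j] + 1L, j]
  if (!is.null(truth$shape_beta) && nrow(truth$shape_beta) > 0) {
    prof <- predict_shape(mwords, truth$table)
    for (r in seq_len(nrow(truth$shape_beta))) {
      kind <- truth$shape_beta$kind[r]
      pos <- truth$shape_beta$pos[r]
      v <- prof[[kind]][, pos]
      if (anyNA(v)) stop(kind, " undefined at position ", pos)
      E <- E + truth$shape_beta$beta[r] *
        (v - SHAPE_CENTER[[kind]]) / SHAPE_SCALE[[kind]]
    }
  }
  exp(truth$scale * E)
}

#' Simulation configuration
#'
#' @param pool_size Reads sequenced per round (default 30000).
#' @param read_length Oligonucleotide design length (default 16).
#' @param rounds Number of selection rounds (default 4; at least 3 so the
#'   scoring round floor is exercised).
#' @param pcr_rate Expected fraction of PCR duplicates injected per round
#'   (default 0.05).
#' @param seed RNG seed for the whole experiment.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(pool_size = 30000, read_length = 16, rounds = 4,
                       pcr_rate = 0.05, seed = 1) {
  stopifnot(rounds >= 1, pool_size >= 1, pcr_rate >= 0, pcr_rate < 1)
  structure(list(pool_size = as.integer(pool_size),
                 read_length = as.integer(read_length),
                 rounds = as.integer(rounds),
                 pcr_rate = pcr_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an HT-SELEX experiment
#'
#' Round 0 is a background pool in which every read carries one planted
#' core-motif site (a random realization of the IUPAC core) at a uniform
#' offset leaving full flanks, embedded in uniform random sequence. Each
#' selection round multiplies read frequencies by the ground-truth
#' affinity of the read's M-word, renormalizes, and draws `pool_size`
#' reads multinomially; PCR duplicates are then injected at `pcr_rate`.
#' Identical seeds give byte-identical pools.
#'
#' @param truth A [ground_truth()] model.
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, per-round files
#'   `round_<i>.txt` are written.
#' @return Object of class `selex_sim`: `pools` (list of [read_pool()]s
#'   for rounds 0..rounds), `truth`, `config`, plus per-initial-read
#'   `mwords` and `affinities`.
#' @export
simulate_experiment <- function(truth, cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  Lr <- cfg$read_length; Lm <- truth$core$literal_length
  fl <- truth$flank_len; n <- cfg$pool_size
  if (Lm + 2 * fl > Lr) stop("core plus flanks longer than the read")
  set.seed(cfg$seed)
  bg <- matrix(sample(BASES, n * Lr, replace = TRUE), n, Lr)
  core_ch <- .chars(truth$core$symbols)
  core_mat <- vapply(core_ch, function(sym)
    sample(IUPAC_SETS[[sym]], n, replace = TRUE), character(n))
  offs <- sample((fl + 1):(Lr - Lm - fl + 1), n, replace = TRUE)
  for (j in seq_len(Lm)) bg[cbind(seq_len(n), offs + j - 1L)] <- core_mat[, j]
  reads <- do.call(paste0, as.data.frame(bg, stringsAsFactors = FALSE))
  mwords <- substr(reads, offs - fl, offs + Lm - 1L + fl)
  aff <- affinity(truth, mwords)

  pools <- list(read_pool(reads, 0))
  counts <- rep(1, n)
  for (i in seq_len(cfg$rounds)) {
    p <- counts * aff
    p <- p / sum(p)
    counts <- as.vector(stats::rmultinom(1, size = cfg$pool_size, prob = p))
    dup <- if (cfg$pcr_rate > 0) stats::rbinom(n, counts, cfg$pcr_rate)
           else integer(n)
    pools[[i + 1]] <- read_pool(rep(reads, counts + dup), i)
  }
  names(pools) <- paste0("round", 0:cfg$rounds)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(pools))
      write_pool(pools[[i]], file.path(dir, paste0("round_", i - 1, ".txt")))
  }
  structure(list(pools = pools, truth = truth, config = cfg,
                 mwords = mwords, affinities = aff, offsets = offs),
            class = "selex_sim")
}

#' @export
print.selex_sim <- function(x, ...) {
  cat("Simulated HT-SELEX experiment: core ", x$truth$core$symbols,
      ", M = ", x$truth$M, ", ", x$config$rounds, " rounds of ",
      x$config$pool_size, " reads\n", sep = "")
  invisible(x)
}

#' Enumerate all M-words consistent with a core motif
#'
#' All exact-core realizations with every flank combination — the state
#' space of the noiseless enrichment recursion.
#'
#' @param core IUPAC core (string or [core_motif()]).
#' @param flank_len Flank length per side.
#' @return Character vector of M-words.
#' @export
enumerate_mwords <- function(core, flank_len) {
  core <- .as_core_motif(core)
  cores <- expand_motif(core)
  if (flank_len == 0) return(sort(cores))
  flanks <- expand_motif(core_motif(strrep("N", flank_len)))
  out <- outer(flanks, cores, paste0)
  out <- outer(as.vector(out), flanks, paste0)
  sort(as.vector(out))
}

#' Exact (noiseless) enrichment of M-word frequencies
#'
#' Propagates frequencies deterministically: `f_i(w)` is proportional to
#' `f_0(w) * affinity(w)^i`. Under i-th-root scoring against the true
#' initial frequencies, scores are exactly proportional to affinities.
#'
#' @param truth A [ground_truth()] model.
#' @param mwords M-words (default: [enumerate_mwords()] of the truth).
#' @param freq0 Initial frequencies (default uniform over `mwords`).
#' @param round_index Selection round i.
#' @return data.frame with `mword`, `freq0`, `freq_i`, `affinity`.
#' @export
exact_enrichment <- function(truth, round_index, mwords = NULL,
                             freq0 = NULL) {
  if (is.null(mwords)) mwords <- enumerate_mwords(truth$core, truth$flank_len)
  if (is.null(freq0)) freq0 <- rep(1 / length(mwords), length(mwords))
  stopifnot(length(freq0) == length(mwords), all(freq0 > 0))
  freq0 <- freq0 / sum(freq0)
  a <- affinity(truth, mwords)
  fi <- freq0 * a^round_index
  fi <- fi / sum(fi)
  data.frame(mword = mwords, freq0 = freq0, freq_i = fi, affinity = a,
             stringsAsFactors = FALSE)
}

.random_words <- function(n, L) {
  m <- matrix(sample(BASES, n * L, replace = TRUE), n, L)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# records table for a hand-built QC fixture; est_freq0 back-derived so
# that score = (freq/est_freq0)^(1/round) holds by construction
.fixture_dataset <- function(words, counts, scores, core, flank_len,
                             round_index = 4, tf_name = NA_character_) {
  freq <- counts / sum(counts)
  rec <- data.frame(mword = words, count = counts, freq = freq,
                    est_freq0 = freq / scores^round_index, score = scores,
                    stringsAsFactors = FALSE)
  mword_dataset(rec, core, flank_len, round_index, tf_name)
}

#' Named catalogue of synthetic test fixtures
#'
#' Builds, from one seed, the scenarios the pipeline's behavior is
#' specified on: a stage-1-QC-passing dataset, one dataset failing each
#' stage-1 criterion in isolation, shape-driven and sequence-only
#' simulated experiments, a palindromic-core experiment, and a pool
#' contaminated with multi-site reads. A `manifest` entry documents each
#' fixture's ground truth.
#'
#' @param seed Integer seed.
#' @param pool_size Pool size for the simulated experiments (default
#'   20000, enough for informative scores while staying fast).
#' @return Named list of fixtures plus `manifest`.
#' @export
make_fixture_suite <- function(seed = 1, pool_size = 20000) {
  set.seed(seed)
  table <- gen_shape_table(seed)
  core <- core_motif("ACGTAC")
  fl <- initial_flank_length(core$literal_length)

  n_ok <- 1500
  words <- unique(.random_words(3 * n_ok, 10))[seq_len(n_ok)]
  qc_pass <- .fixture_dataset(words, counts = sample(9:60, n_ok, TRUE) +
                                c(150, rep(0, n_ok - 1)),
                              scores = stats::runif(n_ok, 0.8, 2.2),
                              core, fl, tf_name = "qc_pass")
  qc_fail_low_counts <- .fixture_dataset(words, rep(5, n_ok),
                                         stats::runif(n_ok, 0.8, 2.2),
                                         core, fl, tf_name = "qc_fail_low_counts")
  qc_fail_sample_size <- .fixture_dataset(words[1:400],
                                          sample(9:200, 400, TRUE) +
                                            c(150, rep(0, 399)),
                                          stats::runif(400, 0.8, 2.2),
                                          core, fl, tf_name = "qc_fail_sample_size")
  qc_fail_variability <- .fixture_dataset(words, sample(9:60, n_ok, TRUE) +
                                            c(150, rep(0, n_ok - 1)),
                                          rep(1.5, n_ok),
                                          core, fl, tf_name = "qc_fail_variability")
  qc_fail_max_count <- .fixture_dataset(words, sample(9:50, n_ok, TRUE),
                                        stats::runif(n_ok, 0.8, 2.2),
                                        core, fl, tf_name = "qc_fail_max_count")

  planted_pos <- fl + 1
  # moderate effect sizes: enrichment strong enough for a clear readout
  # signal but weak enough that round-4 pools keep their word diversity
  flank_energy <- matrix(0, 4, core$literal_length + 2 * fl,
                         dimnames = list(BASES, NULL))
  flank_energy[, c(ncol(flank_energy) - 1, ncol(flank_energy))] <-
    stats::rnorm(8, 0, 0.25)
  shape_truth <- ground_truth(core, fl, table, seq_energy = flank_energy,
                              shape_beta = data.frame(kind = "MGW",
                                                      pos = planted_pos,
                                                      beta = 0.5))
  shape_driven <- simulate_experiment(shape_truth,
                                      sim_config(pool_size = pool_size,
                                                 seed = seed))
  seq_energy <- matrix(0, 4, shape_truth$M, dimnames = list(BASES, NULL))
  seq_energy[, c(1, 2, shape_truth$M - 1, shape_truth$M)] <-
    stats::rnorm(16, 0, 0.25)
  seq_truth <- ground_truth(core, fl, table, seq_energy = seq_energy)
  sequence_only <- simulate_experiment(seq_truth,
                                       sim_config(pool_size = pool_size,
                                                  seed = seed + 1))
  pal_truth <- ground_truth("CACGTG", 2, table,
                            shape_beta = data.frame(kind = "MGW", pos = 3,
                                                    beta = 0.5))
  palindromic <- simulate_experiment(pal_truth,
                                     sim_config(pool_size = pool_size,
                                                seed = seed + 2))

  # multi-site contamination: re-plant a second exact core into a known
  # fraction of round-0 reads
  contaminated <- shape_driven$pools$round0$reads
  frac <- 0.1
  n_bad <- floor(frac * length(contaminated))
  # only reads whose planted site leaves the first Lm positions free, so
  # the injected second site never corrupts the original one
  candidates <- which(shape_driven$offsets > core$literal_length + 1)
  bad_idx <- sample(candidates, min(n_bad, length(candidates)))
  site <- expand_motif(core)[1]
  substr(contaminated[bad_idx], 1, core$literal_length) <- site
  multi_site <- read_pool(contaminated, 0)

  list(qc_pass = qc_pass,
       qc_fail_low_counts = qc_fail_low_counts,
       qc_fail_sample_size = qc_fail_sample_size,
       qc_fail_variability = qc_fail_variability,
       qc_fail_max_count = qc_fail_max_count,
       shape_driven = shape_driven,
       sequence_only = sequence_only,
       palindromic = palindromic,
       multi_site = list(pool = multi_site, contaminated_fraction = frac,
                         contaminated_index = bad_idx),
       manifest = list(
         seed = seed, table_seed = seed, core = core$symbols,
         flank_len = fl, planted_shape = list(kind = "MGW",
                                              pos = planted_pos,
                                              beta = 1.2),
         qc_fixtures = c("qc_pass passes all stage-1 criteria",
                         "qc_fail_low_counts: every count <= 8",
                         "qc_fail_sample_size: < 1000 words after filter",
                         "qc_fail_variability: p90 - p10 spread < 0.2",
                         "qc_fail_max_count: max count < 100"),
         multi_site_fraction = frac))
}
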