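# Shared simulation helpers: one seeded experiment -> scored dataset.

test_shape_table <- function(seed = 7) gen_shape_table(seed)

# ground truth with a single planted MGW readout position plus weak 1mer
# energies at the 3' flank (so the 1mer baseline has signal)
shape_truth <- function(table, beta = 0.5, planted_pos = 3, seed = 99,
                        core = "ACGTAC", flank = 2) {
  cm <- core_motif(core)
  M <- cm$literal_length + 2 * flank
  se <- matrix(0, 4, M, dimnames = list(c("A", "C", "G", "T"), NULL))
  set.seed(seed)
  se[, c(M - 1, M)] <- rnorm(8, 0, 0.25)
  ground_truth(cm, flank, table, seq_energy = se,
               shape_beta = data.frame(kind = "MGW", pos = planted_pos,
                                       beta = beta))
}

seq_truth <- function(table, seed = 99, core = "ACGTAC", flank = 2) {
  cm <- core_motif(core)
  M <- cm$literal_length + 2 * flank
  se <- matrix(0, 4, M, dimnames = list(c("A", "C", "G", "T"), NULL))
  set.seed(seed)
  se[, c(1, 2, M - 1, M)] <- rnorm(16, 0, 0.25)
  ground_truth(cm, flank, table, seq_energy = se)
}

# run simulator + scoring for a truth; returns the scored dataset
scored_dataset <- function(truth, seed, pool_size = 30000, rounds = 4) {
  sim <- simulate_experiment(truth, sim_config(pool_size = pool_size,
                                               rounds = rounds, seed = seed))
  bg <- fit_markov(sim$pools$round0)
  ct <- count_mwords(sim$pools[[paste0("round", rounds)]], truth$core,
                     truth$flank_len)
  score_mwords(ct, bg, rounds, truth$core, truth$flank_len)
}

random_words <- function(n, L, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
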