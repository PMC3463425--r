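# shared test fixtures, built in code

# width-2 matrix with unanimous columns (pseudocount 0, uniform background):
# log-odds 2.0 for A1/C2, -Inf elsewhere
tiny_wm <- function() {
  build_weight_matrix(build_pfm(c("AC", "AC"), pseudocount = 0))
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1L))
}

# small synthetic spec for fast end-to-end tests
small_spec <- function(seed = 11L, ...) {
  synthetic_spec(seed = seed, genome_length = 60000L, n_operons = 15L,
                 n_strong = 5L, n_weak = 5L, n_activating = 2L,
                 n_decoy = 3L, ...)
}
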