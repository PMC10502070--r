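# shared helpers for the suite

# the eight input states in the fixed abscissa order
all_states <- function() {
  matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1,
           1, 1, 0, 1, 0, 1, 0, 1, 1, 1, 1, 1),
         ncol = 3, byrow = TRUE)
}

# bits of a gate over all eight states, logical engine
logic_bits <- function(gate) {
  st <- all_states()
  vapply(seq_len(nrow(st)), function(r) evaluate_gate(gate, st[r, ]), 0L)
}

# all subsets of {1,2,3} as index vectors
input_subsets <- function() {
  st <- all_states()
  lapply(seq_len(nrow(st)), function(r) which(st[r, ] == 1))
}

# deterministic pool of random fixtures within the oracle's size bounds
random_fixture_pool <- function(n_fixtures, seed = 2024) {
  set.seed(seed)
  sizes <- sample(4:8, n_fixtures, replace = TRUE)
  lapply(seq_len(n_fixtures), function(i)
    generate_fixture("random-valid", sizes[i], seed = i))
}
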