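# small in-code fixtures shared across test files

# normalized binary dataset with a clear class signal on the first k columns
make_normalized_dataset <- function(n = 200, m = 6, k = 2, effect = 2,
                                    seed = 1, class_count = 2) {
  d <- generate_synthetic_tabular(synthetic_spec(n, m, k, effect_size = effect,
                                                 class_count = class_count,
                                                 seed = seed))
  apply_minmax(d, fit_minmax(d))
}

# dataset where feature 1 equals the label (perfectly separable by one column)
make_copy_label_dataset <- function(n = 60, m = 3, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- cbind(y, matrix(runif(n * (m - 1)), n, m - 1))
  tabular_dataset(X, y)
}

# a short admitted hash chain over synthetic model digests
make_chain <- function(n_blocks = 5, seed = 1) {
  set.seed(seed)
  led <- ledger_create()
  for (i in seq_len(n_blocks)) {
    led <- append_block(led, list(model_digest = sha256_hex(rnorm(4)),
                                  round = i), 0.9)$ledger
  }
  led
}

# honest client updates drawn around a shared optimum
make_honest_updates <- function(n_clients, dim = 100, sd = 1, seed = 1) {
  set.seed(seed)
  base <- rnorm(dim)
  lapply(seq_len(n_clients), function(k) {
    client_update(sprintf("c%02d", k), base + rnorm(dim, sd = sd), 10)
  })
}
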