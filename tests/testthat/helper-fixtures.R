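# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

rand_bag <- function(n, d, id = "b", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new_bag(matrix(rnorm(n * d), n, d), id)
}

rand_bags <- function(n_bags, d, sizes = NULL, seed = 1, prefix = "b") {
  set.seed(seed)
  if (is.null(sizes)) sizes <- sample(1:4, n_bags, replace = TRUE)
  lapply(seq_len(n_bags), function(i) {
    new_bag(matrix(rnorm(sizes[i] * d), sizes[i], d),
            sprintf("%s%03d", prefix, i))
  })
}

rand_dataset <- function(n_bags, d, K, seed = 1, domain = "unsplit",
                         min_pos = 1) {
  set.seed(seed)
  bags <- rand_bags(n_bags, d, seed = seed)
  repeat {
    Y <- matrix(rbinom(n_bags * K, 1, 0.4), n_bags, K)
    if (K == 0 || all(colSums(Y) >= min_pos)) break
  }
  miml_dataset(bags, Y, class_ids = if (K) sprintf("c%02d", seq_len(K)),
               domain = domain)
}

small_shift_config <- function(seed = 1, n_source = 60, n_target = 60,
                               d = 8, K = 3, label_rate = 0.3, ...) {
  generator_config(d = d, K = K, n_source = n_source, n_target = n_target,
                   label_rate = label_rate, seed = seed, ...)
}

# fast hyperparameters for tests that only need a few optimizer sweeps
quick_hp <- function(...) metric_hyperparams(max_iter = 50L, ...)
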