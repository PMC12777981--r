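# Shared fixtures: tiny configs, small random event sets, and a
# finite-difference gradient oracle used by the model tests.

tiny_mcfg <- function(...) {
  model_config(d = 6L, d_k = 4L, d_v = 4L, n_layers = 1L, h = 2L, p1 = 0,
               ffn_dim = 10L, w = 3L, ...)
}

toy_mcfg <- function(backbone = "attention") {
  model_config(d = 32L, d_k = 32L, d_v = 32L, n_layers = 2L, h = 2L, w = 12L,
               backbone = backbone)
}

toy_tcfg <- function(epochs_pretrain = 30L, epochs_finetune = 30L, seed = 1L,
                     ...) {
  train_config(epochs_pretrain = epochs_pretrain,
               epochs_finetune = epochs_finetune, batch_size = 8L,
               seed = seed, ...)
}

random_event_set <- function(n = 5L, len_range = c(4L, 12L), seed = 1L,
                             labels = c("a", "b")) {
  withr::with_seed(seed, {
    events <- lapply(seq_len(n), function(i) {
      event_record(sprintf("ev%03d", i),
                   trace = round(stats::rnorm(sample(len_range[1]:len_range[2], 1)), 6),
                   label = sample(labels, 1), source = "helper")
    })
    event_set(events)
  })
}

# Preprocessed three-class peptide set (moderate noise unless overridden).
abeta_set <- function(n_per_class = 30L, noise_sd = 0.08, seed = 42L) {
  ds <- generate_dataset("peptide", n_per_class = n_per_class,
                         params = peptide_sim_params(noise_sd = noise_sd),
                         seed = seed)
  preprocess_events(ds, 500L, mode = "interpolate", standardize = "none")
}

# Central-difference gradient of f at x (numeric vector), for gradient checks.
numeric_gradient <- function(f, x, idx = seq_along(x), eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}
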