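# Shared fixtures. Everything is generated in code; heavier objects are
# memoised so several test files can reuse them within one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# micro network configuration: fast enough for gradient-level and
# learning-behaviour tests on one CPU
micro_spec <- function(n_streams = 2, input_size = 32) {
  network_spec(n_streams = n_streams, input_size = input_size,
               channels = c(4, 8, 16, 32, 64))
}

micro_phantoms <- function(n_patients = 8, seed = 11, noise_sigma = 0.04,
                           irregularity = 1, n_slices = 2, size = 32) {
  cfg <- phantom_config(
    n_patients = n_patients, image_size = size, n_modalities = 2,
    tumor_area_frac_range = c(0.04, 0.1), tumor_irregularity = irregularity,
    noise_sigma = noise_sigma, n_slices = n_slices, seed = seed)
  normalize_slices(derive_weak_labels(generate_phantoms(cfg)), size = size)
}

micro_train_config <- function(...) {
  args <- modifyList(list(learning_rate = 0.02, batch_size = 8,
                          epochs_round1 = 4, epochs_round2 = 6, seed = 5),
                     list(...))
  do.call(train_config, args)
}

random_mask <- function(n = 16, p = 0.3) {
  matrix(as.numeric(runif(n * n) < p), n, n)
}

# brute-force confusion counting by explicit pixel enumeration -- the
# independent oracle for the metric implementations
brute_counts <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1) fp <- fp + 1L
      else if (truth[i, j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

expect_input_error <- function(expr) {
  expect_error(expr, class = "ellipseg_input_error")
}

expect_config_error <- function(expr) {
  expect_error(expr, class = "ellipseg_config_error")
}
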