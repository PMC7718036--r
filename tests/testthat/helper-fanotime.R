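# Shared fixtures and Monte-Carlo assertion helpers.

# counts 2, 0, 1, 1 on a window of length 2: sample variance 2/3, mean 1
toy_set <- function() {
  spike_train_set(list(c(0.2, 0.9), numeric(0), 0.5, 1.8), window = 2)
}

# build a spike-train set with prescribed per-trial counts (spikes evenly
# spaced inside the window)
set_from_counts <- function(counts, window) {
  spike_train_set(lapply(counts, function(k) {
    if (k == 0) numeric(0) else window * seq_len(k) / (k + 1)
  }), window)
}

expect_within_se <- function(value, target, se, k = 3) {
  expect_lt(abs(value - target), k * se)
}

# Monte-Carlo standard error of a sample mean
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
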