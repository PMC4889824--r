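# Naive loop-based reference implementations of the time-domain features.
# Kept deliberately independent of the vectorised package code.

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

oracle_wamp <- function(x, thr) {
  n <- 0
  for (i in seq_len(length(x) - 1)) {
    if (abs(x[i] - x[i + 1]) >= thr) n <- n + 1
  }
  n
}

oracle_ssc <- function(x, thr) {
  n <- 0
  for (i in 2:(length(x) - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= thr) n <- n + 1
  }
  n
}

# Small labelled two-cluster-per-class fixture for classifier tests:
# k well-separated Gaussian blobs in 2-D.
blob_dataset <- function(k = 6, n_per_class = 12, sep = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- cbind(sep * cos(2 * pi * seq_len(k) / k),
                   sep * sin(2 * pi * seq_len(k) / k))
  labs <- gesture_labels()[seq_len(k)]
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(rnorm(n_per_class, centers[i, 1], sd),
          rnorm(n_per_class, centers[i, 2], sd))
  }))
  df <- data.frame(f1 = x[, 1], f2 = x[, 2],
                   label = factor(rep(labs, each = n_per_class), levels = labs))
  df
}

# Compact synthetic SEMG feature dataset (fewer repetitions than a full
# session, to keep tests quick).
small_semg_dataset <- function(seed = 1, reps = 3, sep = 6,
                               features = "MAV") {
  cfg <- generator_config(reps_per_gesture = reps, class_separation = sep,
                          rng_seed = seed)
  generate_feature_dataset(cfg, feature_config(features))
}

# Tiny deterministic recording with one annotation per gesture.
tiny_recording <- function(n_per_block = 12, fs = 16) {
  labs <- gesture_labels()
  n <- n_per_block * length(labs)
  x <- cbind(flexor = seq_len(n) / n, extensor = rev(seq_len(n)) / n)
  ann <- data.frame(start = (seq_along(labs) - 1L) * n_per_block + 2L,
                    end = seq_along(labs) * n_per_block - 2L,
                    label = labs)
  semg_recording(x, fs, ann)
}
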