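# Small deterministic fixtures shared across test files. Everything is built
# in code at test time; nothing binary ships with the package.

tiny_spec <- function(...) {
  args <- list(n_subjects = 2L, n_sessions = 1L, n_trials_per_session = 15L,
               n_segments_per_trial = 4L, n_channels = 6L, n_bands = 3L,
               n_classes = 3L, seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_spec, args)
}

tiny_fs <- function(...) synth_generate(tiny_spec(...))$data

# a linearly separable two-cluster feature matrix for discriminator sanity fits
separable_clusters <- function(n_per = 60L, d = 8L, gap = 6, k = 2L,
                               seed = 1L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k) - 1L, function(c) {
    center <- rep(0, d); center[c %% d + 1L] <- gap * (c + 1L)
    sweep(matrix(rnorm(n_per * d), n_per, d), 2L, center, `+`)
  }))
  list(x = x, y = rep(seq_len(k) - 1L, each = n_per))
}

# brute-force elementwise BCE used as an independent oracle
loop_bce <- function(y, p) {
  if (length(y) == 1L) y <- rep(y, length(p))
  tot <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], 1e-7), 1 - 1e-7)
    tot <- tot - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  tot / length(p)
}
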