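#' Specification for the synthetic multi-subject EEG benchmark
#'
#' Describes a generated dataset with the three statistical ingredients the
#' adversarial decoder is designed around: class-dependent mean patterns,
#' per-subject distribution shift (a near-identity channel-mixing gain matrix
#' plus a small offset, so adaptation is non-trivial yet linearly
#' correctable), and
#' graph-structured channel correlations (channels grouped into latent
#' communities share band profiles and noise).
#'
#' The defaults define the package's standard benchmark: 6 subjects, 1
#' session, 15 trials of 25 segments, 16 channels, 5 bands, 3 classes, sized
#' so that full protocol sweeps run on a laptop CPU in minutes while leaving
#' clear headroom between the source-only baseline and the adapted models.
#'
#' @param n_subjects,n_sessions,n_trials_per_session,n_segments_per_trial
#'   layout counts.
#' @param n_channels,n_bands,n_classes feature and label dimensions.
#' @param class_separation scale of class-mean differences (in noise SD
#'   units).
#' @param subject_shift scale of the per-subject affine perturbation; 0 turns
#'   domain shift off.
#' @param trial_jitter scale of the per-trial perturbation of the mixing
#'   matrix (trial-to-trial nonstationarity); 0 makes every trial of a
#'   subject share one exact transform.
#' @param graph_strength weight of the shared within-community noise
#'   component; larger values give stronger within-community channel
#'   correlation.
#' @param n_communities number of latent channel communities.
#' @param noise_sd independent per-channel noise level.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 6L, n_sessions = 1L,
                       n_trials_per_session = 15L, n_segments_per_trial = 25L,
                       n_channels = 16L, n_bands = 5L, n_classes = 3L,
                       class_separation = 0.6, subject_shift = 1.0,
                       trial_jitter = 0.8, graph_strength = 1.0,
                       n_communities = 4L, noise_sd = 1.0, seed = 1L) {
  sp <- list(n_subjects = as.integer(n_subjects),
             n_sessions = as.integer(n_sessions),
             n_trials_per_session = as.integer(n_trials_per_session),
             n_segments_per_trial = as.integer(n_segments_per_trial),
             n_channels = as.integer(n_channels), n_bands = as.integer(n_bands),
             n_classes = as.integer(n_classes),
             class_separation = class_separation,
             subject_shift = subject_shift, trial_jitter = trial_jitter,
             graph_strength = graph_strength,
             n_communities = as.integer(n_communities), noise_sd = noise_sd,
             seed = as.integer(seed))
  counts <- unlist(sp[c("n_subjects", "n_sessions", "n_trials_per_session",
                        "n_segments_per_trial", "n_channels", "n_bands",
                        "n_classes", "n_communities")])
  if (any(counts < 1L)) stop("all synth_spec counts must be >= 1", call. = FALSE)
  if (sp$class_separation < 0 || sp$subject_shift < 0 ||
      sp$trial_jitter < 0 || sp$graph_strength < 0 || sp$noise_sd < 0) {
    stop("synth_spec scales must be >= 0", call. = FALSE)
  }
  if (sp$n_communities > sp$n_channels) {
    stop("n_communities cannot exceed n_channels", call. = FALSE)
  }
  structure(sp, class = "synth_spec")
}

#' Generate a synthetic multi-subject feature set
#'
#' For each class `c` a latent mean over (channels x bands) is built from
#' channel communities: channels in the same community share a class-specific
#' band profile scaled by `class_separation`. Each segment of class `c` is a
#' per-subject affine transform of `mu_c` plus community-correlated noise:
#'
#' \deqn{x = G_s (\mu_c + g\,\eta_{comm} + \sigma\,\epsilon) + b_s}
#'
#' with `G_s` a near-identity channel-mixing gain matrix
#' `I + subject_shift * N(0, 1/n_channels)` (each subject observes a slightly
#' different linear combination of the latent channel signals — distorting
#' class geometry across subjects while leaving feature means roughly
#' aligned), offset `b_s ~ 0.2 * subject_shift * N(0,1)` per (channel, band),
#' community noise
#' `eta` shared by all channels of a community within a segment (weight
#' `g = graph_strength`) and independent noise `epsilon` (SD `noise_sd`).
#' Trial `t` carries class `(t-1) mod n_classes`, so ordered trial splits are
#' class-stratified and per-session class priors are balanced.
#'
#' @param spec a [synth_spec()].
#' @return a list with `data` (a [feature_set()]) and `truth` (list with
#'   `communities` — the channel community index —, `class_means`, and
#'   per-subject `gains` / `offsets`).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  N <- spec$n_channels; B <- spec$n_bands; C <- spec$n_classes
  comm <- rep(seq_len(spec$n_communities), length.out = N)
  comm <- sort(comm)
  # class means: community-level band profiles
  class_means <- vector("list", C)
  profs <- array(stats::rnorm(C * spec$n_communities * B),
                 c(C, spec$n_communities, B))
  # center across classes so the class-balanced feature mean is zero and
  # domain differences live in the covariance structure, not trivial means
  profs <- sweep(profs, c(2L, 3L), apply(profs, c(2L, 3L), mean))
  for (c in seq_len(C)) {
    pc <- matrix(profs[c, , ], spec$n_communities, B)
    class_means[[c]] <- spec$class_separation * pc[comm, , drop = FALSE]
  }
  gains <- vector("list", spec$n_subjects)
  offsets <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    gains[[s]] <- diag(N) +
      spec$subject_shift * matrix(stats::rnorm(N * N, sd = 1 / sqrt(N)), N, N)
    offsets[[s]] <- 0.2 * spec$subject_shift * matrix(stats::rnorm(N * B), N, B)
  }
  n_per <- spec$n_segments_per_trial
  total <- spec$n_subjects * spec$n_sessions * spec$n_trials_per_session * n_per
  feats <- array(NA_real_, c(total, N, B))
  labels <- integer(total); subj <- integer(total)
  sess <- integer(total); tri <- integer(total)
  at <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (e in seq_len(spec$n_sessions)) {
      for (t in seq_len(spec$n_trials_per_session)) {
        cls <- (t - 1L) %% C
        mu <- class_means[[cls + 1L]]
        # trial-to-trial nonstationarity: every trial sees its own jittered
        # mixing, drawn from the same family as the subject shift, so the
        # source domain spans a cloud of mixing conditions that overlaps the
        # target's
        g_trial <- gains[[s]] +
          spec$trial_jitter * matrix(stats::rnorm(N * N, sd = 1 / sqrt(N)), N, N)
        for (g in seq_len(n_per)) {
          eta <- matrix(stats::rnorm(spec$n_communities * B),
                        spec$n_communities, B)
          eps <- matrix(stats::rnorm(N * B, sd = spec$noise_sd), N, B)
          x <- mu + spec$graph_strength * eta[comm, , drop = FALSE] + eps
          x <- g_trial %*% x + offsets[[s]]
          at <- at + 1L
          feats[at, , ] <- x
          labels[at] <- cls; subj[at] <- s; sess[at] <- e; tri[at] <- t
        }
      }
    }
  }
  data <- feature_set(feats, labels, subj, sess, tri, n_classes = C)
  list(data = data,
       truth = list(communities = comm, class_means = class_means,
                    gains = gains, offsets = offsets))
}
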