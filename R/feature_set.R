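#' Labeled multi-subject EEG feature container
#'
#' A `feature_set` holds per-segment channel-by-band feature tensors (typically
#' differential-entropy values, one per channel and frequency band) together
#' with the emotion label and subject / session / trial metadata of each
#' segment. All model and protocol functions in the package consume this
#' container.
#'
#' @param features numeric array of dimension
#'   `(n_segments, n_channels, n_bands)`.
#' @param labels integer vector of emotion classes in `0..n_classes-1`, one per
#'   segment. May contain `NA` for unlabeled (target-domain) data.
#' @param subject_id,session_id,trial_id integer vectors, one entry per
#'   segment.
#' @param channel_names,band_names optional character vectors naming the
#'   channel and band axes; defaults `ch1..chN` / `band1..bandB`.
#' @param n_classes number of emotion classes; defaults to
#'   `max(labels) + 1`.
#'
#' @return An object of class `feature_set` with elements `features`,
#'   `labels`, `subject_id`, `session_id`, `trial_id`, `channel_names`,
#'   `band_names`, `n_classes`.
#' @export
feature_set <- function(features, labels, subject_id, session_id, trial_id,
                        channel_names = NULL, band_names = NULL,
                        n_classes = NULL) {
  if (!is.array(features) || length(dim(features)) != 3L) {
    stop("`features` must be a 3-d array (segments x channels x bands)",
         call. = FALSE)
  }
  n <- dim(features)[1L]
  for (nm in c("labels", "subject_id", "session_id", "trial_id")) {
    v <- get(nm)
    if (length(v) != n) {
      stop(sprintf("`%s` has length %d but there are %d segments",
                   nm, length(v), n), call. = FALSE)
    }
  }
  labels <- as.integer(labels)
  if (is.null(n_classes)) {
    n_classes <- if (all(is.na(labels))) 0L else max(labels, na.rm = TRUE) + 1L
  }
  ok <- is.na(labels) | (labels >= 0L & labels < n_classes)
  if (!all(ok)) {
    stop(sprintf("labels must lie in 0..%d", n_classes - 1L), call. = FALSE)
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(features)[2L]))
  if (is.null(band_names)) band_names <- paste0("band", seq_len(dim(features)[3L]))
  stopifnot(length(channel_names) == dim(features)[2L],
            length(band_names) == dim(features)[3L])
  structure(
    list(features = features, labels = labels,
         subject_id = as.integer(subject_id),
         session_id = as.integer(session_id),
         trial_id = as.integer(trial_id),
         channel_names = as.character(channel_names),
         band_names = as.character(band_names),
         n_classes = as.integer(n_classes)),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<feature_set> %d segments, %d channels x %d bands (F = %d)\n",
              d[1L], d[2L], d[3L], d[2L] * d[3L]))
  cat(sprintf("  subjects: %s\n", paste(sort(unique(x$subject_id)), collapse = ", ")))
  cat(sprintf("  sessions: %d, trials/session: up to %d, classes: %d\n",
              length(unique(x$session_id)), max(table(paste(x$subject_id, x$session_id))),
              x$n_classes))
  invisible(x)
}

#' Number of segments in a feature set
#' @param fs a [feature_set()].
#' @return integer segment count.
#' @export
n_segments <- function(fs) dim(fs$features)[1L]

#' Subset a feature set by segment index
#'
#' @param fs a [feature_set()].
#' @param idx integer or logical index over segments.
#' @return a `feature_set` containing the selected segments.
#' @export
fs_subset <- function(fs, idx) {
  feature_set(fs$features[idx, , , drop = FALSE], fs$labels[idx],
              fs$subject_id[idx], fs$session_id[idx], fs$trial_id[idx],
              fs$channel_names, fs$band_names, n_classes = fs$n_classes)
}

#' Concatenate feature sets along the segment axis
#' @param ... `feature_set` objects with identical channel/band axes.
#' @return a single combined `feature_set`.
#' @export
fs_bind <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  ref <- parts[[1L]]
  for (p in parts[-1L]) {
    stopifnot(identical(p$channel_names, ref$channel_names),
              identical(p$band_names, ref$band_names))
  }
  feats <- do.call(abind3, lapply(parts, `[[`, "features"))
  feature_set(feats,
              unlist(lapply(parts, `[[`, "labels")),
              unlist(lapply(parts, `[[`, "subject_id")),
              unlist(lapply(parts, `[[`, "session_id")),
              unlist(lapply(parts, `[[`, "trial_id")),
              ref$channel_names, ref$band_names,
              n_classes = max(vapply(parts, `[[`, integer(1L), "n_classes")))
}

# rbind for 3-d arrays along the first axis
abind3 <- function(...) {
  parts <- list(...)
  d2 <- dim(parts[[1L]])[2L]; d3 <- dim(parts[[1L]])[3L]
  n <- sum(vapply(parts, function(a) dim(a)[1L], integer(1L)))
  out <- array(NA_real_, c(n, d2, d3))
  at <- 0L
  for (a in parts) {
    stopifnot(dim(a)[2L] == d2, dim(a)[3L] == d3)
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

# flatten segments x channels x bands into segments x (channels*bands)
flatten_features <- function(features) {
  d <- dim(features)
  matrix(features, nrow = d[1L], ncol = d[2L] * d[3L])
}
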