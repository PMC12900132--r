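#' Load SEED-style extracted differential-entropy features
#'
#' Reads a directory laid out like the SEED / SEED-IV "ExtractedFeatures"
#' releases: one MAT file per subject and session named
#' `<subject>_<session>.mat` (any non-numeric suffix such as a recording date
#' is also accepted as the session key), each containing one array per trial
#' under variables `de_LDS1, de_LDS2, ...` with dimensions
#' `(n_channels, n_segments, n_bands)`, plus a single `label.mat` file in the
#' directory whose `label` vector gives the native per-trial emotion codes.
#'
#' Native label codes are remapped to contiguous classes `0..C-1`:
#'
#' * `seed` (3 classes): `-1` (negative) -> 0, `0` (neutral) -> 1,
#'   `1` (positive) -> 2;
#' * `seed_iv` (4 classes): native codes `0..3` kept as-is
#'   (neutral, sad, fear, happy).
#'
#' Each stored per-window feature vector is treated as one segment; no
#' re-windowing is performed (the releases ship precomputed per-window DE
#' values). Whatever segment count the files contain is accepted and recorded.
#'
#' @param path directory containing the MAT files.
#' @param dataset_variant `"seed"` (3-class) or `"seed_iv"` (4-class).
#' @return a [feature_set()] with `features` ordered (segment, channel, band)
#'   and subject / session / trial metadata populated.
#' @export
load_seed_features <- function(path, dataset_variant = c("seed", "seed_iv")) {
  dataset_variant <- match.arg(dataset_variant)
  if (!dir.exists(path)) {
    stop(sprintf("feature directory does not exist: %s", path), call. = FALSE)
  }
  files <- list.files(path, pattern = "\\.mat$", full.names = TRUE)
  label_file <- files[basename(files) == "label.mat"]
  files <- setdiff(files, label_file)
  if (length(files) == 0L) {
    stop(sprintf("no per-subject feature MAT files found under %s", path),
         call. = FALSE)
  }
  parsed <- regmatches(basename(files),
                       regexec("^([0-9]+)_(.+)\\.mat$", basename(files)))
  bad <- vapply(parsed, length, integer(1L)) != 3L
  if (any(bad)) {
    stop(sprintf("file name not in <subject>_<session>.mat form: %s",
                 basename(files)[bad][1L]), call. = FALSE)
  }
  subj <- as.integer(vapply(parsed, `[`, character(1L), 2L))
  sess_key <- vapply(parsed, `[`, character(1L), 3L)

  trial_labels <- NULL
  if (length(label_file) == 1L) {
    lm <- read_mat(label_file)
    if (is.null(lm$label)) {
      stop(sprintf("%s: no 'label' variable", label_file), call. = FALSE)
    }
    trial_labels <- as.vector(lm$label)
  }

  parts <- vector("list", length(files))
  for (i in seq_along(files)) {
    vars <- read_mat(files[i])
    de_names <- grep("^de_LDS[0-9]+$", names(vars), value = TRUE)
    if (length(de_names) == 0L) {
      stop(sprintf("%s: no de_LDS<trial> arrays found", files[i]), call. = FALSE)
    }
    trials <- sort(as.integer(sub("^de_LDS", "", de_names)))
    lab_vec <- trial_labels
    if (is.null(lab_vec)) {
      if (is.null(vars$label)) {
        stop(sprintf("%s: no label.mat in directory and no 'label' variable in file",
                     files[i]), call. = FALSE)
      }
      lab_vec <- as.vector(vars$label)
    }
    if (length(lab_vec) < max(trials)) {
      stop(sprintf("%s: label vector has %d entries but trial %d present",
                   files[i], length(lab_vec), max(trials)), call. = FALSE)
    }
    tr_parts <- vector("list", length(trials))
    for (j in seq_along(trials)) {
      t <- trials[j]
      a <- vars[[paste0("de_LDS", t)]]
      if (!is.array(a) || length(dim(a)) != 3L) {
        stop(sprintf("%s: variable 'de_LDS%d' is not a 3-d array", files[i], t),
             call. = FALSE)
      }
      # native layout (channels, segments, bands) -> (segments, channels, bands)
      a <- aperm(a, c(2L, 1L, 3L))
      nseg <- dim(a)[1L]
      cls <- remap_label(lab_vec[t], dataset_variant)
      tr_parts[[j]] <- feature_set(
        a, rep(cls, nseg), rep(subj[i], nseg),
        rep(NA_integer_, nseg), rep(t, nseg),
        n_classes = if (dataset_variant == "seed") 3L else 4L)
    }
    parts[[i]] <- do.call(fs_bind, tr_parts)
  }
  # session ids: ordinal of the session key within each subject
  fs <- do.call(fs_bind, parts)
  sess_of_file <- integer(length(files))
  for (s in unique(subj)) {
    k <- which(subj == s)
    sess_of_file[k] <- match(sess_key[k], sort(unique(sess_key[k])))
  }
  seg_file <- rep(seq_along(files),
                  vapply(parts, n_segments, integer(1L)))
  fs$session_id <- sess_of_file[seg_file]
  fs
}

remap_label <- function(code, variant) {
  if (variant == "seed") {
    m <- c("-1" = 0L, "0" = 1L, "1" = 2L)
    out <- m[as.character(as.integer(code))]
    if (is.na(out)) {
      stop(sprintf("native SEED label code %s not in {-1, 0, 1}", code),
           call. = FALSE)
    }
    unname(out)
  } else {
    code <- as.integer(code)
    if (code < 0L || code > 3L) {
      stop(sprintf("native SEED-IV label code %d not in 0..3", code),
           call. = FALSE)
    }
    code
  }
}

unmap_label <- function(cls, variant) {
  if (variant == "seed") c(-1L, 0L, 1L)[cls + 1L] else cls
}

#' Write a feature set in the SEED-style MAT fixture layout
#'
#' Emits one MAT file per (subject, session) named `<subject>_<session>.mat`
#' containing `de_LDS<trial>` arrays of dimension
#' `(n_channels, n_segments, n_bands)`, plus a `label.mat` with the native
#' per-trial codes, so that [load_seed_features()] round-trips the data. Every
#' trial must carry a single emotion class.
#'
#' @param fs a [feature_set()].
#' @param path output directory (created if needed).
#' @param dataset_variant label-code table to use, as in
#'   [load_seed_features()].
#' @param dialect MAT dialect passed to [write_mat()].
#' @return the directory path, invisibly.
#' @export
write_fixture_mat <- function(fs, path, dataset_variant = c("seed", "seed_iv"),
                              dialect = c("v5", "v7", "v7.3")) {
  dataset_variant <- match.arg(dataset_variant)
  dialect <- match.arg(dialect)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  key <- paste(fs$subject_id, fs$session_id, sep = "_")
  # per-trial labels must be consistent and shared across files
  trial_lab <- tapply(fs$labels, fs$trial_id, function(v) {
    u <- unique(v)
    if (length(u) != 1L) stop("a trial carries more than one emotion class", call. = FALSE)
    u
  })
  n_trials <- max(fs$trial_id)
  lab_vec <- integer(n_trials)
  lab_vec[as.integer(names(trial_lab))] <- as.integer(trial_lab)
  write_mat(file.path(path, "label.mat"),
            list(label = matrix(as.double(unmap_label(lab_vec, dataset_variant)),
                                nrow = 1L)),
            dialect = dialect)
  for (k in unique(key)) {
    idx <- which(key == k)
    vars <- list()
    for (t in sort(unique(fs$trial_id[idx]))) {
      rows <- idx[fs$trial_id[idx] == t]
      # (segments, channels, bands) -> native (channels, segments, bands)
      vars[[paste0("de_LDS", t)]] <-
        aperm(fs$features[rows, , , drop = FALSE], c(2L, 1L, 3L))
    }
    write_mat(file.path(path, paste0(k, ".mat")), vars, dialect = dialect)
  }
  invisible(path)
}
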