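# Per-feature z-scoring fitted on the pooled source + target segments of a
# split (label-free, hence legitimate in the unsupervised-target setting);
# standard preprocessing for differential-entropy features.
fit_normalizer <- function(source, target) {
  all <- rbind(flatten_features(source$features),
               flatten_features(target$features))
  mu <- colMeans(all)
  sd_ <- apply(all, 2L, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  list(mean = mu, sd = sd_)
}

apply_normalizer <- function(norm, fs) {
  d <- dim(fs$features)
  m <- sweep(sweep(flatten_features(fs$features), 2L, norm$mean), 2L,
             norm$sd, "/")
  fs$features <- array(m, d)
  fs
}

new_split <- function(name, source, target, target_subject = NA_integer_,
                      subject = NA_integer_, session = NA_integer_,
                      split_rule = "") {
  structure(list(name = name, source = source, target = target,
                 target_subject = target_subject, subject = subject,
                 session = session, split_rule = split_rule),
            class = "protocol_split")
}

#' @export
print.protocol_split <- function(x, ...) {
  cat(sprintf("<protocol_split> %s: %d source / %d target segments (%s)\n",
              x$name, n_segments(x$source), n_segments(x$target), x$split_rule))
  invisible(x)
}

#' Subject-dependent trial splits
#'
#' For every (subject, session) pair, trials are ordered by their native
#' index and split into a supervised source block and an unlabeled target
#' block: the first 9 trials vs the remaining 6 for the 15-trial 3-class
#' layout (`variant = "seed"`), the first 16 vs the remaining 8 for the
#' 24-trial 4-class layout (`variant = "seed_iv"`).
#'
#' @param data a [feature_set()].
#' @param variant `"seed"` (9/6 rule) or `"seed_iv"` (16/8 rule).
#' @return list of `protocol_split` objects, one per (subject, session).
#' @export
make_subject_dependent_splits <- function(data, variant = c("seed", "seed_iv")) {
  variant <- match.arg(variant)
  n_src_trials <- if (variant == "seed") 9L else 16L
  combos <- unique(data.frame(subject = data$subject_id,
                              session = data$session_id))
  combos <- combos[order(combos$subject, combos$session), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(combos))) {
    s <- combos$subject[i]; e <- combos$session[i]
    idx <- which(data$subject_id == s & data$session_id == e)
    trials <- sort(unique(data$trial_id[idx]))
    if (length(trials) <= n_src_trials) {
      stop(sprintf(
        "subject %d session %d has %d trials; the %d/%d rule needs more",
        s, e, length(trials), n_src_trials,
        if (variant == "seed") 6L else 8L), call. = FALSE)
    }
    src_trials <- trials[seq_len(n_src_trials)]
    src <- idx[data$trial_id[idx] %in% src_trials]
    tgt <- setdiff(idx, src)
    out[[length(out) + 1L]] <- new_split(
      "subject_dependent", fs_subset(data, src), fs_subset(data, tgt),
      target_subject = s, subject = s, session = e,
      split_rule = sprintf("first %d trials source / remaining %d target",
                           n_src_trials, length(trials) - n_src_trials))
  }
  out
}

#' Leave-one-subject-out splits
#'
#' One split per subject: that subject's full data is the unlabeled target
#' domain and all remaining subjects form the source domain.
#'
#' @param data a [feature_set()] with at least two subjects.
#' @return list of `protocol_split` objects.
#' @export
make_loso_splits <- function(data) {
  subjects <- sort(unique(data$subject_id))
  if (length(subjects) < 2L) {
    stop("leave-one-subject-out needs at least two subjects", call. = FALSE)
  }
  lapply(subjects, function(s) {
    new_split("loso",
              fs_subset(data, data$subject_id != s),
              fs_subset(data, data$subject_id == s),
              target_subject = s,
              split_rule = sprintf("subject %d held out as target", s))
  })
}

#' Train the adversarial decoder on one protocol split
#'
#' Runs `epochs` passes over paired source/target mini-batches, minimizing
#' the total objective (classification + domain adversarial + individual
#' adversarial + weighted cluster loss) with RMSprop. The gradient-reversal
#' strength advances once per optimizer step along its sigmoid schedule, with
#' `max_iters = steps_per_epoch * epochs`. Target emotion labels are never
#' read. The run is fully reproducible from `config$seed`.
#'
#' When the split contains a single subject (subject-dependent runs), the
#' individual discriminator is disabled automatically: a one-class
#' subject-membership cross-entropy is degenerate.
#'
#' @param split a `protocol_split` from [make_subject_dependent_splits()] or
#'   [make_loso_splits()].
#' @param config a [train_config()].
#' @return a list of class `tddann_fit` with `model`, `history` (per-epoch
#'   data frame of loss components, reversal strength and target accuracy)
#'   and `config`.
#' @export
train_model <- function(split, config = train_config()) {
  stopifnot(inherits(split, "protocol_split"), inherits(config, "train_config"))
  source <- split$source; target <- split$target
  norm <- NULL
  if (isTRUE(config$normalize_features)) {
    norm <- fit_normalizer(source, target)
    source <- apply_normalizer(norm, source)
    target <- apply_normalizer(norm, target)
  }
  d <- dim(source$features)
  subjects <- sort(union(unique(source$subject_id), unique(target$subject_id)))
  model <- init_model(d[2L], d[3L], source$n_classes, length(subjects), config)
  model$normalization <- norm

  half <- config$batch_size %/% 2L
  steps_per_epoch <- max(ceiling(n_segments(source) / half),
                         ceiling(n_segments(target) / half))
  max_iters <- steps_per_epoch * config$epochs
  sched_dom <- grl_schedule(config$hi, config$lo, config$alpha,
                            iter_num = 0L, max_iters = max_iters)
  ind_hi <- config$individual_hi %||% config$hi
  ind_lo <- config$individual_lo %||% config$lo
  sched_ind <- if (ind_hi == 0 && ind_lo == 0) NULL else
    grl_schedule(ind_hi, ind_lo, config$alpha, 0L, max_iters)

  hist <- vector("list", config$epochs)
  iter <- 0L
  for (epoch in seq_len(config$epochs)) {
    batches <- make_domain_batches(source, target, config$batch_size,
                                   seed = derive_seed(config$seed, 100L + epoch))
    acc_losses <- c(cls = 0, domain = 0, individual = 0, cluster = 0,
                    total = 0)
    n_sel_tot <- 0L
    for (b in batches) {
      sched_dom$iter_num <- iter
      coeff_dom <- grl_coefficient(sched_dom)
      coeff_ind <- if (is.null(sched_ind)) 0 else {
        sched_ind$iter_num <- iter
        grl_coefficient(sched_ind)
      }
      st <- train_step(model, b, coeff_dom, coeff_ind)
      model <- st$model
      if (!is.finite(st$losses$total)) {
        stop(sprintf("training diverged (non-finite loss) at iteration %d",
                     iter), call. = FALSE)
      }
      acc_losses <- acc_losses +
        c(st$losses$cls, st$losses$domain, st$losses$individual,
          st$losses$cluster, st$losses$total)
      n_sel_tot <- n_sel_tot + st$losses$n_selected
      iter <- iter + 1L
    }
    ev <- evaluate_model(model, target)
    hist[[epoch]] <- data.frame(
      epoch = epoch, t(acc_losses / length(batches)),
      coeff = grl_coefficient(sched_dom), n_selected = n_sel_tot,
      target_accuracy = ev$accuracy)
  }
  history <- do.call(rbind, hist)
  fit <- list(model = model, history = history, config = config,
              split_rule = split$split_rule,
              target_subject = split$target_subject)
  if (isTRUE(config$record_best)) {
    fit$best_epoch <- history$epoch[which.max(history$target_accuracy)]
    fit$best_accuracy <- max(history$target_accuracy)
  }
  class(fit) <- "tddann_fit"
  fit
}

#' @export
print.tddann_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<tddann_fit> %d epochs; final target accuracy %.3f, total loss %.4f\n",
              n, x$history$target_accuracy[n], x$history$total[n]))
  invisible(x)
}

#' Evaluate emotion-decoding accuracy on a target feature set
#'
#' @param model a `tddann_model` or `tddann_fit`.
#' @param target a labeled [feature_set()].
#' @return list with `accuracy` (fraction of segments whose argmax class
#'   matches the label), `per_class` accuracy, `confusion` (counts; rows =
#'   true class, columns = predicted) and `confusion_norm` (row-normalized).
#' @export
evaluate_model <- function(model, target) {
  if (inherits(model, "tddann_fit")) model <- model$model
  if (n_segments(target) == 0L) {
    stop("cannot evaluate on an empty target set", call. = FALSE)
  }
  if (any(is.na(target$labels))) {
    stop("evaluation requires labeled target data", call. = FALSE)
  }
  pred <- predict_classes(model, target)$class
  cc <- model$n_classes
  conf <- matrix(0L, cc, cc,
                 dimnames = list(true = 0:(cc - 1L), pred = 0:(cc - 1L)))
  for (i in seq_along(pred)) {
    conf[target$labels[i] + 1L, pred[i] + 1L] <-
      conf[target$labels[i] + 1L, pred[i] + 1L] + 1L
  }
  rs <- rowSums(conf)
  conf_norm <- conf / ifelse(rs == 0L, 1L, rs)
  list(accuracy = mean(pred == target$labels),
       per_class = diag(conf_norm),
       confusion = conf, confusion_norm = conf_norm)
}

#' Run a full evaluation protocol
#'
#' Builds every split of the requested protocol, trains the configured model
#' variant on each, evaluates on its target set, and aggregates mean and
#' standard deviation of accuracy across splits.
#'
#' @param data a [feature_set()].
#' @param protocol `"loso"` or `"subject_dependent"`.
#' @param config a [train_config()].
#' @param variant split rule for the subject-dependent protocol (`"seed"` /
#'   `"seed_iv"`).
#' @param out_dir optional directory; per-split metrics (JSON-like CSV),
#'   learned adjacencies (CSV) and the summary are written there.
#' @return a `run_summary` (see [summarize_runs()]) with the per-split table
#'   in `$per_split` and fits in `$fits`.
#' @export
run_protocol <- function(data, protocol = c("loso", "subject_dependent"),
                         config = train_config(), variant = "seed",
                         out_dir = NULL) {
  protocol <- match.arg(protocol)
  splits <- if (protocol == "loso") make_loso_splits(data)
            else make_subject_dependent_splits(data, variant)
  fits <- vector("list", length(splits))
  evals <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    fits[[i]] <- train_model(splits[[i]], config)
    evals[[i]] <- evaluate_model(fits[[i]]$model, splits[[i]]$target)
    evals[[i]]$split_id <- i
    evals[[i]]$target_subject <- splits[[i]]$target_subject
  }
  summ <- summarize_runs(evals, protocol = protocol)
  summ$fits <- fits
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summ$per_split,
                     file.path(out_dir, "per_split_accuracy.csv"),
                     row.names = FALSE)
    for (i in seq_along(fits)) {
      if (!fits[[i]]$model$extractor$use_mlp) {
        write_adjacency_csv(fits[[i]]$model,
                            file.path(out_dir, sprintf("adjacency_split%02d.csv", i)),
                            channel_names = data$channel_names)
      }
    }
  }
  summ
}
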