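#' Aggregate per-split evaluation results
#'
#' Computes the protocol summary: mean and sample standard deviation (n - 1
#' denominator) of accuracy across splits, and the confusion matrix pooled
#' over splits before row normalization.
#'
#' @param evals list of per-split evaluation results as returned by
#'   [evaluate_model()] (optionally carrying `split_id` / `target_subject`).
#' @param protocol optional protocol name recorded in the summary.
#' @param ablation_tag optional variant tag (for ablation tables).
#' @return a `run_summary` list with `per_split` (data frame), `mean`, `sd`,
#'   `confusion` and `confusion_norm`.
#' @export
summarize_runs <- function(evals, protocol = NA_character_,
                           ablation_tag = NA_character_) {
  if (length(evals) == 0L) stop("no runs to summarize", call. = FALSE)
  acc <- vapply(evals, `[[`, numeric(1L), "accuracy")
  per_split <- data.frame(
    split_id = vapply(seq_along(evals),
                      function(i) evals[[i]]$split_id %||% i, numeric(1L)),
    target_subject = vapply(evals, function(e)
      as.numeric(e$target_subject %||% NA_real_), numeric(1L)),
    accuracy = acc)
  conf <- Reduce(`+`, lapply(evals, `[[`, "confusion"))
  rs <- rowSums(conf)
  structure(list(protocol = protocol, ablation_tag = ablation_tag,
                 per_split = per_split,
                 mean = mean(acc),
                 sd = if (length(acc) > 1L) stats::sd(acc) else 0,
                 confusion = conf,
                 confusion_norm = conf / ifelse(rs == 0L, 1L, rs)),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %s%s: accuracy %.2f%% +/- %.2f%% over %d splits\n",
              x$protocol %||% "runs",
              if (!is.na(x$ablation_tag)) paste0(" [", x$ablation_tag, "]") else "",
              100 * x$mean, 100 * x$sd, nrow(x$per_split)))
  invisible(x)
}

#' Ablation comparison table
#'
#' Formats mean +/- sd accuracy per model variant, with the full model first,
#' in the row order full / without individual discriminator / without graph
#' extractor / without both.
#'
#' @param summaries named list of `run_summary` objects; must contain an
#'   entry named `"full"`.
#' @param format `"data.frame"`, `"markdown"` or `"csv"` (rendered string).
#' @return a data frame, or a character string for the rendered formats.
#' @export
ablation_table <- function(summaries, format = c("data.frame", "markdown", "csv")) {
  format <- match.arg(format)
  if (!("full" %in% names(summaries))) {
    stop("ablation table requires the full model under the name 'full'",
         call. = FALSE)
  }
  canonical <- c("full", "no_individual", "no_gcn", "no_both")
  ord <- c(intersect(canonical, names(summaries)),
           setdiff(names(summaries), canonical))
  labels <- c(full = "full model",
              no_individual = "w/o individual discriminator",
              no_gcn = "w/o graph extractor",
              no_both = "w/o graph extractor and individual discriminator")
  df <- data.frame(
    variant = vapply(ord, function(v) labels[v] %||% v, character(1L)),
    mean_accuracy = vapply(summaries[ord], `[[`, numeric(1L), "mean"),
    sd_accuracy = vapply(summaries[ord], `[[`, numeric(1L), "sd"),
    row.names = NULL)
  if (format == "data.frame") return(df)
  cell <- sprintf("%.2f +/- %.2f", 100 * df$mean_accuracy, 100 * df$sd_accuracy)
  if (format == "markdown") {
    paste(c("| Variant | ACC +/- STD (%) |", "|---|---|",
            sprintf("| %s | %s |", df$variant, cell)), collapse = "\n")
  } else {
    paste(c("variant,acc_mean_pct,acc_sd_pct",
            sprintf("%s,%.2f,%.2f", df$variant,
                    100 * df$mean_accuracy, 100 * df$sd_accuracy)),
          collapse = "\n")
  }
}

#' Two-dimensional embedding of learned features
#'
#' Projects feature vectors to 2-D for visual inspection of class structure,
#' using principal components (a deterministic linear embedding).
#'
#' @param features matrix `(rows, d)` with at least 10 rows.
#' @param labels optional class labels attached to the output.
#' @param seed unused by the PCA backend; kept so callers can treat the
#'   embedding as seeded plumbing.
#' @return data frame with `dim1`, `dim2` and (when given) `label`.
#' @export
embed_features_2d <- function(features, labels = NULL, seed = 1L) {
  if (nrow(features) < 10L) {
    stop("need at least 10 rows to embed", call. = FALSE)
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = 2L)
  coords <- pc$x[, 1:2, drop = FALSE]
  # fix the sign convention so the embedding is unique
  for (j in 1:2) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  out <- data.frame(dim1 = coords[, 1L], dim2 = coords[, 2L])
  if (!is.null(labels)) out$label <- labels
  out
}
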