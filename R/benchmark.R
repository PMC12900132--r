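#' Synthetic cross-subject ablation benchmark
#'
#' Runs the leave-one-subject-out protocol on generated multi-subject data
#' for a set of model variants, pairing every variant over the same seeds and
#' folds so that ablation comparisons are matched. Variant names follow the
#' ablation convention:
#'
#' * `"full"` — graph extractor, domain and individual discriminators,
#'   cluster loss;
#' * `"no_individual"` — individual discriminator removed;
#' * `"no_gcn"` — graph extractor replaced by the two-layer perceptron;
#' * `"no_both"` — both ablations at once;
#' * `"source_only"` — plain source classifier, no adversarial terms.
#'
#' For every seed the generator is re-seeded (fresh subjects and transforms)
#' and `folds_per_seed` LOSO folds are evaluated, rotating the held-out
#' subject across seeds so all subjects are exercised.
#'
#' @param seeds integer vector of benchmark seeds.
#' @param variants subset of the variant names above.
#' @param spec a [synth_spec()]; its `seed` field is overridden per benchmark
#'   seed.
#' @param epochs training epochs per run (reduced relative to the full
#'   protocol so the benchmark stays desk-sized).
#' @param folds_per_seed LOSO folds evaluated per seed.
#' @param config base [train_config()] whose variant-independent fields are
#'   reused.
#' @return data frame with columns `seed`, `fold`, `target_subject`,
#'   `variant`, `accuracy`.
#' @export
run_synthetic_benchmark <- function(seeds = 1:5,
                                    variants = c("full", "no_individual",
                                                 "source_only"),
                                    spec = synth_spec(), epochs = 30L,
                                    folds_per_seed = 2L,
                                    config = train_config()) {
  bad <- setdiff(variants, c("full", "no_individual", "no_gcn", "no_both",
                             "source_only"))
  if (length(bad)) {
    stop(sprintf("unknown benchmark variant(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(seeds)) {
    seed <- seeds[i]
    sp_gen <- spec
    sp_gen$seed <- as.integer(seed)
    gen <- synth_generate(sp_gen)
    splits <- make_loso_splits(gen$data)
    n_subj <- length(splits)
    folds <- ((folds_per_seed * (i - 1L) + seq_len(folds_per_seed) - 1L) %%
                n_subj) + 1L
    for (fold in folds) {
      for (v in variants) {
        cfg <- variant_config(config, v, seed = seed, epochs = epochs)
        fit <- train_model(splits[[fold]], cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, fold = fold,
          target_subject = splits[[fold]]$target_subject, variant = v,
          accuracy = utils::tail(fit$history$target_accuracy, 1L))
      }
    }
  }
  do.call(rbind, rows)
}

# derive the train_config for one ablation variant
variant_config <- function(config, variant, seed, epochs) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  cfg$epochs <- as.integer(epochs)
  cfg$use_domain <- variant != "source_only"
  cfg$use_individual <- variant %in% c("full", "no_gcn")
  cfg$use_mlp_ablation <- variant %in% c("no_gcn", "no_both")
  if (variant == "source_only") cfg$lambda_cluster <- 0
  cfg
}

#' Summarize a benchmark table into per-variant means
#'
#' @param bench data frame from [run_synthetic_benchmark()].
#' @return data frame with one row per variant: mean, sd and the per-seed
#'   means pivoted long in the `seed_means` attribute.
#' @export
summarize_benchmark <- function(bench) {
  agg <- stats::aggregate(accuracy ~ variant, bench, mean)
  agg$sd <- stats::aggregate(accuracy ~ variant, bench, stats::sd)$accuracy
  seed_means <- stats::aggregate(accuracy ~ seed + variant, bench, mean)
  attr(agg, "seed_means") <- seed_means
  agg[order(-agg$accuracy), ]
}
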