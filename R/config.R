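#' Read a training configuration from a YAML file
#'
#' The file uses dotted sections mirroring the programmatic defaults:
#'
#' ```yaml
#' dataset: {variant: seed, path: /data/ExtractedFeatures}
#' training: {batch_size: 96, epochs: 1000, learning_rate: 0.0005,
#'            l2_weight: 0.0001, lambda_cluster: 1.0, seed: 1}
#' model: {cheb_order: 3, gcn_layers: 1, gcn_out_dim: 32, leaky_slope: 0.01,
#'         disc_hidden: 128, cls_head: ova_bce, use_mlp_ablation: false}
#' grl: {hi: 0.9, lo: 0.5, alpha: 10.0}
#' cluster: {rule: threshold, threshold: 0.9, fraction: 0.5}
#' ```
#'
#' Unknown keys raise an error; missing keys fall back to the
#' [train_config()] defaults.
#'
#' @param path YAML file path.
#' @return list with `config` (a [train_config()]) and `dataset` (list with
#'   `variant` and `path`, possibly empty).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- list(
    training = c(batch_size = "batch_size", epochs = "epochs",
                 learning_rate = "learning_rate", l2_weight = "l2_weight",
                 lambda_cluster = "lambda_cluster", seed = "seed",
                 normalize_features = "normalize_features"),
    model = c(cheb_order = "cheb_order", gcn_layers = "gcn_layers",
              gcn_out_dim = "gcn_out_dim", leaky_slope = "leaky_slope",
              disc_hidden = "disc_hidden", cls_head = "cls_head",
              use_mlp_ablation = "use_mlp_ablation", mlp_hidden = "mlp_hidden",
              adjacency_init_bound = "adjacency_bound",
              use_individual = "use_individual", use_domain = "use_domain"),
    grl = c(hi = "hi", lo = "lo", alpha = "alpha",
            individual_hi = "individual_hi", individual_lo = "individual_lo"),
    cluster = c(rule = "cluster_rule", threshold = "cluster_threshold",
                fraction = "cluster_fraction"))
  args <- list()
  for (section in names(known)) {
    for (key in names(y[[section]] %||% list())) {
      if (!(key %in% names(known[[section]]))) {
        stop(sprintf("unknown config key %s.%s", section, key), call. = FALSE)
      }
      args[[known[[section]][[key]]]] <- y[[section]][[key]]
    }
  }
  extra <- setdiff(names(y), c(names(known), "dataset"))
  if (length(extra)) {
    stop(sprintf("unknown config section(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  list(config = do.call(train_config, args),
       dataset = y$dataset %||% list())
}

#' Write the resolved configuration next to a run's results
#'
#' @param config a [train_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   path)
  invisible(path)
}
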