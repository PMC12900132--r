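#' Training configuration
#'
#' Collects every tunable of the adversarial decoder with the defaults used
#' throughout: RMSprop learning rate 5e-4, L2 weight decay 1e-4, batch size
#' 96, Chebyshev order 3, reversal-strength bounds `hi = 0.9`, `lo = 0.5`,
#' ramp rate `alpha = 10`. The default epoch budget follows the full protocol
#' (1000); synthetic-benchmark runs override it downward.
#'
#' @param learning_rate RMSprop learning rate.
#' @param l2_weight L2 weight-decay coefficient applied to all learnable
#'   parameters, the adjacency included.
#' @param batch_size even total mini-batch size (half source, half target).
#' @param epochs training epochs.
#' @param cheb_order Chebyshev polynomial order `K`.
#' @param gcn_layers,gcn_out_dim extractor depth and per-channel width.
#' @param leaky_slope Leaky ReLU negative slope.
#' @param hi,lo,alpha gradient-reversal schedule parameters.
#' @param individual_hi,individual_lo bounds for the individual branch's own
#'   reversal schedule. The default is a weak reversal (0.3 / 0.1): the
#'   branch's role is to balance domain alignment against the loss of
#'   subject-specific patterns, and full-strength reversal suppresses
#'   exactly what it should preserve (see the methods vignette). `NULL`
#'   shares the domain schedule; 0 detaches the branch from the extractor;
#'   negative values make it cooperative.
#' @param lambda_cluster weight of the target cluster loss.
#' @param cluster_rule,cluster_threshold,cluster_fraction confident-target
#'   selection rule, see [select_confident_targets()].
#' @param cls_head `"ova_bce"` or `"softmax_ce"` classification head.
#' @param disc_hidden discriminator hidden width.
#' @param use_individual,use_domain enable the individual / domain
#'   adversarial branches (`use_domain = FALSE` gives a plain source-only
#'   classifier).
#' @param use_mlp_ablation replace the graph extractor by the two-layer
#'   perceptron ablation.
#' @param mlp_hidden hidden width of the ablation perceptron.
#' @param adjacency_bound optional override of the adjacency init bound.
#' @param rmsprop_rho,rmsprop_eps RMSprop smoothing constant and stabilizer
#'   (library-conventional defaults 0.99 / 1e-8).
#' @param normalize_features z-score every (channel, band) feature using the
#'   pooled source + target segments of the split before training (label-free
#'   standard preprocessing for DE features; the fitted transform is stored
#'   in the model and re-applied at prediction time).
#' @param record_best also track the best-epoch target accuracy in the
#'   history (reported accuracy remains final-epoch).
#' @param seed integer master seed; parameter draws and every epoch's
#'   shuffling derive from it deterministically.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, l2_weight = 1e-4,
                         batch_size = 96L, epochs = 1000L, cheb_order = 3L,
                         gcn_layers = 1L, gcn_out_dim = 32L,
                         leaky_slope = 0.01, hi = 0.9, lo = 0.5, alpha = 10,
                         individual_hi = 0.3, individual_lo = 0.1,
                         lambda_cluster = 1, cluster_rule = "threshold",
                         cluster_threshold = 0.9, cluster_fraction = 0.5,
                         cls_head = "ova_bce", disc_hidden = 128L,
                         use_individual = TRUE, use_domain = TRUE,
                         use_mlp_ablation = FALSE, mlp_hidden = 128L,
                         adjacency_bound = NULL, rmsprop_rho = 0.99,
                         rmsprop_eps = 1e-8, normalize_features = TRUE,
                         record_best = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$learning_rate <= 0 || cfg$l2_weight < 0 || cfg$epochs < 1L ||
      cfg$batch_size < 2L || cfg$cheb_order < 1L) {
    stop("invalid training configuration", call. = FALSE)
  }
  structure(cfg, class = "train_config")
}

# deterministic component seeds derived from the master seed; kept well below
# .Machine$integer.max
derive_seed <- function(seed, k) {
  ((abs(as.integer(seed)) %% 100000L) * 10007L + k) %% 2147483629L
}

init_model <- function(n_channels, n_bands, n_classes, n_individuals, cfg) {
  extractor <- init_extractor(
    n_channels, n_bands, cheb_order = cfg$cheb_order,
    n_layers = cfg$gcn_layers, out_dim = cfg$gcn_out_dim,
    negative_slope = cfg$leaky_slope, adjacency_bound = cfg$adjacency_bound,
    use_mlp = cfg$use_mlp_ablation, mlp_hidden = cfg$mlp_hidden,
    seed = derive_seed(cfg$seed, 1L))
  set.seed(derive_seed(cfg$seed, 2L))
  classifier <- dense_init(extractor$d_feat, n_classes)
  use_ind <- cfg$use_individual && n_individuals >= 2L
  if (cfg$use_individual && n_individuals < 2L) {
    message("individual discriminator disabled: only one subject in this split")
  }
  model <- list(extractor = extractor, classifier = classifier,
                domain_disc = NULL, individual_disc = NULL,
                n_classes = as.integer(n_classes),
                n_individuals = as.integer(n_individuals),
                cfg = cfg, use_individual = use_ind,
                use_domain = isTRUE(cfg$use_domain))
  if (model$use_domain) {
    model$domain_disc <- init_domain_discriminator(
      extractor$d_feat, hidden = cfg$disc_hidden,
      seed = derive_seed(cfg$seed, 3L))
  }
  if (use_ind) {
    model$individual_disc <- init_individual_discriminator(
      extractor$d_feat, n_individuals, hidden = cfg$disc_hidden,
      seed = derive_seed(cfg$seed, 4L))
  }
  model$opt <- list(
    extractor = rmsprop_state(extractor$params),
    classifier = rmsprop_state(classifier),
    domain_disc = if (!is.null(model$domain_disc)) rmsprop_state(model$domain_disc),
    individual_disc = if (!is.null(model$individual_disc)) rmsprop_state(model$individual_disc))
  class(model) <- "tddann_model"
  model
}

#' @export
print.tddann_model <- function(x, ...) {
  cat(sprintf("<tddann_model> extractor: %s, d_feat = %d, classes = %d\n",
              if (x$extractor$use_mlp) "2-layer perceptron (ablation)"
              else sprintf("graph conv (K = %d, %d layer(s), F_out = %d)",
                           x$extractor$cheb_order, x$extractor$n_layers,
                           x$extractor$out_dim),
              x$extractor$d_feat, x$n_classes))
  cat(sprintf("  domain discriminator: %s; individual discriminator: %s (C = %d)\n",
              if (x$use_domain) "on" else "off",
              if (x$use_individual) "on" else "off", x$n_individuals))
  invisible(x)
}

# one optimizer step over one domain batch; returns the loss bundle and the
# updated model
train_step <- function(model, batch, coeff_dom, coeff_ind) {
  cfg <- model$cfg
  bs <- dim(batch$xs)[1L]; bt <- dim(batch$xt)[1L]
  x <- abind3(batch$xs, batch$xt)
  fwd <- extractor_forward(model$extractor, x, cache = TRUE)
  f <- fwd$features
  g_f <- matrix(0, nrow(f), ncol(f))

  # ---- supervised emotion classification on source rows
  l_cls <- 0
  g_clf <- grad_zero_like(model$classifier)
  if (bs > 0L) {
    fs <- f[seq_len(bs), , drop = FALSE]
    scores_s <- dense_forward(model$classifier, fs)
    l_cls <- classification_loss(scores_s, batch$ys, head = cfg$cls_head)
    g_scores <- classification_loss_grad(scores_s, batch$ys, head = cfg$cls_head)
    bk <- dense_backward(model$classifier, fs, g_scores)
    g_clf <- list(w = bk$w, b = bk$b)
    g_f[seq_len(bs), ] <- g_f[seq_len(bs), ] + bk$x
  }

  # ---- domain adversarial branch (GRL-reversed) + target cluster term
  l_dom <- 0; l_clu <- 0; n_sel <- 0L
  g_dd <- NULL
  if (model$use_domain && bs > 0L && bt > 0L) {
    dd_fwd <- mlp2_forward(model$domain_disc, f)
    d_prob <- as.vector(sigmoid(dd_fwd$out))
    d_s <- d_prob[seq_len(bs)]
    d_t <- d_prob[bs + seq_len(bt)]
    l_dom <- domain_loss(d_s, d_t)
    gl <- domain_loss_grad(d_s, d_t)
    g_u_dom <- matrix(c(gl$s, gl$t), ncol = 1L)
    bk_dom <- mlp2_backward(model$domain_disc, dd_fwd, g_u_dom)
    g_dd <- bk_dom$grads
    g_f <- g_f + reverse_gradient_backward(bk_dom$g_x, coeff_dom)

    # confident-target selection uses the classifier's current scores,
    # detached from the gradient
    if (cfg$lambda_cluster > 0) {
      ft <- f[bs + seq_len(bt), , drop = FALSE]
      scores_t <- dense_forward(model$classifier, ft)
      sel <- select_confident_targets(
        scores_t, rule = cfg$cluster_rule, threshold = cfg$cluster_threshold,
        fraction = cfg$cluster_fraction, head = cfg$cls_head)
      n_sel <- sel$n_selected
      if (n_sel > 0L) {
        d_sel <- d_t[sel$idx]
        l_clu <- cluster_loss(d_sel)
        g_u_clu <- matrix(0, bs + bt, 1L)
        g_u_clu[bs + sel$idx, 1L] <-
          cfg$lambda_cluster * cluster_loss_grad(d_sel)
        bk_clu <- mlp2_backward(model$domain_disc, dd_fwd, g_u_clu)
        g_dd <- grad_add(g_dd, bk_clu$grads)
        # the cluster term is not reversed: it pulls selected target
        # features toward the source side of the decision boundary
        g_f <- g_f + bk_clu$g_x
      }
    }
  }

  # ---- individual adversarial branch (its own GRL)
  l_ind <- 0
  g_di <- NULL
  if (model$use_individual) {
    di_fwd <- mlp2_forward(model$individual_disc, f)
    prob <- softmax_rows(di_fwd$out)
    l_ind <- individual_loss(prob, batch$individual_labels, model$n_individuals)
    g_logits <- individual_loss_grad(prob, batch$individual_labels)
    bk_ind <- mlp2_backward(model$individual_disc, di_fwd, g_logits)
    g_di <- bk_ind$grads
    g_f <- g_f + reverse_gradient_backward(bk_ind$g_x, coeff_ind)
  }

  g_ext <- extractor_backward(model$extractor, fwd, g_f)

  cfgl <- cfg
  up <- rmsprop_update(model$extractor$params, g_ext, model$opt$extractor,
                       lr = cfgl$learning_rate, weight_decay = cfgl$l2_weight,
                       rho = cfgl$rmsprop_rho, eps = cfgl$rmsprop_eps)
  model$extractor$params <- up$p; model$opt$extractor <- up$v
  up <- rmsprop_update(model$classifier, g_clf, model$opt$classifier,
                       lr = cfgl$learning_rate, weight_decay = cfgl$l2_weight,
                       rho = cfgl$rmsprop_rho, eps = cfgl$rmsprop_eps)
  model$classifier <- up$p; model$opt$classifier <- up$v
  if (!is.null(g_dd)) {
    up <- rmsprop_update(model$domain_disc, g_dd, model$opt$domain_disc,
                         lr = cfgl$learning_rate, weight_decay = cfgl$l2_weight,
                         rho = cfgl$rmsprop_rho, eps = cfgl$rmsprop_eps)
    model$domain_disc <- up$p; model$opt$domain_disc <- up$v
  }
  if (!is.null(g_di)) {
    up <- rmsprop_update(model$individual_disc, g_di, model$opt$individual_disc,
                         lr = cfgl$learning_rate, weight_decay = cfgl$l2_weight,
                         rho = cfgl$rmsprop_rho, eps = cfgl$rmsprop_eps)
    model$individual_disc <- up$p; model$opt$individual_disc <- up$v
  }

  bundle <- total_loss(l_cls, l_dom, l_ind, l_clu,
                       lambda_cluster = cfg$lambda_cluster, n_selected = n_sel)
  list(model = model, losses = bundle)
}

#' Predict emotion-class scores for a feature set
#'
#' @param model a trained `tddann_model`.
#' @param fs a [feature_set()].
#' @return list with `scores` (rows x C logits) and `class` (0-based argmax
#'   predictions).
#' @export
predict_classes <- function(model, fs) {
  if (!is.null(model$normalization)) {
    fs <- apply_normalizer(model$normalization, fs)
  }
  f <- extract_features(fs$features, model$extractor)
  scores <- dense_forward(model$classifier, f)
  list(scores = scores, class = max.col(scores, ties.method = "first") - 1L)
}

#' Export the learned channel adjacency
#'
#' Writes the symmetrized raw adjacency as CSV with channel names as header
#' and row names, for inspection of the learned channel graph.
#'
#' @param model a trained `tddann_model` (graph extractor variant).
#' @param path output CSV path.
#' @param channel_names optional channel names; defaults to `ch<i>`.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(model, path, channel_names = NULL) {
  if (model$extractor$use_mlp) {
    stop("the perceptron ablation has no adjacency to export", call. = FALSE)
  }
  a <- model$extractor$params$adjacency
  a <- (a + t(a)) / 2
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(a)))
  dimnames(a) <- list(channel_names, channel_names)
  utils::write.csv(as.data.frame(a), path, row.names = TRUE)
  invisible(path)
}
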