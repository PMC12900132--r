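#' Graph convolution forward pass
#'
#' Applies one Chebyshev graph-convolution layer,
#' `Z = LeakyReLU( sum_k T_k(L) X W_k )`, to every element of a batch. `X` is
#' the channel-by-feature matrix of one segment; the polynomial bank `T_k(L)`
#' localizes mixing to `k`-hop neighborhoods of the learned channel graph.
#'
#' @param x numeric array `(batch, n_channels, f_in)`.
#' @param bank list of Chebyshev matrices from [chebyshev_stack()].
#' @param layer list with `weights` (list of `K` matrices `f_in x f_out`) and
#'   `negative_slope`.
#' @return array `(batch, n_channels, f_out)`.
#' @export
graph_conv_forward <- function(x, bank, layer) {
  fw <- gcn_layer_forward(batch_to_nfb(x), bank, layer)
  nfb_to_batch(array(leaky_relu(fw$pre, layer$negative_slope %||% 0.01),
                     dim = dim(fw$pre)))
}

# internal layout helpers: public arrays are (batch, N, F); the compute
# layout is (N, F, batch) so the graph operator applies as one matmul.
batch_to_nfb <- function(x) aperm(x, c(2L, 3L, 1L))
nfb_to_batch <- function(x) aperm(x, c(3L, 1L, 2L))

# forward for one layer in (N, F, B) layout; returns pre-activation and the
# caches needed for the backward pass
gcn_layer_forward <- function(x_nfb, bank, layer) {
  d <- dim(x_nfb); n <- d[1L]; f_in <- d[2L]; b <- d[3L]
  k_ord <- length(bank)
  stopifnot(length(layer$weights) == k_ord,
            nrow(layer$weights[[1L]]) == f_in)
  f_out <- ncol(layer$weights[[1L]])
  xmat <- matrix(x_nfb, n, f_in * b)
  p_list <- vector("list", k_ord)
  s <- matrix(0, n * b, f_out)
  for (k in seq_len(k_ord)) {
    m <- bank[[k]] %*% xmat                       # (N, F*B)
    p <- matrix(aperm(array(m, c(n, f_in, b)), c(1L, 3L, 2L)), n * b, f_in)
    p_list[[k]] <- p
    s <- s + p %*% layer$weights[[k]]
  }
  list(pre = array(aperm(array(s, c(n, b, f_out)), c(1L, 3L, 2L)),
                   c(n, f_out, b)),
       p_list = p_list, xmat = xmat, n = n, f_in = f_in, b = b,
       f_out = f_out)
}

# backward for one layer given g_pre in (N, F_out, B) layout; returns weight
# gradients, the adjoint of each Chebyshev matrix, and the input adjoint
gcn_layer_backward <- function(cache, bank, layer, g_pre) {
  n <- cache$n; f_in <- cache$f_in; b <- cache$b; f_out <- cache$f_out
  g_s <- matrix(aperm(array(g_pre, c(n, f_out, b)), c(1L, 3L, 2L)),
                n * b, f_out)
  g_w <- vector("list", length(bank))
  g_bank <- vector("list", length(bank))
  g_xmat <- matrix(0, n, f_in * b)
  for (k in seq_along(bank)) {
    g_w[[k]] <- crossprod(cache$p_list[[k]], g_s)
    g_p <- tcrossprod(g_s, layer$weights[[k]])     # (N*B, F_in)
    g_m <- matrix(aperm(array(g_p, c(n, b, f_in)), c(1L, 3L, 2L)),
                  n, f_in * b)
    g_bank[[k]] <- tcrossprod(g_m, cache$xmat)     # (N, N)
    g_xmat <- g_xmat + crossprod(bank[[k]], g_m)
  }
  list(g_w = g_w, g_bank = g_bank,
       g_x = array(g_xmat, c(n, f_in, b)))
}

#' Initialize the graph-convolutional feature extractor
#'
#' Builds the learnable adjacency plus a stack of Chebyshev graph-convolution
#' layers mapping `(n_channels, n_bands)` inputs to a flat feature vector of
#' length `n_channels * out_dim`. With `use_mlp = TRUE` the graph machinery is
#' replaced by the ablation variant: a two-linear-layer perceptron on the
#' flattened `n_channels * n_bands` input with matching output
#' dimensionality.
#'
#' @param n_channels,n_bands input dimensions.
#' @param cheb_order Chebyshev polynomial order `K` (default 3).
#' @param n_layers number of stacked graph-conv layers (default 1).
#' @param out_dim per-channel output width `F_out` of every layer
#'   (default 32).
#' @param negative_slope Leaky ReLU slope (default 0.01).
#' @param adjacency_bound optional override of the adjacency init bound.
#' @param use_mlp replace the graph extractor by the two-layer perceptron
#'   ablation.
#' @param mlp_hidden hidden width of the ablation perceptron (default 128).
#' @param seed integer seed for all parameter draws.
#' @return an `extractor_state` list; `$d_feat` gives the flattened output
#'   dimension.
#' @export
init_extractor <- function(n_channels, n_bands, cheb_order = 3L, n_layers = 1L,
                           out_dim = 32L, negative_slope = 0.01,
                           adjacency_bound = NULL, use_mlp = FALSE,
                           mlp_hidden = 128L, seed = 1L) {
  if (cheb_order < 1L) stop("cheb_order must be >= 1", call. = FALSE)
  if (n_layers < 1L) stop("n_layers must be >= 1", call. = FALSE)
  d_feat <- as.integer(n_channels * out_dim)
  st <- list(n_channels = as.integer(n_channels), n_bands = as.integer(n_bands),
             cheb_order = as.integer(cheb_order), n_layers = as.integer(n_layers),
             out_dim = as.integer(out_dim), negative_slope = negative_slope,
             use_mlp = isTRUE(use_mlp), d_feat = d_feat)
  if (st$use_mlp) {
    set.seed(seed)
    st$params <- list(mlp = mlp2_init(n_channels * n_bands, mlp_hidden, d_feat))
  } else {
    adj <- init_adjacency(n_channels, seed = seed, bound = adjacency_bound)
    # layer weights drawn after the adjacency from the same stream
    layers <- vector("list", n_layers)
    f_in <- n_bands
    for (l in seq_len(n_layers)) {
      bound <- sqrt(6 / (f_in + out_dim))
      layers[[l]] <- list(
        weights = lapply(seq_len(cheb_order), function(k) {
          matrix(stats::runif(f_in * out_dim, -bound, bound), f_in, out_dim)
        }))
      f_in <- out_dim
    }
    st$params <- list(adjacency = adj$raw_weights, layers = layers)
  }
  structure(st, class = "extractor_state")
}

# forward through the whole extractor; returns flat features (batch x d_feat)
# and, when `cache = TRUE`, everything the backward pass needs
extractor_forward <- function(st, x, cache = FALSE) {
  stopifnot(inherits(st, "extractor_state"))
  b <- dim(x)[1L]
  if (st$use_mlp) {
    flat <- flatten_features(x)
    h1 <- mlp2_forward(st$params$mlp, flat, st$negative_slope)
    out <- leaky_relu(h1$out, st$negative_slope)
    if (!cache) return(out)
    return(list(features = out, mlp_cache = h1, mlp_pre = h1$out))
  }
  adj <- normalize_adjacency(st$params$adjacency)
  bank <- chebyshev_stack(adj$normalized, st$cheb_order)
  cur <- batch_to_nfb(x)
  layer_caches <- vector("list", st$n_layers)
  for (l in seq_len(st$n_layers)) {
    layer <- list(weights = st$params$layers[[l]]$weights)
    fw <- gcn_layer_forward(cur, bank, layer)
    act <- array(leaky_relu(fw$pre, st$negative_slope), dim = dim(fw$pre))
    if (cache) layer_caches[[l]] <- list(fw = fw, pre = fw$pre)
    cur <- act
  }
  # (N, F_out, B) -> flatten per segment to (B, N * F_out)
  features <- matrix(aperm(cur, c(3L, 1L, 2L)), b, st$d_feat)
  if (!cache) return(features)
  list(features = features, adj = adj, bank = bank,
       layer_caches = layer_caches, batch = b)
}

# backward: g_feat is (batch x d_feat); returns gradient list congruent with
# st$params
extractor_backward <- function(st, fwd, g_feat) {
  b <- nrow(g_feat)
  if (st$use_mlp) {
    g_out <- g_feat * leaky_relu_grad(fwd$mlp_pre, st$negative_slope)
    bk <- mlp2_backward(st$params$mlp, fwd$mlp_cache, g_out, st$negative_slope)
    return(list(mlp = bk$grads))
  }
  n <- st$n_channels
  g_cur <- aperm(array(g_feat, c(b, n, st$out_dim)), c(2L, 3L, 1L))
  g_bank_total <- replicate(st$cheb_order,
                            matrix(0, n, n), simplify = FALSE)
  g_layers <- vector("list", st$n_layers)
  for (l in rev(seq_len(st$n_layers))) {
    cc <- fwd$layer_caches[[l]]
    g_pre <- g_cur * leaky_relu_grad(cc$pre, st$negative_slope)
    layer <- list(weights = st$params$layers[[l]]$weights)
    bk <- gcn_layer_backward(cc$fw, fwd$bank, layer, g_pre)
    g_layers[[l]] <- list(weights = bk$g_w)
    for (k in seq_len(st$cheb_order)) {
      g_bank_total[[k]] <- g_bank_total[[k]] + bk$g_bank[[k]]
    }
    g_cur <- bk$g_x
  }
  g_l <- chebyshev_backward(fwd$bank, fwd$adj$normalized, g_bank_total)
  g_adj <- adjacency_backward(fwd$adj, g_l)
  list(adjacency = g_adj, layers = g_layers)
}

#' Map a batch of channel-by-band inputs to flat feature vectors
#'
#' Runs the configured extractor stack (graph convolutions, or the perceptron
#' ablation) and flattens the per-channel outputs. The same map is applied to
#' source and target rows during training — the extractor is shared.
#'
#' @param x numeric array `(batch, n_channels, n_bands)`.
#' @param st an `extractor_state` from [init_extractor()].
#' @return matrix `(batch, d_feat)`.
#' @export
extract_features <- function(x, st) {
  if (!inherits(st, "extractor_state")) {
    stop("extractor not initialized; call init_extractor() first", call. = FALSE)
  }
  extractor_forward(st, x, cache = FALSE)
}
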