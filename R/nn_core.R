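# Small neural-network primitives shared by the extractor, the classifier and
# the discriminators: Leaky ReLU, dense layers with Glorot-uniform init, and
# an RMSprop optimizer with L2 weight decay that walks arbitrary nested
# parameter lists.

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

dense_init <- function(fan_in, fan_out) {
  bound <- sqrt(6 / (fan_in + fan_out))
  list(w = matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
       b = rep(0, fan_out))
}

dense_forward <- function(layer, x) {
  sweep(x %*% layer$w, 2L, layer$b, `+`)
}

# returns gradients for the layer and the input, given upstream gradient g_y
dense_backward <- function(layer, x, g_y) {
  list(w = crossprod(x, g_y), b = colSums(g_y), x = tcrossprod(g_y, layer$w))
}

# two-layer perceptron head: fan_in -> hidden -> fan_out, Leaky ReLU hidden
mlp2_init <- function(fan_in, hidden, fan_out) {
  list(l1 = dense_init(fan_in, hidden), l2 = dense_init(hidden, fan_out))
}

mlp2_forward <- function(params, x, slope = 0.01) {
  h_pre <- dense_forward(params$l1, x)
  h <- leaky_relu(h_pre, slope)
  list(out = dense_forward(params$l2, h), h_pre = h_pre, h = h, x = x)
}

mlp2_backward <- function(params, cache, g_out, slope = 0.01) {
  b2 <- dense_backward(params$l2, cache$h, g_out)
  g_h <- b2$x * leaky_relu_grad(cache$h_pre, slope)
  b1 <- dense_backward(params$l1, cache$x, g_h)
  list(grads = list(l1 = list(w = b1$w, b = b1$b),
                    l2 = list(w = b2$w, b = b2$b)),
       g_x = b1$x)
}

# ---- RMSprop over nested parameter lists -----------------------------------

rmsprop_state <- function(params) {
  rapply(params, function(p) array(0, dim = dim(p) %||% length(p)),
         how = "replace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One RMSprop step: v <- rho v + (1 - rho) g^2; p <- p - lr g / (sqrt(v)+eps),
# with L2 weight decay folded into the gradient (g <- g + wd * p).
rmsprop_update <- function(params, grads, state, lr, weight_decay = 0,
                           rho = 0.99, eps = 1e-8) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      g <- g + weight_decay * p
      v <- rho * v + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(v) + eps), v = v)
    }
  }
  walk(params, grads, state)
}

# elementwise sum of two congruent nested gradient lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

grad_scale <- function(a, s) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_scale(a[[nm]], s)
    a
  } else {
    a * s
  }
}

grad_zero_like <- function(p) {
  rapply(p, function(x) array(0, dim = dim(x) %||% length(x)), how = "replace")
}
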