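#' Initialize the learnable channel adjacency
#'
#' The adjacency over EEG channels is a free parameter learned jointly with
#' the network rather than derived from electrode geometry. Entries are drawn
#' i.i.d. uniform on `(-1/sqrt(N), 1/sqrt(N))` (Xavier-style bounds for a
#' square matrix, `N` = number of channels) and the draw is symmetrized as
#' `(W + t(W))/2`; symmetry is thereafter maintained structurally — the stored
#' parameter is unconstrained and the symmetrized matrix is formed at every
#' use.
#'
#' @param n_channels number of graph nodes (EEG channels), at least 2.
#' @param seed integer seed for the draw.
#' @param bound optional override of the uniform half-width; default
#'   `1/sqrt(n_channels)`.
#' @return an `adjacency_state` list with `raw_weights` (symmetric
#'   `n_channels x n_channels`) and `n_channels`.
#' @export
init_adjacency <- function(n_channels, seed = 1L, bound = NULL) {
  if (n_channels < 2L) {
    stop("n_channels must be >= 2 for a channel graph", call. = FALSE)
  }
  if (is.null(bound)) bound <- 1 / sqrt(n_channels)
  set.seed(seed)
  w <- matrix(stats::runif(n_channels^2, -bound, bound), n_channels, n_channels)
  w <- (w + t(w)) / 2
  structure(list(raw_weights = w, n_channels = as.integer(n_channels)),
            class = "adjacency_state")
}

#' Symmetric normalization of the rectified adjacency
#'
#' Computes the propagation matrix used by the Chebyshev filters:
#' `A' = ReLU(A)` (elementwise, so edge weights are nonnegative), degree
#' `D_ii = sum_j A'_ij`, and `L = D^{-1/2} A' D^{-1/2}`. Rows whose rectified
#' degree vanishes (isolated channels, possible early in training) are guarded
#' with `max(D_ii, epsilon)` and come out as zero rows rather than dividing by
#' zero. The spectral radius of `L` is at most 1, which keeps the Chebyshev
#' recursion bounded.
#'
#' @param state an `adjacency_state` (or a plain symmetric matrix).
#' @param epsilon zero-degree guard, default `1e-8`.
#' @return the input `state` augmented with `rectified`, `degree` (vector)
#'   and `normalized` (the matrix `L`).
#' @export
normalize_adjacency <- function(state, epsilon = 1e-8) {
  if (is.matrix(state)) {
    state <- structure(list(raw_weights = state, n_channels = nrow(state)),
                       class = "adjacency_state")
  }
  a <- state$raw_weights
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  a <- (a + t(a)) / 2                       # structural symmetry
  rect <- pmax(a, 0)
  deg <- rowSums(rect)
  s <- 1 / sqrt(pmax(deg, epsilon))
  l <- rect * (s %o% s)
  state$sym <- a
  state$rectified <- rect
  state$degree <- deg
  state$normalized <- l
  state$inv_sqrt_degree <- s
  state$epsilon <- epsilon
  state
}

# Gradient of a scalar loss wrt the unconstrained raw adjacency parameter,
# given the gradient `g_l` wrt the normalized matrix L. Chain:
# L = S A' S with S = diag(d^{-1/2}), d_i = sum_j A'_ij (clamped at epsilon),
# A' = ReLU(sym(A)), sym(A) = (A + t(A))/2.
adjacency_backward <- function(state, g_l) {
  s <- state$inv_sqrt_degree
  active <- state$degree > state$epsilon
  h <- g_l * state$rectified
  rho <- -0.5 * s^3 * (h %*% s + crossprod(h, s))  # row-wise degree terms
  rho[!active] <- 0
  g_rect <- g_l * (s %o% s) + matrix(rho, nrow(g_l), ncol(g_l))
  g_sym <- g_rect * (state$sym > 0)
  (g_sym + t(g_sym)) / 2
}

#' Chebyshev polynomial bank of the propagation matrix
#'
#' Builds `T_0(L) .. T_{K-1}(L)` by the recursion `T_0 = I`, `T_1 = L`,
#' `T_k = 2 L T_{k-1} - T_{k-2}`. The bank is recomputed from the live
#' adjacency at every forward pass so that gradients reach the adjacency
#' parameter; nothing is cached across optimizer steps.
#'
#' @param normalized square symmetric propagation matrix `L`.
#' @param order polynomial order `K >= 1`; the filter mixes information up to
#'   `K-1` hops over the channel graph.
#' @return list of `K` matrices.
#' @export
chebyshev_stack <- function(normalized, order) {
  if (order < 1L) stop("Chebyshev order must be >= 1", call. = FALSE)
  n <- nrow(normalized)
  stopifnot(ncol(normalized) == n)
  bank <- vector("list", order)
  bank[[1L]] <- diag(n)
  if (order >= 2L) bank[[2L]] <- normalized
  if (order >= 3L) {
    for (k in 3:order) {
      bank[[k]] <- 2 * normalized %*% bank[[k - 1L]] - bank[[k - 2L]]
    }
  }
  bank
}

# Backward through the Chebyshev recursion: given adjoints g_bank[[k]] for
# each T_{k-1}(L), accumulate the adjoint of L itself.
chebyshev_backward <- function(bank, normalized, g_bank) {
  order <- length(bank)
  g_l <- matrix(0, nrow(normalized), ncol(normalized))
  if (order >= 3L) {
    for (k in order:3L) {
      g <- g_bank[[k]]
      g_l <- g_l + 2 * g %*% t(bank[[k - 1L]])
      g_bank[[k - 1L]] <- g_bank[[k - 1L]] + 2 * t(normalized) %*% g
      g_bank[[k - 2L]] <- g_bank[[k - 2L]] - g
    }
  }
  if (order >= 2L) g_l <- g_l + g_bank[[2L]]
  g_l
}
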