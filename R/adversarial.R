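#' Sigmoid-scheduled gradient-reversal strength
#'
#' The reversal strength ramps smoothly from `lo` toward `hi` over training,
#' so that early steps learn usable features before the adversarial pressure
#' is applied in full:
#'
#' \deqn{coeff = \frac{2(hi-lo)}{1+\exp(-\alpha\,iter/max\_iters)} - (hi-lo) + lo}
#'
#' At `iter_num = 0` the value is exactly `lo`; it increases monotonically
#' (for `alpha > 0`, `hi > lo`) and approaches but never reaches `hi`.
#'
#' @param hi,lo upper and lower reversal-strength bounds (defaults 0.9 / 0.5).
#' @param alpha ramp-rate parameter, `> 0` (default 10).
#' @param iter_num current optimizer iteration, `>= 0`.
#' @param max_iters total planned iterations, `> 0`.
#' @return list of class `grl_schedule`; [grl_coefficient()] evaluates it.
#' @export
grl_schedule <- function(hi = 0.9, lo = 0.5, alpha = 10, iter_num = 0L,
                         max_iters = 1000L) {
  if (max_iters <= 0L) stop("max_iters must be positive", call. = FALSE)
  if (hi < lo) stop("hi must be >= lo", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  structure(list(hi = hi, lo = lo, alpha = alpha,
                 iter_num = as.integer(iter_num),
                 max_iters = as.integer(max_iters)),
            class = "grl_schedule")
}

#' @rdname grl_schedule
#' @param schedule a `grl_schedule`.
#' @export
grl_coefficient <- function(schedule) {
  with(schedule,
       2 * (hi - lo) / (1 + exp(-alpha * iter_num / max_iters)) -
         (hi - lo) + lo)
}

#' Gradient reversal
#'
#' Identity in the forward direction; during backpropagation the gradient
#' flowing back to `features` is multiplied by `-coeff`. With hand-rolled
#' backward passes the two directions are separate functions:
#' `reverse_gradient()` is the (identity) forward map and
#' [reverse_gradient_backward()] applies the scaling to an upstream gradient.
#'
#' @param features numeric matrix or array.
#' @param coeff finite reversal strength.
#' @return `reverse_gradient()`: `features` unchanged;
#'   `reverse_gradient_backward()`: `-coeff * grad`.
#' @export
reverse_gradient <- function(features, coeff) {
  stopifnot(is.finite(coeff))
  features
}

#' @rdname reverse_gradient
#' @param grad upstream gradient with the shape of `features`.
#' @export
reverse_gradient_backward <- function(grad, coeff) {
  -coeff * grad
}

#' Initialize the domain and individual discriminators
#'
#' Each discriminator is a two-layer perceptron `d_feat -> hidden -> out`
#' with Leaky ReLU hidden activation: the domain head emits one logit per row
#' (sigmoid probability of source membership), the individual head emits one
#' logit per subject.
#'
#' @param d_feat input feature width.
#' @param hidden hidden width (default 128).
#' @param n_individuals number of subjects `C >= 2` (individual head only).
#' @param seed seed for parameter draws.
#' @return parameter list usable with the forward functions below.
#' @name discriminators
NULL

#' @rdname discriminators
#' @export
init_domain_discriminator <- function(d_feat, hidden = 128L, seed = 1L) {
  set.seed(seed)
  mlp2_init(d_feat, hidden, 1L)
}

#' @rdname discriminators
#' @export
init_individual_discriminator <- function(d_feat, n_individuals, hidden = 128L,
                                          seed = 1L) {
  if (n_individuals < 2L) {
    stop("the individual discriminator needs at least 2 subjects", call. = FALSE)
  }
  set.seed(seed)
  mlp2_init(d_feat, hidden, as.integer(n_individuals))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Domain discriminator forward pass
#'
#' @param features matrix `(rows, d_feat)`.
#' @param params parameters from [init_domain_discriminator()].
#' @return numeric vector of source-membership probabilities in `(0, 1)`.
#' @export
domain_discriminator_forward <- function(features, params) {
  fw <- mlp2_forward(params, features)
  as.vector(sigmoid(fw$out))
}

#' Individual discriminator forward pass
#'
#' @param features matrix `(rows, d_feat)`.
#' @param params parameters from [init_individual_discriminator()].
#' @return list with `logits` (rows x C) and `prob` (softmax rows).
#' @export
individual_discriminator_forward <- function(features, params) {
  fw <- mlp2_forward(params, features)
  list(logits = fw$out, prob = softmax_rows(fw$out))
}
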