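CLAMP_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, CLAMP_EPS), 1 - CLAMP_EPS)

#' Binary cross-entropy
#'
#' Mean over rows of `-[y log(p) + (1 - y) log(1 - p)]`; predicted
#' probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param y targets in `{0, 1}` (or soft targets in `[0, 1]`).
#' @param p predicted probabilities, same length as `y`.
#' @return scalar loss, `>= 0`.
#' @export
bce <- function(y, p) {
  if (length(y) == 1L) y <- rep(y, length(p))
  if (length(y) != length(p)) stop("y and p differ in length", call. = FALSE)
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Domain adversarial loss
#'
#' `0.5 * (BCE(d_s, 1) + BCE(d_t, 0))`: source rows are pushed toward domain
#' label 1 and target rows toward 0, with the two sides averaged
#' symmetrically.
#'
#' @param d_s,d_t domain-discriminator probabilities on source / target rows;
#'   both sides must be non-empty.
#' @return scalar loss.
#' @export
domain_loss <- function(d_s, d_t) {
  if (length(d_s) == 0L || length(d_t) == 0L) {
    stop("domain_loss requires non-empty source and target sides", call. = FALSE)
  }
  0.5 * (bce(1, d_s) + bce(0, d_t))
}

#' Individual (subject) adversarial loss
#'
#' Cross-entropy of the subject-membership softmax against the true subject
#' index: mean over rows of `-log p[row, id_row]`.
#'
#' @param p matrix `(rows, C)` of subject probabilities (rows sum to 1).
#' @param id integer subject labels in `0..C-1`.
#' @param n_individuals `C`.
#' @return scalar loss.
#' @export
individual_loss <- function(p, id, n_individuals) {
  if (any(id < 0L | id >= n_individuals)) {
    stop("subject label outside 0..C-1", call. = FALSE)
  }
  picked <- p[cbind(seq_along(id), id + 1L)]
  -mean(log(clamp_prob(picked)))
}

#' Source-domain emotion classification loss
#'
#' The default head treats the C-class problem as one-vs-all binary
#' cross-entropy: per-class sigmoid probabilities against one-hot labels,
#' averaged over rows and classes. `head = "softmax_ce"` switches to the
#' conventional softmax cross-entropy.
#'
#' @param scores matrix `(rows, C)` of class logits.
#' @param labels integer emotion labels in `0..C-1`.
#' @param head `"ova_bce"` (default) or `"softmax_ce"`.
#' @return scalar loss.
#' @export
classification_loss <- function(scores, labels, head = c("ova_bce", "softmax_ce")) {
  head <- match.arg(head)
  cc <- ncol(scores)
  if (any(labels < 0L | labels >= cc)) {
    stop("emotion label outside 0..C-1", call. = FALSE)
  }
  onehot <- matrix(0, nrow(scores), cc)
  onehot[cbind(seq_along(labels), labels + 1L)] <- 1
  if (head == "ova_bce") {
    p <- clamp_prob(sigmoid(scores))
    -mean(onehot * log(p) + (1 - onehot) * log(1 - p))
  } else {
    p <- softmax_rows(scores)
    -mean(log(clamp_prob(p[cbind(seq_along(labels), labels + 1L)])))
  }
}

#' Select confident target-domain samples
#'
#' The cluster loss only uses target rows whose predicted emotion confidence
#' (maximum class probability) passes a rule: either a fixed threshold
#' (default `tau = 0.9`) or the top fraction of the batch by confidence. An
#' empty selection is allowed and makes the cluster term vanish.
#'
#' @param scores matrix `(rows, C)` of target-row class logits.
#' @param rule `"threshold"` or `"top_fraction"`.
#' @param threshold confidence threshold `tau` for the threshold rule.
#' @param fraction fraction `q` of rows kept by the top-fraction rule.
#' @param head scoring head, as in [classification_loss()]; determines how
#'   logits map to probabilities.
#' @return list with `idx` (selected row indices) and `n_selected`.
#' @export
select_confident_targets <- function(scores, rule = c("threshold", "top_fraction"),
                                     threshold = 0.9, fraction = 0.5,
                                     head = c("ova_bce", "softmax_ce")) {
  rule <- match.arg(rule)
  head <- match.arg(head)
  prob <- if (head == "ova_bce") sigmoid(scores) else softmax_rows(scores)
  conf <- apply(prob, 1L, max)
  if (rule == "threshold") {
    idx <- which(conf >= threshold)
  } else {
    k <- floor(fraction * length(conf))
    idx <- if (k >= 1L) order(conf, decreasing = TRUE)[seq_len(k)] else integer(0L)
    idx <- sort(idx)
  }
  list(idx = idx, n_selected = length(idx))
}

#' Target cluster loss
#'
#' Mean over the selected target rows of `BCE(d_T, 1)`: the domain
#' discriminator's output on each confident target sample is pushed toward
#' the source label, compacting target representations on the source side of
#' the decision boundary. Returns 0 for an empty selection.
#'
#' @param d_t_selected domain probabilities of the selected target rows.
#' @return scalar loss.
#' @export
cluster_loss <- function(d_t_selected) {
  if (length(d_t_selected) == 0L) return(0)
  bce(1, d_t_selected)
}

#' Assemble the total adversarial objective
#'
#' `L_total = L_cls + L_domain + L_individual + lambda * L_cluster`.
#'
#' @param cls,domain,individual,cluster the four component losses.
#' @param lambda_cluster cluster-term weight `lambda` (default 1).
#' @param n_selected number of target rows behind the cluster term.
#' @return a `loss_bundle` list with the components, `lambda_cluster`,
#'   `n_selected` and `total`.
#' @export
total_loss <- function(cls, domain, individual, cluster,
                       lambda_cluster = 1, n_selected = 0L) {
  structure(list(cls = cls, domain = domain, individual = individual,
                 cluster = cluster, lambda_cluster = lambda_cluster,
                 n_selected = as.integer(n_selected),
                 total = cls + domain + individual + lambda_cluster * cluster),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf(
    "<loss_bundle> total %.4f = cls %.4f + domain %.4f + individual %.4f + %.2f * cluster %.4f (N_selected = %d)\n",
    x$total, x$cls, x$domain, x$individual, x$lambda_cluster, x$cluster,
    x$n_selected))
  invisible(x)
}

# ---- gradients of the losses wrt logits (used by the training loop) --------

# one-vs-all BCE: d/dlogits = (sigmoid(z) - onehot) / (rows * classes);
# softmax CE: (softmax(z) - onehot) / rows
classification_loss_grad <- function(scores, labels, head = "ova_bce") {
  cc <- ncol(scores)
  onehot <- matrix(0, nrow(scores), cc)
  onehot[cbind(seq_along(labels), labels + 1L)] <- 1
  if (head == "ova_bce") {
    (sigmoid(scores) - onehot) / (nrow(scores) * cc)
  } else {
    (softmax_rows(scores) - onehot) / nrow(scores)
  }
}

# d L_domain / d logit for each row: sigmoid BCE gradient with the 1/2 and
# per-side averaging folded in
domain_loss_grad <- function(d_s, d_t) {
  list(s = 0.5 * (d_s - 1) / length(d_s),
       t = 0.5 * d_t / length(d_t))
}

# d L_cluster / d logit on the selected rows
cluster_loss_grad <- function(d_sel) {
  if (length(d_sel) == 0L) return(numeric(0L))
  (d_sel - 1) / length(d_sel)
}

# d L_individual / d logits
individual_loss_grad <- function(prob, id) {
  onehot <- matrix(0, nrow(prob), ncol(prob))
  onehot[cbind(seq_along(id), id + 1L)] <- 1
  (prob - onehot) / nrow(prob)
}
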