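#' Assemble paired source/target mini-batches for one epoch
#'
#' Each batch holds `batch_size/2` source rows and `batch_size/2` target rows
#' (50/50, matching the symmetric averaging of the domain loss), drawn without
#' replacement within the epoch; when the two sets differ in size the larger
#' side keeps filling batches after the smaller is exhausted, and the final
#' batch may be smaller. Concatenation order inside a batch is source rows
#' first, then target rows. Target emotion labels are never exposed.
#'
#' @param source a labeled [feature_set()] (the supervised domain).
#' @param target an unlabeled-use [feature_set()]; its emotion labels are
#'   ignored.
#' @param batch_size even total batch size (default 96).
#' @param seed integer seed controlling the epoch's shuffling.
#' @return list of `domain_batch` objects with elements `xs`, `xt` (feature
#'   arrays), `ys` (source emotion labels), `domain_labels` (1 for source
#'   rows then 0 for target rows), `individual_labels` (0-based subject index
#'   over the sorted union of subjects, source rows first) and
#'   `n_individuals`.
#' @export
make_domain_batches <- function(source, target, batch_size = 96L, seed = 1L) {
  if (n_segments(source) == 0L || n_segments(target) == 0L) {
    stop("source and target must both be non-empty", call. = FALSE)
  }
  if (batch_size %% 2L != 0L || batch_size < 2L) {
    stop("batch_size must be a positive even number", call. = FALSE)
  }
  if (any(is.na(source$labels))) {
    stop("source feature set must be fully labeled", call. = FALSE)
  }
  half <- batch_size %/% 2L
  ns <- n_segments(source); nt <- n_segments(target)
  set.seed(seed)
  ord_s <- sample.int(ns)
  ord_t <- sample.int(nt)
  subjects <- sort(union(unique(source$subject_id), unique(target$subject_id)))
  n_batches <- max(ceiling(ns / half), ceiling(nt / half))
  out <- vector("list", n_batches)
  for (i in seq_len(n_batches)) {
    lo <- (i - 1L) * half + 1L
    is_ <- if (lo <= ns) ord_s[lo:min(i * half, ns)] else integer(0L)
    it_ <- if (lo <= nt) ord_t[lo:min(i * half, nt)] else integer(0L)
    ind <- c(match(source$subject_id[is_], subjects),
             match(target$subject_id[it_], subjects)) - 1L
    out[[i]] <- structure(
      list(xs = source$features[is_, , , drop = FALSE],
           xt = target$features[it_, , , drop = FALSE],
           ys = source$labels[is_],
           domain_labels = c(rep(1L, length(is_)), rep(0L, length(it_))),
           individual_labels = ind,
           n_individuals = length(subjects),
           source_rows = is_, target_rows = it_),
      class = "domain_batch")
  }
  out
}
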