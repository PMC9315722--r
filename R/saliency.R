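#' Scalar node-importance scores from attention gates
#'
#' Reduces per-subject post-softmax gate matrices to one nonnegative score
#' per node: each subject's node score is the mean of that node's gate values
#' across the embedding dimensions, and the group score is the mean across
#' subjects.
#'
#' @param gates a single `N x d` gate matrix or a non-empty list of them
#'   (one per subject of the group).
#' @return Numeric length-`N` vector of node scores.
#' @export
node_weight_from_gates <- function(gates) {
  if (is.matrix(gates)) gates <- list(gates)
  if (!is.list(gates) || length(gates) == 0L)
    stopf("gates must be a non-empty list of gate matrices (empty group?)")
  n <- nrow(gates[[1L]])
  scores <- lapply(gates, function(g) {
    g <- as.matrix(g)
    if (nrow(g) != n) stopf("gate matrices disagree on node count")
    rowMeans(g)
  })
  Reduce(`+`, scores) / length(scores)
}

#' Top-q ROIs by node weight
#'
#' The `q` highest-scoring ROI ids; ties spanning the q-th rank are broken
#' by ascending ROI id, so the selection is deterministic.
#'
#' @param weights numeric length-`N` score vector.
#' @param q number of ROIs to select, `1 <= q <= N`.
#' @param roi_ids optional ROI identifiers; defaults to `1:N`.
#' @return Integer vector of `q` ROI ids, highest score first.
#' @export
top_q_rois <- function(weights, q, roi_ids = seq_along(weights)) {
  n <- length(weights)
  if (q < 1L || q > n) stopf("q must be in 1..%d", n)
  if (length(roi_ids) != n) stopf("roi_ids must match weights length")
  roi_ids[order(-weights, roi_ids)[seq_len(q)]]
}

#' Consolidate per-fold attention into salient-ROI sets
#'
#' For every layer and diagnostic group, counts over the cross-validation
#' folds how often each ROI ranked in the top `q` by attention score, and
#' retains the ROIs selected in *strictly more than* `min_folds` folds (the
#' "more than half of the 10 folds" rule; an ROI selected in exactly
#' `min_folds` folds is excluded).
#'
#' @param x a [gin_cv()] result, or a raw records list shaped
#'   `[[fold]][[layer]]$case / $control` of length-`N` score vectors.
#' @param q top-rank cutoff per fold; default `ceiling(N / 4)` (the "first
#'   quarter" rule, 50 of 200 ROIs).
#' @param min_folds strict lower bound on the selection count; default
#'   `floor(K / 2)` for `K` folds.
#' @return An object of class `salient_rois`: data.frame with columns
#'   `layer`, `group`, `roi_id`, `count`, `mean_weight` (one row per salient
#'   ROI), with attributes `selection_counts` (layer x group x ROI array of
#'   counts for *all* ROIs), `q`, `min_folds`, `n_folds`, `n_rois`.
#' @export
salient_rois <- function(x, q = NULL, min_folds = NULL) {
  records <- if (inherits(x, "gin_cv")) x$gate_records else x
  if (!is.list(records) || length(records) == 0L)
    stopf("no gate records supplied")
  K <- length(records)
  ok <- !vapply(records, is.null, logical(1))
  if (!all(ok))
    stopf("missing gate records for fold(s): %s",
          paste(which(!ok), collapse = ", "))
  L <- length(records[[1L]])
  N <- length(records[[1L]][[1L]]$case %||% records[[1L]][[1L]]$control)
  q <- q %||% as.integer(ceiling(N / 4))
  min_folds <- min_folds %||% (K %/% 2L)
  groups <- c("case", "control")

  counts <- array(0L, dim = c(L, 2L, N),
                  dimnames = list(NULL, groups, NULL))
  wsum <- array(0, dim = c(L, 2L, N))
  for (f in seq_len(K)) {
    if (length(records[[f]]) != L)
      stopf("fold %d has %d layers of records, expected %d",
            f, length(records[[f]]), L)
    for (k in seq_len(L)) {
      for (gi in 1:2) {
        w <- records[[f]][[k]][[groups[gi]]]
        if (is.null(w))
          stopf("missing %s-group record for fold %d, layer %d", groups[gi], f, k)
        sel <- top_q_rois(w, q)
        counts[k, gi, sel] <- counts[k, gi, sel] + 1L
        wsum[k, gi, ] <- wsum[k, gi, ] + w
      }
    }
  }

  rows <- list()
  for (k in seq_len(L)) {
    for (gi in 1:2) {
      inc <- which(counts[k, gi, ] > min_folds)
      if (length(inc))
        rows[[length(rows) + 1L]] <- data.frame(
          layer = k, group = groups[gi], roi_id = inc,
          count = counts[k, gi, inc],
          mean_weight = wsum[k, gi, inc] / K)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(layer = integer(0), group = character(0),
                         roi_id = integer(0), count = integer(0),
                         mean_weight = numeric(0))
  structure(out, selection_counts = counts, q = q, min_folds = min_folds,
            n_folds = K, n_rois = N,
            class = c("salient_rois", "data.frame"))
}

#' @exportS3Method base::print
print.salient_rois <- function(x, ...) {
  cat(sprintf("Salient ROIs: top-%d per fold, retained if selected in > %d of %d folds\n",
              attr(x, "q"), attr(x, "min_folds"), attr(x, "n_folds")))
  if (nrow(x) == 0L) {
    cat("  (no ROI met the selection rule)\n")
    return(invisible(x))
  }
  tab <- table(x$layer, x$group)
  cat("  set sizes (layer x group):\n")
  print(tab)
  invisible(x)
}

#' Network composition of salient-ROI sets
#'
#' For each (layer, group) salient set, the fraction of its ROIs falling in
#' each of the seven canonical functional networks (the quantities shown as
#' pie charts in connectome-saliency figures). Fractions sum to 1 within
#' each set.
#'
#' @param x a [salient_rois()] result with at least one salient ROI.
#' @param parcellation data.frame with columns `roi_id`, `roi_name`,
#'   `network`, `x`, `y`, `z` (see [read_parcellation()] /
#'   [toy_parcellation()]).
#' @return data.frame with columns `layer`, `group`, `network`, `n_rois`,
#'   `fraction`.
#' @export
network_proportions <- function(x, parcellation) {
  stopifnot(inherits(x, "salient_rois"))
  parc <- validate_parcellation(parcellation)
  if (nrow(x) == 0L)
    stopf("empty salient-ROI set: no proportions defined")
  unknown <- setdiff(x$roi_id, parc$roi_id)
  if (length(unknown))
    stopf("salient ROI id(s) not in parcellation: %s",
          paste(unknown, collapse = ", "))
  net <- parc$network[match(x$roi_id, parc$roi_id)]
  out <- list()
  for (k in unique(x$layer)) {
    for (g in unique(x$group[x$layer == k])) {
      sel <- x$layer == k & x$group == g
      tab <- table(factor(net[sel], levels = yeo7_networks))
      out[[length(out) + 1L]] <- data.frame(
        layer = k, group = g, network = yeo7_networks,
        n_rois = as.integer(tab), fraction = as.numeric(tab) / sum(sel),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
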