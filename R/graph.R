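new_brain_graph <- function(subject_id, label, n_nodes, edges, weights,
                            feature_ids = seq_len(n_nodes),
                            density = NA_real_, case = NA_character_,
                            roi_ids = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  structure(
    list(subject_id = as.character(subject_id),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         n_nodes = as.integer(n_nodes),
         edges = edges,
         weights = as.numeric(weights),
         feature_ids = as.integer(feature_ids),
         density = density, case = as.character(case),
         roi_ids = roi_ids),
    class = "brain_graph"
  )
}

#' Build a sparse weighted brain graph from an FC matrix
#'
#' Thresholds a Fisher-z functional-connectivity matrix down to the strongest
#' `density` percent of the `N(N-1)/2` candidate connections and returns an
#' undirected weighted graph whose nodes are ROIs and whose node features are
#' one-hot ROI labels. Three edge-weight conventions are supported:
#'
#' * `"abs"` — rank by `|z|`, keep `|z|` as the weight (all weights
#'   positive);
#' * `"positive_only"` — discard non-positive connections, rank the positive
#'   ones by `z`, keep `z`;
#' * `"signed"` — rank by `|z|` (so strong negative connections are retained
#'   rather than discarded), keep the signed `z` as the weight.
#'
#' The number of retained edges is `round(density/100 * N(N-1)/2)`
#' (half-up). Ties at the cutoff are broken deterministically by descending
#' ranking key, then ascending `(i, j)`. Under `"positive_only"`, if fewer
#' positive connections exist than the target count, all of them are kept and
#' a warning is issued.
#'
#' @param fc an `fc_matrix`.
#' @param label binary class label (0 = control, 1 = case) or `NA`.
#' @param density percentage of candidate edges to retain, in (0, 100].
#' @param case edge-weight convention, one of `"abs"`, `"positive_only"`,
#'   `"signed"`.
#' @return An object of class `brain_graph`: list with `edges` (two-column
#'   matrix, `i < j`, 1-based), `weights`, `n_nodes`, `label`, `feature_ids`
#'   (which one-hot input feature each node carries; identity by default).
#' @examples
#' fc <- compute_fc(matrix(rnorm(60 * 10), 60))
#' g <- build_graph(fc, label = 0, density = 25)
#' nrow(g$edges)  # round(0.25 * 45) = 11
#' @export
build_graph <- function(fc, label = NA_integer_, density = 25,
                        case = c("abs", "positive_only", "signed")) {
  stopifnot(inherits(fc, "fc_matrix"))
  case <- match.arg(case)
  if (!is.numeric(density) || length(density) != 1L || density <= 0 || density > 100)
    stopf("density must be a percentage in (0, 100], got %s", format(density))
  if (!is.na(label) && !label %in% c(0, 1))
    stopf("label must be 0, 1 or NA")
  n <- fc$n_rois
  ut <- which(upper.tri(fc$z))
  ii <- row(fc$z)[ut]
  jj <- col(fc$z)[ut]
  zz <- fc$z[ut]
  n_pairs <- length(zz)
  target <- round_half_up(density / 100 * n_pairs)

  if (case == "positive_only") {
    keep <- zz > 0
    ii <- ii[keep]; jj <- jj[keep]; zz <- zz[keep]
    key <- zz
    w <- zz
    if (length(zz) < target) {
      warnf("only %d positive connections available for target of %d edges; keeping all",
            length(zz), target)
      target <- length(zz)
    }
  } else {
    key <- abs(zz)
    w <- if (case == "abs") abs(zz) else zz
  }

  ord <- order(-key, ii, jj)
  sel <- ord[seq_len(target)]
  # canonical storage order: ascending (i, j)
  o2 <- order(ii[sel], jj[sel])
  sel <- sel[o2]
  new_brain_graph(fc$subject_id, label, n,
                  edges = cbind(ii[sel], jj[sel]), weights = w[sel],
                  density = density, case = case, roi_ids = fc$roi_ids)
}

#' @exportS3Method base::print
print.brain_graph <- function(x, ...) {
  cat(sprintf("Brain graph '%s': %d nodes, %d edges (density %s%%, case '%s'), label %s\n",
              x$subject_id, x$n_nodes, nrow(x$edges),
              format(x$density), x$case,
              if (is.na(x$label)) "NA" else x$label))
  invisible(x)
}

#' Relabel the nodes of a brain graph
#'
#' Applies a node permutation: node `v` of the input becomes node `perm[v]`
#' of the output, carrying its one-hot feature and incident edges with it.
#' Model predictions are invariant under this operation (the Weisfeiler-Lehman
#' consistency property of the GIN).
#'
#' @param graph a [build_graph()] result.
#' @param perm integer permutation of `1:n_nodes`.
#' @return A `brain_graph`.
#' @export
permute_graph <- function(graph, perm) {
  stopifnot(inherits(graph, "brain_graph"))
  n <- graph$n_nodes
  if (length(perm) != n || !setequal(perm, seq_len(n)))
    stopf("perm must be a permutation of 1:%d", n)
  pi_ <- perm[graph$edges[, 1L]]
  pj <- perm[graph$edges[, 2L]]
  ei <- pmin(pi_, pj)
  ej <- pmax(pi_, pj)
  o <- order(ei, ej)
  feat <- integer(n)
  feat[perm] <- graph$feature_ids
  new_brain_graph(graph$subject_id, graph$label, n,
                  edges = cbind(ei[o], ej[o]), weights = graph$weights[o],
                  feature_ids = feat,
                  density = graph$density, case = graph$case,
                  roi_ids = graph$roi_ids)
}

# weighted symmetric adjacency as a sparse Matrix (no self loops)
graph_adjacency <- function(graph) {
  n <- graph$n_nodes
  e <- graph$edges
  if (nrow(e) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = rep(graph$weights, 2L), dims = c(n, n))
}
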