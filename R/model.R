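#' GIN classifier architecture configuration
#'
#' Hyperparameters of the edge-weighted Graph Isomorphism Network (GIN)
#' classifier: `n_layers` message-passing layers, each a
#' `(1 + epsilon) * h_v + sum_u w_uv * h_u` aggregation followed by a
#' `mlp_depth`-layer perceptron; per-layer gated attention pooling; and a
#' readout that sums per-layer class scores (or, optionally, classifies the
#' concatenated per-layer graph embeddings).
#'
#' `epsilon_mode = "fixed_zero"` is the GIN-0 variant (epsilon frozen at 0);
#' `"learnable"` registers one trainable scalar per layer initialized at
#' `epsilon_init`.
#'
#' The attention gate is vector-valued by default (a learned linear map to
#' the embedding dimension, softmax-normalized across nodes independently per
#' dimension); `gate_mode = "scalar"` switches to a single softmax weight per
#' node for sensitivity analyses.
#'
#' @param input_dim node-feature dimension; equals the node count `N` because
#'   node features are one-hot ROI labels.
#' @param n_layers number of GIN layers `L`.
#' @param mlp_depth number of linear layers in each GIN update MLP.
#' @param hidden_dim embedding width of every hidden layer.
#' @param epsilon_mode `"fixed_zero"` or `"learnable"`.
#' @param epsilon_init initial epsilon when learnable.
#' @param dropout dropout rate applied to pooled graph embeddings before the
#'   readout linear layer, training time only. In `[0, 1)`.
#' @param n_classes number of classes (2: control vs case).
#' @param batch_norm use batch normalization between MLP linear layers?
#' @param gate_mode `"vector"` or `"scalar"` attention gate.
#' @param readout `"sum"` (sum of per-layer class scores) or `"concat"`
#'   (single linear layer on concatenated embeddings).
#' @return An object of class `gin_config`.
#' @export
gin_config <- function(input_dim, n_layers = 4L, mlp_depth = 2L,
                       hidden_dim = 64L,
                       epsilon_mode = c("fixed_zero", "learnable"),
                       epsilon_init = 0.1, dropout = 0.2, n_classes = 2L,
                       batch_norm = TRUE,
                       gate_mode = c("vector", "scalar"),
                       readout = c("sum", "concat")) {
  epsilon_mode <- match.arg(epsilon_mode)
  gate_mode <- match.arg(gate_mode)
  readout <- match.arg(readout)
  stopifnot(input_dim >= 1L, n_layers >= 1L, mlp_depth >= 1L, hidden_dim >= 1L,
            n_classes >= 2L, dropout >= 0, dropout < 1)
  structure(
    list(input_dim = as.integer(input_dim), n_layers = as.integer(n_layers),
         mlp_depth = as.integer(mlp_depth), hidden_dim = as.integer(hidden_dim),
         epsilon_mode = epsilon_mode, epsilon_init = epsilon_init,
         dropout = dropout, n_classes = as.integer(n_classes),
         batch_norm = batch_norm, gate_mode = gate_mode, readout = readout),
    class = "gin_config"
  )
}

#' @exportS3Method base::print
print.gin_config <- function(x, ...) {
  cat(sprintf(paste0("GIN config: %d layers (hidden %d, MLP depth %d%s), ",
                     "epsilon %s, %s gate, %s readout, dropout %g, %d-dim one-hot input\n"),
              x$n_layers, x$hidden_dim, x$mlp_depth,
              if (x$batch_norm) ", batch-norm" else "",
              if (x$epsilon_mode == "fixed_zero") "= 0 (GIN-0)"
              else sprintf("learnable (init %g)", x$epsilon_init),
              x$gate_mode, x$readout, x$dropout, x$input_dim))
  invisible(x)
}

# Parameters are stored output-major (d_out x d_in): internally all node
# embeddings live as d x M matrices (features in rows, nodes in columns), so
# bias and batch-norm broadcasts are plain vector recycling.
glorot_uniform <- function(d_out, d_in) {
  a <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_out * d_in, -a, a), d_out, d_in)
}

#' Initialize GIN parameters
#'
#' Creates a fresh parameter state for a [gin_config()]: Glorot-uniform
#' weight matrices, zero biases, unit batch-norm scale. Deterministic given
#' `seed`.
#'
#' @param config a [gin_config()].
#' @param seed RNG seed; `NULL` draws from the current stream.
#' @return An object of class `gin_state`.
#' @export
init_gin_state <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gin_config"))
  build <- function() {
    L <- config$n_layers
    h <- config$hidden_dim
    m <- config$mlp_depth
    layers <- vector("list", L)
    for (k in seq_len(L)) {
      d_in <- if (k == 1L) config$input_dim else h
      W <- vector("list", m); b <- vector("list", m)
      for (j in seq_len(m)) {
        W[[j]] <- glorot_uniform(h, if (j == 1L) d_in else h)
        b[[j]] <- numeric(h)
      }
      bn <- NULL
      if (config$batch_norm && m >= 2L) {
        bn <- lapply(seq_len(m - 1L), function(j)
          list(gamma = rep(1, h), beta = numeric(h),
               run_mean = numeric(h), run_var = rep(1, h)))
      }
      gd <- if (config$gate_mode == "vector") h else 1L
      layers[[k]] <- list(
        W = W, b = b, bn = bn,
        eps = if (config$epsilon_mode == "learnable") config$epsilon_init else 0,
        Wg = glorot_uniform(gd, h), bg = numeric(gd),
        Wr = if (config$readout == "sum") glorot_uniform(config$n_classes, h),
        br = if (config$readout == "sum") numeric(config$n_classes)
      )
    }
    readout <- NULL
    if (config$readout == "concat")
      readout <- list(W = glorot_uniform(config$n_classes, L * h),
                      b = numeric(config$n_classes))
    structure(list(schema_version = "braingin-model/1", config = config,
                   layers = layers, readout = readout, seed = seed),
              class = "gin_state")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

n_params <- function(state) {
  cnt <- 0L
  acc <- function(x) {
    if (is.numeric(x)) cnt <<- cnt + length(x)
    else if (is.list(x)) lapply(x, acc)
    invisible(NULL)
  }
  for (lp in state$layers) {
    acc(lp$W); acc(lp$b); acc(lp$Wg); acc(lp$bg)
    if (!is.null(lp$Wr)) { acc(lp$Wr); acc(lp$br) }
    if (!is.null(lp$bn)) for (bnj in lp$bn) { acc(bnj$gamma); acc(bnj$beta) }
    if (state$config$epsilon_mode == "learnable") cnt <- cnt + 1L
  }
  if (!is.null(state$readout)) { acc(state$readout$W); acc(state$readout$b) }
  cnt
}

#' @exportS3Method base::print
print.gin_state <- function(x, ...) {
  cat(sprintf("GIN parameter state: %d layers, %d trainable parameters\n",
              x$config$n_layers, n_params(x)))
  invisible(x)
}

BN_EPS <- 1e-5

is_sparse <- function(x) inherits(x, "sparseMatrix")

# D %*% S with S a dgCMatrix, via the compiled CSC kernel. All sparse
# matrices built in this file are already column-compressed.
spmul <- function(D, S) {
  if (!inherits(S, "dgCMatrix")) S <- methods::as(S, "CsparseMatrix")
  dense_sparse_prod(D, S)
}

# MLP of one GIN layer on feature-major input (d_in x M). `X` may be sparse
# (layer-1 aggregate of one-hot features). use_batch_stats: normalize by this
# batch's statistics (training) or by running statistics (inference).
# ReLU activation masks are recovered from the cached ReLU *outputs*
# (out > 0), so pre-activation matrices need not be cached.
mlp_forward <- function(X, lp, cfg, use_batch_stats, keep_cache = FALSE) {
  m <- cfg$mlp_depth
  cache <- if (keep_cache) list(X = vector("list", m),
                                Uhat = vector("list", m),
                                invstd = vector("list", m), tX1 = NULL)
  H <- X
  bn_new <- NULL
  for (j in seq_len(m)) {
    if (keep_cache) {
      if (j == 1L && is_sparse(H)) cache$tX1 <- Matrix::t(H)
      else cache$X[[j]] <- H
    }
    U <- if (is_sparse(H)) spmul(lp$W[[j]], H) else lp$W[[j]] %*% H
    add_bias_inplace(U, lp$b[[j]])
    if (j < m && !is.null(lp$bn)) {
      bnj <- lp$bn[[j]]
      if (use_batch_stats) {
        mv <- row_mean_var(U)
        mu <- mv$mu
        va <- mv$va
        if (is.null(bn_new)) bn_new <- vector("list", m - 1L)
        bn_new[[j]] <- list(mu = mu, va = va)
      } else {
        mu <- bnj$run_mean
        va <- bnj$run_var
      }
      invstd <- 1 / sqrt(va + BN_EPS)
      bf <- bn_fwd(U, mu, invstd, bnj$gamma, bnj$beta)
      if (keep_cache) {
        cache$Uhat[[j]] <- bf$Uhat
        cache$invstd[[j]] <- invstd
      }
      H <- relu_fwd(bf$Bout)
    } else {
      H <- relu_fwd(U)
    }
  }
  list(H = H, cache = cache, bn_batch = bn_new)
}

# need_dX: the gradient w.r.t. the layer input is only needed when a
# previous GIN layer exists. `Hout` is the layer's cached ReLU output (the
# activation mask). Returns dU1 (gradient at the first linear output) for
# the layer-1 epsilon gradient.
mlp_backward <- function(dH, Hout, lp, cfg, cache, need_dX = TRUE) {
  m <- cfg$mlp_depth
  gW <- vector("list", m); gb <- vector("list", m)
  gGamma <- NULL; gBeta <- NULL
  if (!is.null(lp$bn)) { gGamma <- vector("list", m - 1L); gBeta <- vector("list", m - 1L) }
  dU <- relu_bwd(dH, Hout)
  for (j in rev(seq_len(m))) {
    gW[[j]] <- if (j == 1L && !is.null(cache$tX1)) spmul(dU, cache$tX1)
               else tcrossprod(dU, cache$X[[j]])
    gb[[j]] <- rowSums(dU)
    if (j == 1L) {
      dX <- if (need_dX) crossprod(lp$W[[1L]], dU)
      return(list(dX = dX, dU1 = dU, gW = gW, gb = gb,
                  gGamma = gGamma, gBeta = gBeta))
    }
    dX <- crossprod(lp$W[[j]], dU)
    jm <- j - 1L
    dBout <- relu_bwd(dX, cache$X[[j]])   # X[[j]] is sublayer jm's ReLU output
    if (!is.null(lp$bn)) {
      bb <- bn_bwd(dBout, cache$Uhat[[jm]], lp$bn[[jm]]$gamma,
                   cache$invstd[[jm]])
      gGamma[[jm]] <- bb$gGamma
      gBeta[[jm]] <- bb$gBeta
      dU <- bb$dU
    } else {
      dU <- dBout
    }
  }
}

# Gated attention pooling over nodes, batched. Softmax is taken across the
# nodes of each graph, independently per gate dimension. The vector-gate
# default runs in the fused kernel; the scalar-gate variant is a plain-R
# path.
gate_forward <- function(H, batch, lp, cfg) {
  Graw <- lp$Wg %*% H
  add_bias_inplace(Graw, lp$bg)
  if (cfg$gate_mode == "vector") {
    sp <- softmax_pool_fwd(Graw, H, batch$gid, batch$B)
    return(list(g = sp$g, gate = sp$gate))
  }
  rmax <- max(Graw)
  E <- exp(Graw - rmax)
  den <- spmul(E, batch$P)
  den[den < 1e-300] <- 1e-300
  gate <- E / den[, batch$gid, drop = FALSE]
  g <- spmul(H * rep(as.vector(gate), each = nrow(H)), batch$P)
  list(g = g, gate = gate)
}

gate_backward <- function(dg, H, gate, batch, lp, cfg) {
  gid <- batch$gid
  if (cfg$gate_mode == "vector") {
    sb <- softmax_pool_bwd(dg, H, gate, gid)
    dH <- sb$dH
    dGraw <- sb$dGraw
    axpy_inplace(dH, crossprod(lp$Wg, dGraw), 1)
  } else {
    h <- nrow(H)
    gv <- as.vector(gate)
    dgE <- dg[, gid, drop = FALSE]
    dgate <- colSums(dgE * H)
    dH <- dgE * rep(gv, each = h)
    s <- as.vector(spmul(matrix(gv * dgate, 1L), batch$P))
    dGraw <- matrix(gv * (dgate - s[gid]), 1L)
    dH <- dH + crossprod(lp$Wg, dGraw)
  }
  list(dH = dH, gWg = tcrossprod(dGraw, H), gbg = rowSums(dGraw))
}

graph_triplets <- function(graph) {
  e <- graph$edges
  list(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
       x = rep(graph$weights, 2L), feat = graph$feature_ids,
       n = graph$n_nodes)
}

# Assemble a block-diagonal batch (an environment, so the layer-1 aggregate
# can be memoized). Fields: A (M x M weighted adjacency), P (M x B pooling
# indicator), S (input_dim x M: one-hot features folded through A), feat,
# gid, B, M.
make_batch <- function(trips, input_dim) {
  ns <- vapply(trips, `[[`, integer(1), "n")
  off <- cumsum(c(0L, ns[-length(ns)]))
  M <- sum(ns)
  ii <- unlist(mapply(function(tr, o) tr$i + o, trips, off, SIMPLIFY = FALSE),
               use.names = FALSE)
  jj <- unlist(mapply(function(tr, o) tr$j + o, trips, off, SIMPLIFY = FALSE),
               use.names = FALSE)
  xx <- unlist(lapply(trips, `[[`, "x"), use.names = FALSE)
  feat <- unlist(lapply(trips, `[[`, "feat"), use.names = FALSE)
  b <- new.env(parent = emptyenv())
  b$A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(M, M))
  b$P <- Matrix::sparseMatrix(i = seq_len(M),
                              j = rep(seq_along(trips), times = ns),
                              x = 1, dims = c(M, length(trips)))
  # S[f, m] = sum over nodes c with feature f of A[c, m]: the sparse layer-1
  # aggregate of the one-hot inputs, built directly from triplets
  b$S <- Matrix::sparseMatrix(i = feat[ii], j = jj, x = xx,
                              dims = c(input_dim, M))
  b$feat <- feat
  b$gid <- rep(seq_along(trips), times = ns)
  b$B <- length(trips)
  b$M <- M
  b$input_dim <- input_dim
  b$Z1_eps <- NA_real_
  b
}

# Layer-1 aggregate (1 + eps) * H0 + H0 %*% A as a sparse input_dim x M
# matrix, memoized per batch (it only changes when epsilon does).
batch_layer1 <- function(batch, eps) {
  if (!identical(batch$Z1_eps, eps)) {
    self <- Matrix::sparseMatrix(i = batch$feat, j = seq_len(batch$M),
                                 x = rep(1 + eps, batch$M),
                                 dims = c(batch$input_dim, batch$M))
    batch$Z1 <- methods::as(batch$S + self, "CsparseMatrix")
    batch$tZ1 <- Matrix::t(batch$Z1)
    batch$Z1_eps <- eps
  }
  batch
}

# Full batched forward pass (feature-major). Returns logits (B x n_classes)
# and, on request, per-layer node gates / embeddings (d x M) and the caches
# for the backward pass.
forward_batch <- function(state, batch, training = FALSE,
                          collect_gates = FALSE, collect_embeddings = FALSE,
                          keep_cache = FALSE) {
  cfg <- state$config
  L <- cfg$n_layers
  B <- batch$B
  H <- NULL
  caches <- if (keep_cache) vector("list", L)
  gates <- if (collect_gates) vector("list", L)
  embs <- if (collect_embeddings) vector("list", L)
  gs <- vector("list", L)
  bn_updates <- vector("list", L)
  logits_t <- matrix(0, cfg$n_classes, B)
  for (k in seq_len(L)) {
    lp <- state$layers[[k]]
    H_prev <- H
    Z <- if (k == 1L) {
      batch_layer1(batch, lp$eps)$Z1
    } else {
      Zk <- spmul(H_prev, batch$A)
      axpy_inplace(Zk, H_prev, 1 + lp$eps)
      Zk
    }
    mf <- mlp_forward(Z, lp, cfg, use_batch_stats = training,
                      keep_cache = keep_cache)
    H <- mf$H
    bn_updates[[k]] <- mf$bn_batch
    gf <- gate_forward(H, batch, lp, cfg)
    g <- gf$g
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- matrix((stats::runif(length(g)) >= cfg$dropout) / (1 - cfg$dropout),
                     nrow(g), ncol(g))
      g <- g * mask
    }
    gs[[k]] <- g
    if (cfg$readout == "sum")
      logits_t <- logits_t + lp$Wr %*% g + lp$br
    if (collect_gates) gates[[k]] <- gf$gate
    if (collect_embeddings) embs[[k]] <- H
    if (keep_cache)
      caches[[k]] <- list(H_prev = H_prev, H = H, mlp = mf$cache,
                          gate = gf$gate, mask = mask)
  }
  if (cfg$readout == "concat") {
    gcat <- do.call(rbind, gs)
    logits_t <- state$readout$W %*% gcat + state$readout$b
  }
  list(logits = t(logits_t), caches = caches, gates = gates,
       embeddings = embs, gs = gs, bn_updates = bn_updates)
}

single_graph_batch <- function(graph, input_dim) {
  make_batch(list(graph_triplets(graph)), input_dim)
}

#' One edge-weighted GIN layer applied to a graph
#'
#' Computes, for every node `v`, the aggregate
#' `(1 + epsilon) * h_v + sum_{u in N(v)} w_uv * h_u` (each undirected edge
#' contributing in both directions; an isolated node reduces to its scaled
#' self term) and passes the result row-wise through the layer's MLP.
#'
#' @param h_prev `N x d` matrix of node representations entering layer `k`.
#' @param graph a [build_graph()] result.
#' @param state a `gin_state`.
#' @param k layer index.
#' @param training use batch statistics in batch-norm (training-time
#'   behaviour)? Defaults to inference-mode running statistics.
#' @return `N x hidden_dim` matrix of updated node representations.
#' @export
gin_layer_forward <- function(h_prev, graph, state, k, training = FALSE) {
  stopifnot(inherits(state, "gin_state"), inherits(graph, "brain_graph"))
  cfg <- state$config
  if (k < 1L || k > cfg$n_layers) stopf("layer index k must be in 1..%d", cfg$n_layers)
  h_prev <- as.matrix(h_prev)
  d_exp <- if (k == 1L) cfg$input_dim else cfg$hidden_dim
  if (nrow(h_prev) != graph$n_nodes || ncol(h_prev) != d_exp)
    stopf("h_prev must be %d x %d for layer %d, got %d x %d",
          graph$n_nodes, d_exp, k, nrow(h_prev), ncol(h_prev))
  lp <- state$layers[[k]]
  Ht <- t(h_prev)
  Z <- (1 + lp$eps) * Ht + spmul(Ht, graph_adjacency(graph))
  t(mlp_forward(Z, lp, cfg, use_batch_stats = training)$H)
}

#' Gated attention pooling of node embeddings
#'
#' Collapses an `N x d` matrix of node representations into one graph-level
#' embedding. A learned linear gate scores every node; scores are
#' softmax-normalized across the nodes (independently for each embedding
#' dimension under the vector gate, a single weight per node under the scalar
#' gate) and the graph embedding is the gate-weighted sum of node embeddings.
#' The post-softmax gate values are returned as well: they are the node
#' importance scores used for salient-ROI extraction.
#'
#' @param x `N x hidden_dim` node-embedding matrix, `N >= 1`.
#' @param state a `gin_state`.
#' @param k layer index (selects that layer's gate parameters).
#' @return List with `embedding` (length-`d` vector) and `gates` (`N x d`
#'   matrix for the vector gate, `N x 1` for the scalar gate; every column
#'   sums to 1 over nodes).
#' @export
attention_pool <- function(x, state, k) {
  stopifnot(inherits(state, "gin_state"))
  cfg <- state$config
  if (k < 1L || k > cfg$n_layers) stopf("layer index k must be in 1..%d", cfg$n_layers)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stopf("cannot pool an empty node set")
  if (ncol(x) != cfg$hidden_dim)
    stopf("x must have %d columns, got %d", cfg$hidden_dim, ncol(x))
  n <- nrow(x)
  b <- new.env(parent = emptyenv())
  b$P <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                              dims = c(n, 1L))
  b$gid <- rep(1L, n)
  b$B <- 1L
  gf <- gate_forward(t(x), b, state$layers[[k]], cfg)
  list(embedding = as.vector(gf$g), gates = t(gf$gate))
}

#' Multi-layer readout: class scores from per-layer graph embeddings
#'
#' Maps each layer's pooled graph embedding through that layer's linear
#' classifier and sums the scores over layers (or, under the `"concat"`
#' readout, applies a single linear layer to the concatenated embeddings).
#' Dropout is applied to the embeddings at training time only.
#'
#' @param gs list of `n_layers` graph-embedding vectors (length
#'   `hidden_dim` each).
#' @param state a `gin_state`.
#' @param training apply dropout?
#' @return Numeric vector of `n_classes` scores (logits).
#' @export
readout_predict <- function(gs, state, training = FALSE) {
  stopifnot(inherits(state, "gin_state"))
  cfg <- state$config
  if (!is.list(gs) || length(gs) != cfg$n_layers)
    stopf("gs must be a list of %d per-layer embeddings, got %d",
          cfg$n_layers, length(gs))
  gs <- lapply(gs, function(g) {
    g <- as.numeric(g)
    if (length(g) != cfg$hidden_dim)
      stopf("each embedding must have length %d", cfg$hidden_dim)
    if (training && cfg$dropout > 0)
      g <- g * ((stats::runif(length(g)) >= cfg$dropout) / (1 - cfg$dropout))
    g
  })
  if (cfg$readout == "sum") {
    out <- numeric(cfg$n_classes)
    for (k in seq_len(cfg$n_layers)) {
      lp <- state$layers[[k]]
      out <- out + as.vector(lp$Wr %*% gs[[k]]) + lp$br
    }
    out
  } else {
    as.vector(state$readout$W %*% unlist(gs)) + state$readout$b
  }
}

#' Full forward pass of the GIN classifier on one graph
#'
#' Chains the `n_layers` GIN updates, pools every layer's node embeddings by
#' gated attention, and computes class scores through the readout. The
#' post-softmax node gates of every layer are returned for saliency analysis.
#' Deterministic given `(state, graph)` when `training = FALSE`.
#'
#' @param graph a [build_graph()] result whose node count matches
#'   `config$input_dim`.
#' @param state a `gin_state`.
#' @param training training-time behaviour (batch-norm batch statistics,
#'   dropout)?
#' @return List with `logits` (length `n_classes`), `gates` (list of
#'   per-layer `N x d` gate matrices) and `embeddings` (list of per-layer
#'   `N x d` node representations).
#' @export
gin_forward <- function(graph, state, training = FALSE) {
  stopifnot(inherits(state, "gin_state"), inherits(graph, "brain_graph"))
  cfg <- state$config
  if (graph$n_nodes != cfg$input_dim)
    stopf("graph has %d nodes but the model expects %d one-hot input features",
          graph$n_nodes, cfg$input_dim)
  fw <- forward_batch(state, single_graph_batch(graph, cfg$input_dim),
                      training = training, collect_gates = TRUE,
                      collect_embeddings = TRUE)
  list(logits = as.vector(fw$logits), gates = lapply(fw$gates, t),
       embeddings = lapply(fw$embeddings, t))
}
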