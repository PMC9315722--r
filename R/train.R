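#' Training configuration
#'
#' Optimization and cross-validation settings: Adam with cross-entropy loss,
#' a fixed epoch budget (no early stopping, which keeps runs deterministic),
#' and stratified k-fold splitting.
#'
#' @param learning_rate Adam step size.
#' @param n_epochs number of passes over the training set.
#' @param batch_size graphs per minibatch.
#' @param n_folds folds for [gin_cv()].
#' @param seed RNG seed governing initialization, shuffling and dropout.
#' @param weight_decay L2 penalty coefficient on weight matrices (not biases,
#'   batch-norm or epsilon).
#' @return An object of class `train_control`.
#' @export
train_control <- function(learning_rate = 0.005, n_epochs = 200L,
                          batch_size = 32L, n_folds = 10L, seed = 1L,
                          weight_decay = 0) {
  stopifnot(learning_rate >= 0, n_epochs >= 1L, batch_size >= 1L,
            n_folds >= 2L, weight_decay >= 0)
  structure(
    list(learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
         batch_size = as.integer(batch_size), n_folds = as.integer(n_folds),
         seed = as.integer(seed), weight_decay = weight_decay),
    class = "train_control"
  )
}

#' @exportS3Method base::print
print.train_control <- function(x, ...) {
  cat(sprintf("Training control: Adam lr %g, %d epochs, batch %d, %d folds, seed %d, weight decay %g\n",
              x$learning_rate, x$n_epochs, x$batch_size, x$n_folds, x$seed,
              x$weight_decay))
  invisible(x)
}

softmax_ce <- function(logits, y) {
  B <- nrow(logits)
  rmax <- logits[, 1L]
  for (cc in seq_len(ncol(logits))[-1L]) rmax <- pmax(rmax, logits[, cc])
  E <- exp(logits - rmax)
  Z <- rowSums(E)
  P <- E / Z
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  d <- P
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / B, prob = P)
}

backward_batch <- function(state, batch, fw, dlogits) {
  cfg <- state$config
  L <- cfg$n_layers
  learn_eps <- cfg$epsilon_mode == "learnable"
  glayers <- vector("list", L)
  greadout <- NULL
  dlog_t <- t(dlogits)                      # n_classes x B

  # readout backward -> per-layer embedding gradients (hidden_dim x B)
  dgs <- vector("list", L)
  if (cfg$readout == "sum") {
    for (k in seq_len(L))
      dgs[[k]] <- crossprod(state$layers[[k]]$Wr, dlog_t)
  } else {
    gcat <- do.call(rbind, fw$gs)
    greadout <- list(W = tcrossprod(dlog_t, gcat), b = rowSums(dlog_t))
    dgcat <- crossprod(state$readout$W, dlog_t)
    h <- cfg$hidden_dim
    for (k in seq_len(L))
      dgs[[k]] <- dgcat[((k - 1L) * h + 1L):(k * h), , drop = FALSE]
  }

  dH_next <- NULL
  for (k in rev(seq_len(L))) {
    lp <- state$layers[[k]]
    cc <- fw$caches[[k]]
    dg <- dgs[[k]]
    if (!is.null(cc$mask)) dg <- dg * cc$mask
    gbk <- gate_backward(dg, cc$H, cc$gate, batch, lp, cfg)
    dH <- gbk$dH
    if (!is.null(dH_next)) axpy_inplace(dH, dH_next, 1)
    mb <- mlp_backward(dH, cc$H, lp, cfg, cc$mlp, need_dX = k > 1L)
    geps <- NULL
    if (learn_eps) {
      # layer 1: d loss / d eps = sum(dZ * H0) collapses onto the one-hot
      # columns of W1, so dZ itself is never materialized
      geps <- if (k == 1L) {
        sum(mb$dU1 * lp$W[[1L]][, batch$feat, drop = FALSE])
      } else {
        sum(mb$dX * cc$H_prev)
      }
    }
    if (k > 1L) {
      dH_next <- spmul(mb$dX, batch$A)
      axpy_inplace(dH_next, mb$dX, 1 + lp$eps)
    }
    bn_g <- NULL
    if (!is.null(mb$gGamma))
      bn_g <- lapply(seq_along(mb$gGamma), function(j)
        list(gamma = mb$gGamma[[j]], beta = mb$gBeta[[j]]))
    glayers[[k]] <- list(
      W = mb$gW, b = mb$gb, bn = bn_g, eps = geps,
      Wg = gbk$gWg, bg = gbk$gbg,
      Wr = if (cfg$readout == "sum") tcrossprod(dlog_t, fw$gs[[k]]),
      br = if (cfg$readout == "sum") rowSums(dlog_t)
    )
  }
  list(layers = glayers, readout = greadout)
}

# One Adam step applied in place over the (parameter, gradient) trees.
# Gradient leaves that are NULL are skipped, so frozen parameters (epsilon in
# GIN-0 mode, batch-norm running statistics) are never touched.
adam_recurse <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8) {
  if (is.null(g)) return(list(p = p, m = m, v = v))
  if (is.numeric(g)) {
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    return(list(p = p - lr * mh / (sqrt(vh) + adam_eps), m = m, v = v))
  }
  if (is.null(m)) { m <- vector("list", length(g)); v <- vector("list", length(g)) }
  nm <- names(g)
  for (idx in seq_along(g)) {
    key <- if (!is.null(nm) && nzchar(nm[idx])) nm[idx] else idx
    res <- adam_recurse(p[[key]], g[[idx]], m[[idx]], v[[idx]], lr, t,
                        beta1, beta2, adam_eps)
    # single-bracket assignment: storing NULL must keep the slot, not drop it
    p[key] <- list(res$p)
    m[idx] <- list(res$m)
    v[idx] <- list(res$v)
  }
  list(p = p, m = m, v = v)
}

BN_MOMENTUM <- 0.1

apply_bn_updates <- function(state, bn_updates) {
  for (k in seq_along(bn_updates)) {
    upd <- bn_updates[[k]]
    if (is.null(upd)) next
    for (j in seq_along(upd)) {
      if (is.null(upd[[j]])) next
      bnj <- state$layers[[k]]$bn[[j]]
      bnj$run_mean <- (1 - BN_MOMENTUM) * bnj$run_mean + BN_MOMENTUM * upd[[j]]$mu
      bnj$run_var <- (1 - BN_MOMENTUM) * bnj$run_var + BN_MOMENTUM * upd[[j]]$va
      state$layers[[k]]$bn[[j]] <- bnj
    }
  }
  state
}

add_weight_decay <- function(grads, state, wd) {
  if (wd == 0) return(grads)
  for (k in seq_along(grads$layers)) {
    lp <- state$layers[[k]]
    for (j in seq_along(grads$layers[[k]]$W))
      grads$layers[[k]]$W[[j]] <- grads$layers[[k]]$W[[j]] + wd * lp$W[[j]]
    grads$layers[[k]]$Wg <- grads$layers[[k]]$Wg + wd * lp$Wg
    if (!is.null(grads$layers[[k]]$Wr))
      grads$layers[[k]]$Wr <- grads$layers[[k]]$Wr + wd * lp$Wr
  }
  if (!is.null(grads$readout))
    grads$readout$W <- grads$readout$W + wd * state$readout$W
  grads
}

check_graphs <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0L ||
      !all(vapply(graphs, inherits, logical(1), "brain_graph")))
    stopf("graphs must be a non-empty list of brain_graph objects")
  ns <- vapply(graphs, `[[`, integer(1), "n_nodes")
  if (length(unique(ns)) != 1L)
    stopf("all graphs must share the same node count; found %s",
          paste(unique(ns), collapse = ", "))
  ns[1L]
}

graph_labels <- function(graphs, labels) {
  if (is.null(labels)) labels <- vapply(graphs, `[[`, integer(1), "label")
  labels <- as.integer(labels)
  if (length(labels) != length(graphs))
    stopf("labels length (%d) does not match number of graphs (%d)",
          length(labels), length(graphs))
  if (!is_binary_label(labels))
    stopf("labels must be 0 (control) / 1 (case) with no missing values")
  labels
}

#' Fit the edge-weighted GIN classifier
#'
#' Trains the GIN on a set of labelled brain graphs by minimizing the mean
#' cross-entropy with Adam for a fixed number of epochs. Minibatches are
#' assembled as block-diagonal sparse graphs so the whole batch is one set of
#' matrix operations. The full run — initialization, shuffling, dropout — is
#' determined by `control$seed`.
#'
#' @param graphs list of [build_graph()] results sharing a node count.
#' @param labels optional integer 0/1 vector; defaults to the graphs' own
#'   labels. Both classes must be present.
#' @param config a [gin_config()]; defaults to the standard architecture
#'   sized to the graphs' node count.
#' @param control a [train_control()].
#' @param verbose print per-epoch loss?
#' @return An object of class `gin_fit` with elements `state` (trained
#'   `gin_state`), `config`, `control`, `loss_trace` (per-epoch mean training
#'   cross-entropy) and `n_train`; see [predict.gin_fit()].
#' @examples
#' cohort <- simulate_fc_cohort(sim_config(n_per_group = 10, n_rois = 20,
#'                                         n_timepoints = 60, planted_rois = 1:5,
#'                                         n_blocks = 4, delta = 0.4))
#' graphs <- mapply(build_graph, cohort$fc, cohort$labels, SIMPLIFY = FALSE)
#' fit <- gin_fit(graphs, config = gin_config(20, hidden_dim = 8),
#'                control = train_control(n_epochs = 3, n_folds = 2))
#' predict(fit, graphs[1:2])
#' @export
gin_fit <- function(graphs, labels = NULL, config = NULL,
                    control = train_control(), verbose = FALSE) {
  n_nodes <- check_graphs(graphs)
  labels <- graph_labels(graphs, labels)
  if (length(unique(labels)) < 2L)
    stopf("training set must contain both classes")
  if (is.null(config)) config <- gin_config(input_dim = n_nodes)
  stopifnot(inherits(config, "gin_config"), inherits(control, "train_control"))
  if (config$input_dim != n_nodes)
    stopf("config$input_dim (%d) must equal the graph node count (%d)",
          config$input_dim, n_nodes)
  trips <- lapply(graphs, graph_triplets)
  n <- length(graphs)

  with_seed(control$seed, {
    state <- init_gin_state(config)
    opt <- list(m = NULL, v = NULL, t = 0L)
    loss_trace <- numeric(control$n_epochs)
    # minibatches are composed once per fit from a seeded shuffle and then
    # revisited every epoch; batch assembly (block-diagonal sparse
    # adjacency) is the costly step, so it is not repeated per epoch
    ord <- sample.int(n)
    starts <- seq(1L, n, by = control$batch_size)
    batch_idx <- lapply(starts, function(s)
      ord[s:min(s + control$batch_size - 1L, n)])
    batches <- lapply(batch_idx, function(idx)
      make_batch(trips[idx], config$input_dim))
    for (epoch in seq_len(control$n_epochs)) {
      ep_loss <- 0
      for (bi in seq_along(batches)) {
        idx <- batch_idx[[bi]]
        batch <- batches[[bi]]
        fw <- forward_batch(state, batch, training = TRUE, keep_cache = TRUE)
        sc <- softmax_ce(fw$logits, labels[idx])
        if (!is.finite(sc$loss))
          stopf("non-finite training loss at epoch %d (lr %g): aborting",
                epoch, control$learning_rate)
        ep_loss <- ep_loss + sc$loss * length(idx)
        state <- apply_bn_updates(state, fw$bn_updates)
        grads <- backward_batch(state, batch, fw, sc$dlogits)
        grads <- add_weight_decay(grads, state, control$weight_decay)
        opt$t <- opt$t + 1L
        res <- adam_recurse(list(layers = state$layers, readout = state$readout),
                            list(layers = grads$layers, readout = grads$readout),
                            opt$m, opt$v, control$learning_rate, opt$t)
        state$layers <- res$p$layers
        state$readout <- res$p$readout
        opt$m <- res$m
        opt$v <- res$v
      }
      loss_trace[epoch] <- ep_loss / n
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f", epoch, loss_trace[epoch]))
    }
    structure(
      list(state = state, config = config, control = control,
           loss_trace = loss_trace, n_train = n,
           class_counts = table(factor(labels, levels = c(0L, 1L))),
           call = match.call()),
      class = "gin_fit"
    )
  })
}

predict_logits <- function(state, graphs, chunk_size = 64L) {
  cfg <- state$config
  trips <- lapply(graphs, graph_triplets)
  out <- matrix(NA_real_, length(graphs), cfg$n_classes)
  starts <- seq(1L, length(graphs), by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, length(graphs))
    batch <- make_batch(trips[idx], cfg$input_dim)
    out[idx, ] <- forward_batch(state, batch, training = FALSE)$logits
  }
  colnames(out) <- c("control", "case")[seq_len(min(2L, cfg$n_classes))]
  out
}

#' Predict from a fitted GIN
#'
#' Inference-mode predictions (running batch-norm statistics, no dropout).
#' Class ties are broken toward the control class (0).
#'
#' @param object a [gin_fit()] result.
#' @param graphs list of brain graphs to score.
#' @param type `"class"` (0/1 labels), `"prob"` (softmax probabilities) or
#'   `"logits"` (raw class scores).
#' @param ... unused.
#' @return Integer vector or numeric matrix according to `type`.
#' @export
predict.gin_fit <- function(object, graphs,
                            type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  check_graphs(graphs)
  logits <- predict_logits(object$state, graphs)
  switch(type,
         logits = logits,
         prob = {
           E <- exp(logits - apply(logits, 1, max))
           E / rowSums(E)
         },
         class = as.integer(logits[, 2L] > logits[, 1L]))
}

#' @exportS3Method base::print
print.gin_fit <- function(x, ...) {
  cat("Edge-weighted GIN classifier\n")
  print(x$config)
  cat(sprintf("Trained on %d graphs (%s control / %s case), %d epochs; final loss %.4f\n",
              x$n_train, x$class_counts[1L], x$class_counts[2L],
              x$control$n_epochs, x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @exportS3Method base::summary
summary.gin_fit <- function(object, ...) {
  eps <- vapply(object$state$layers, `[[`, numeric(1), "eps")
  out <- list(config = object$config, control = object$control,
              n_train = object$n_train, class_counts = object$class_counts,
              epsilon = eps, n_params = n_params(object$state),
              final_loss = object$loss_trace[length(object$loss_trace)])
  class(out) <- "summary.gin_fit"
  out
}

#' @exportS3Method base::print
print.summary.gin_fit <- function(x, ...) {
  print(x$config)
  cat(sprintf("%d trainable parameters; %d training graphs (%s/%s)\n",
              x$n_params, x$n_train, x$class_counts[1L], x$class_counts[2L]))
  cat("Per-layer epsilon:", paste(format(x$epsilon, digits = 4), collapse = ", "), "\n")
  cat(sprintf("Final training cross-entropy: %.4f\n", x$final_loss))
  invisible(x)
}

#' Per-layer epsilon coefficients of a fitted GIN
#'
#' The `(1 + epsilon)` self-weighting scalars are the only interpretable
#' scalar coefficients of the model; they are fixed at zero for GIN-0 and
#' learned per layer otherwise.
#'
#' @param object a [gin_fit()] result.
#' @param ... unused.
#' @return Named numeric vector of per-layer epsilon values.
#' @export
coef.gin_fit <- function(object, ...) {
  eps <- vapply(object$state$layers, `[[`, numeric(1), "eps")
  names(eps) <- paste0("epsilon_layer", seq_along(eps))
  eps
}

#' Training loss curve
#'
#' @param x a [gin_fit()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gin_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "mean training cross-entropy",
                 main = "GIN training loss", ...)
  invisible(x)
}
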