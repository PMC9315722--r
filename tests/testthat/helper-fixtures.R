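# Shared fixtures: all synthetic, built in code at test time.

# A small labelled cohort of thresholded graphs with a planted subnetwork.
tiny_graph_cohort <- function(n_per_group = 8, n_rois = 16, n_timepoints = 80,
                              delta = 0.5, planted = 1:5, n_blocks = 4,
                              seed = 7, density = 25) {
  cfg <- sim_config(n_per_group = n_per_group, n_rois = n_rois,
                    n_timepoints = n_timepoints, delta = delta,
                    planted_rois = planted, n_blocks = n_blocks, seed = seed)
  co <- simulate_fc_cohort(cfg)
  list(graphs = mapply(build_graph, co$fc, co$labels,
                       MoreArgs = list(density = density), SIMPLIFY = FALSE),
       labels = co$labels, cfg = cfg)
}

# A random sparse weighted graph on n nodes (uses the current RNG stream).
rand_graph <- function(n, id = "g", nonneg = FALSE) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- sort(sample(nrow(pairs), size = min(nrow(pairs), max(2L, stats::rpois(1, n)))))
  w <- stats::rnorm(length(keep))
  if (nonneg) w <- abs(w)
  braingin:::new_brain_graph(id, sample(0:1, 1), n,
                             edges = pairs[keep, , drop = FALSE], weights = w)
}

# A GIN state whose MLPs are identity maps (square weights = I, biases 0,
# batch-norm off), so a layer reduces to relu((1 + eps) h + sum w h).
identity_state <- function(n, n_layers = 1L, seed = 1L) {
  cfg <- gin_config(input_dim = n, n_layers = n_layers, hidden_dim = n,
                    batch_norm = FALSE, dropout = 0)
  st <- init_gin_state(cfg, seed = seed)
  for (k in seq_len(n_layers)) {
    for (j in seq_along(st$layers[[k]]$W)) {
      st$layers[[k]]$W[[j]] <- diag(n)
      st$layers[[k]]$b[[j]] <- numeric(n)
    }
  }
  st
}

# A random state jittered away from the zero-bias initialization (so no
# ReLU sits exactly at its kink) with randomized batch-norm running
# statistics, exercising the full inference path.
jittered_state <- function(config, seed = 1L) {
  st <- init_gin_state(config, seed = seed)
  with_seed_local(seed + 500L, {
    jit <- function(x) x + stats::rnorm(length(x), sd = 0.05)
    for (k in seq_along(st$layers)) {
      lp <- st$layers[[k]]
      lp$W <- lapply(lp$W, jit)
      lp$b <- lapply(lp$b, jit)
      lp$Wg <- jit(lp$Wg); lp$bg <- jit(lp$bg)
      if (!is.null(lp$Wr)) { lp$Wr <- jit(lp$Wr); lp$br <- jit(lp$br) }
      if (!is.null(lp$bn)) {
        for (j in seq_along(lp$bn)) {
          lp$bn[[j]]$gamma <- jit(lp$bn[[j]]$gamma)
          lp$bn[[j]]$beta <- jit(lp$bn[[j]]$beta)
          lp$bn[[j]]$run_mean <- stats::rnorm(length(lp$bn[[j]]$run_mean), sd = 0.2)
          lp$bn[[j]]$run_var <- stats::runif(length(lp$bn[[j]]$run_var), 0.5, 1.5)
        }
      }
      st$layers[[k]] <- lp
    }
    if (!is.null(st$readout)) {
      st$readout$W <- jit(st$readout$W)
      st$readout$b <- jit(st$readout$b)
    }
  })
  st
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent dense-matrix reference for one GIN layer: builds the dense
# weighted adjacency with an explicit edge loop, forms
# (1 + eps) * H + A %*% H, and applies the MLP with plain matrix algebra
# and inference-mode batch-norm.
dense_layer_oracle <- function(h_prev, graph, state, k) {
  cfg <- state$config
  lp <- state$layers[[k]]
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges[e, 1L]; j <- graph$edges[e, 2L]
    A[i, j] <- A[i, j] + graph$weights[e]
    A[j, i] <- A[j, i] + graph$weights[e]
  }
  X <- (1 + lp$eps) * h_prev + A %*% h_prev
  m <- cfg$mlp_depth
  for (j in seq_len(m)) {
    U <- X %*% t(lp$W[[j]])
    U <- sweep(U, 2, lp$b[[j]], `+`)
    if (j < m && !is.null(lp$bn)) {
      bnj <- lp$bn[[j]]
      Uhat <- sweep(sweep(U, 2, bnj$run_mean, `-`), 2,
                    sqrt(bnj$run_var + 1e-5), `/`)
      U <- sweep(sweep(Uhat, 2, bnj$gamma, `*`), 2, bnj$beta, `+`)
    }
    X <- pmax(U, 0)
  }
  X
}

# Trainable parameters only (running batch-norm statistics change during
# training even at zero learning rate).
trainable_params <- function(state) {
  lapply(state$layers, function(lp) {
    list(W = lp$W, b = lp$b, eps = lp$eps, Wg = lp$Wg, bg = lp$bg,
         Wr = lp$Wr, br = lp$br,
         bn = if (!is.null(lp$bn))
           lapply(lp$bn, function(x) x[c("gamma", "beta")]))
  })
}
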