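test_that("the GIN layer reproduces hand-expanded aggregates under an identity MLP", {
  # 2-node graph, edge weight w, eps = 0: aggregate of one-hot features is
  # [[1, w], [w, 1]]
  w <- 0.7
  g2 <- braingin:::new_brain_graph("g", 0L, 2L, matrix(c(1L, 2L), 1), w)
  st <- identity_state(2)
  out <- gin_layer_forward(diag(2), g2, st, k = 1)
  expect_equal(out, matrix(c(1, w, w, 1), 2), tolerance = 1e-12)

  # all edge weights zero: empty aggregation, output equals input
  gz <- braingin:::new_brain_graph("z", 0L, 3L,
                                   matrix(c(1L, 2L, 2L, 3L), 2, byrow = TRUE),
                                   c(0, 0))
  st3 <- identity_state(3)
  expect_equal(gin_layer_forward(diag(3), gz, st3, k = 1), diag(3))

  # isolated node: reduces to its (1 + eps) self term, no error
  gi <- braingin:::new_brain_graph("i", 0L, 3L, matrix(c(1L, 2L), 1), 0.4)
  out_i <- gin_layer_forward(diag(3), gi, st3, k = 1)
  expect_equal(out_i[3, ], c(0, 0, 1))
})

test_that("the GIN layer matches a brute-force message-passing loop", {
  set.seed(21)
  for (rep in 1:5) {
    g <- rand_graph(5, nonneg = TRUE)
    st <- identity_state(5)
    h <- matrix(abs(rnorm(25)), 5)
    out <- gin_layer_forward(h, g, st, k = 1)
    agg <- h   # eps = 0: (1 + 0) * h
    for (e in seq_len(nrow(g$edges))) {
      i <- g$edges[e, 1]; j <- g$edges[e, 2]
      agg[i, ] <- agg[i, ] + g$weights[e] * h[j, ]
      agg[j, ] <- agg[j, ] + g$weights[e] * h[i, ]
    }
    expect_lt(max(abs(out - pmax(agg, 0))), 1e-6)
  }
})

test_that("attention pooling is an exact per-dimension softmax over nodes", {
  cfg <- gin_config(input_dim = 6, n_layers = 2, hidden_dim = 3)
  st <- jittered_state(cfg, seed = 5)

  # single node: softmax over one element is 1, pooling is the identity
  x1 <- matrix(rnorm(3), 1)
  p1 <- attention_pool(x1, st, k = 1)
  expect_equal(p1$embedding, as.vector(x1))
  expect_equal(as.vector(p1$gates), rep(1, 3))

  # identical gate scores for all nodes: uniform softmax = column mean
  stu <- st
  stu$layers[[1]]$Wg <- matrix(0, 3, 3)
  x <- matrix(rnorm(12), 4)
  pu <- attention_pool(x, stu, k = 1)
  expect_equal(pu$embedding, colMeans(x), tolerance = 1e-12)

  # brute-force recomputation on a random embedding
  x <- matrix(rnorm(12), 4)
  p <- attention_pool(x, st, k = 2)
  lp <- st$layers[[2]]
  scores <- x %*% t(lp$Wg) + matrix(lp$bg, 4, 3, byrow = TRUE)
  gates <- apply(scores, 2, function(s) exp(s) / sum(exp(s)))
  expect_lt(max(abs(p$gates - gates)), 1e-6)
  expect_lt(max(abs(p$embedding - colSums(gates * x))), 1e-6)
  expect_lt(max(abs(colSums(p$gates) - 1)), 1e-6)

  expect_error(attention_pool(x[0, , drop = FALSE], st, 1), "empty")
})

test_that("the readout sums per-layer linear scores", {
  cfg <- gin_config(input_dim = 4, n_layers = 2, hidden_dim = 3)
  st <- jittered_state(cfg, seed = 9)
  gs <- list(rnorm(3), rnorm(3))

  # zero maps: logits reduce to the bias sum
  st0 <- st
  for (k in 1:2) st0$layers[[k]]$Wr <- matrix(0, 2, 3)
  expect_equal(readout_predict(gs, st0),
               st0$layers[[1]]$br + st0$layers[[2]]$br)

  # hand-computed two-layer sum
  expected <- as.vector(st$layers[[1]]$Wr %*% gs[[1]]) + st$layers[[1]]$br +
    as.vector(st$layers[[2]]$Wr %*% gs[[2]]) + st$layers[[2]]$br
  expect_equal(readout_predict(gs, st), expected, tolerance = 1e-12)

  # L = 1 degenerates to a single linear classifier
  cfg1 <- gin_config(input_dim = 4, n_layers = 1, hidden_dim = 3)
  st1 <- jittered_state(cfg1, seed = 2)
  g1 <- list(rnorm(3))
  expect_equal(readout_predict(g1, st1),
               as.vector(st1$layers[[1]]$Wr %*% g1[[1]]) + st1$layers[[1]]$br)

  expect_error(readout_predict(gs[1], st), "list of 2")
})

test_that("the full forward pass is deterministic and sensitive to structure", {
  set.seed(31)
  cfg <- gin_config(input_dim = 8, n_layers = 3, hidden_dim = 6)
  st <- jittered_state(cfg, seed = 3)
  g <- rand_graph(8)
  f1 <- gin_forward(g, st)
  f2 <- gin_forward(g, st)
  expect_identical(f1$logits, f2$logits)
  expect_identical(f1$gates, f2$gates)

  # every gate column sums to one over nodes
  for (k in 1:3)
    expect_lt(max(abs(colSums(f1$gates[[k]]) - 1)), 1e-6)

  # zero-edge vs complete graph with equal weights: different logits
  g_empty <- braingin:::new_brain_graph("e", 0L, 8L,
                                        matrix(integer(0), 0, 2), numeric(0))
  pairs <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  g_full <- braingin:::new_brain_graph("f", 0L, 8L, pairs, rep(0.5, nrow(pairs)))
  expect_gt(max(abs(gin_forward(g_empty, st)$logits -
                    gin_forward(g_full, st)$logits)), 1e-6)
})

test_that("graph-level logits are invariant under node relabeling", {
  set.seed(41)
  cfg <- gin_config(input_dim = 10, n_layers = 2, hidden_dim = 5)
  st <- jittered_state(cfg, seed = 7)
  g <- rand_graph(10)
  base <- gin_forward(g, st)$logits
  for (rep in 1:5) {
    perm <- sample(10)
    gp <- permute_graph(g, perm)
    expect_lt(max(abs(gin_forward(gp, st)$logits - base)), 1e-5)
  }
})

test_that("GIN-0 and a learnable epsilon frozen at zero coincide", {
  cfg0 <- gin_config(input_dim = 6, n_layers = 2, hidden_dim = 4,
                     epsilon_mode = "fixed_zero")
  cfgl <- gin_config(input_dim = 6, n_layers = 2, hidden_dim = 4,
                     epsilon_mode = "learnable", epsilon_init = 0)
  st0 <- init_gin_state(cfg0, seed = 13)
  stl <- init_gin_state(cfgl, seed = 13)
  set.seed(55)
  g <- rand_graph(6)
  expect_equal(gin_forward(g, st0)$logits, gin_forward(g, stl)$logits,
               tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-exactly", {
  set.seed(61)
  cohort <- tiny_graph_cohort(n_per_group = 5, n_rois = 10, planted = 1:3,
                              n_timepoints = 40)
  fit <- gin_fit(cohort$graphs, config = gin_config(10, n_layers = 2, hidden_dim = 4),
                 control = train_control(n_epochs = 2, batch_size = 4, n_folds = 2))
  before <- predict(fit, cohort$graphs, type = "logits")
  path <- withr::local_tempfile(fileext = ".rds")
  write_gin_model(fit, path)
  restored <- read_gin_model(path)
  expect_identical(predict(restored, cohort$graphs, type = "logits"), before)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(read_gin_model(bad), "schema")
})

test_that("the scalar-gate and concatenation variants run and stay normalized", {
  set.seed(71)
  g <- rand_graph(7)
  cfg_s <- gin_config(input_dim = 7, n_layers = 2, hidden_dim = 4,
                      gate_mode = "scalar")
  st_s <- jittered_state(cfg_s, seed = 1)
  f <- gin_forward(g, st_s)
  for (k in 1:2) {
    expect_identical(ncol(f$gates[[k]]), 1L)
    expect_lt(abs(sum(f$gates[[k]]) - 1), 1e-6)
  }
  cfg_c <- gin_config(input_dim = 7, n_layers = 2, hidden_dim = 4,
                      readout = "concat")
  st_c <- jittered_state(cfg_c, seed = 2)
  expect_length(gin_forward(g, st_c)$logits, 2L)
})
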