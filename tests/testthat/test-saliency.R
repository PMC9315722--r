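make_records <- function(weight_fun, K = 10, L = 2, N = 20) {
  lapply(seq_len(K), function(f)
    lapply(seq_len(L), function(k)
      list(case = weight_fun(f, k, "case"),
           control = weight_fun(f, k, "control"))))
}

test_that("node weights reduce gates by a two-stage mean", {
  # uniform gates: every node scores 1/N
  u <- matrix(1 / 5, 5, 3)
  expect_equal(node_weight_from_gates(list(u, u)), rep(1 / 5, 5))

  # single subject, one dimension: scores equal the gate column
  g1 <- matrix(c(0.1, 0.2, 0.7), 3, 1)
  expect_equal(node_weight_from_gates(g1), c(0.1, 0.2, 0.7))

  # three subjects, hand-computed two-stage mean on 4 nodes x 2 dims
  set.seed(8)
  gs <- lapply(1:3, function(i) matrix(runif(8), 4, 2))
  manual <- rowMeans(sapply(gs, function(g) (g[, 1] + g[, 2]) / 2))
  expect_equal(node_weight_from_gates(gs), manual, tolerance = 1e-12)

  expect_error(node_weight_from_gates(list()), "empty")
})

test_that("top-q selection is rank-correct and breaks ties by ROI id", {
  w <- c(5, 4, 3, 2, 1)
  expect_identical(top_q_rois(w, 5), 1:5)
  expect_identical(top_q_rois(w, 2), 1:2)

  # tie spanning the q-th rank: smallest qualifying ids, size exactly q
  wt <- c(0.9, 0.5, 0.5, 0.5, 0.1)
  sel <- top_q_rois(wt, 2)
  expect_identical(sel, c(1L, 2L))
  sel3 <- top_q_rois(wt, 3)
  expect_identical(sel3, c(1L, 2L, 3L))
  expect_error(top_q_rois(w, 6), "q must be")
})

test_that("consolidation requires strictly more than half of the folds", {
  # ROI 1: top-q in folds 1..5 only (exactly half); ROI 2: all 10 folds
  wf <- function(f, k, g) {
    w <- seq(0.5, 0.01, length.out = 20)   # ROIs 3.. fill the remaining slots
    w[2] <- 2
    w[1] <- if (f <= 5) 3 else 0
    w
  }
  sal <- salient_rois(make_records(wf), q = 5, min_folds = 5)
  expect_false(1 %in% sal$roi_id)
  expect_true(all(2 %in% sal$roi_id[sal$group == "case"]))
  expect_identical(unique(sal$count[sal$roi_id == 2]), 10L)
  counts <- attr(sal, "selection_counts")
  expect_identical(unname(counts[1, "case", 1]), 5L)
  expect_true(all(counts <= 10L))
})

test_that("random fold weights give binomial-null inclusion rates", {
  set.seed(123)
  N <- 2000; q <- 500; K <- 10
  recs <- make_records(function(f, k, g) runif(N), K = K, L = 1, N = N)
  sal <- salient_rois(recs, q = q, min_folds = 5)
  counts <- attr(sal, "selection_counts")[1, "case", ]
  observed <- mean(counts > 5)
  p0 <- pbinom(5, K, q / N, lower.tail = FALSE)   # exact binomial oracle
  expect_lt(abs(observed - p0), 0.015)
})

test_that("incomplete records are rejected with the offending folds listed", {
  recs2 <- make_records(function(f, k, g) runif(10), K = 4, L = 2, N = 10)
  recs2[[2]] <- list(NULL, NULL)
  expect_error(salient_rois(recs2, q = 3), "fold 2")
  recs3 <- make_records(function(f, k, g) runif(10), K = 4, L = 2, N = 10)
  recs3[[4]][[1]]$case <- NULL
  expect_error(salient_rois(recs3, q = 3), "case")
})

test_that("network proportions partition each salient set", {
  parc <- toy_parcellation(21, n_networks = 7)   # three ROIs per network
  wf <- function(f, k, g) {
    w <- numeric(21)
    w[if (g == "case") c(1, 2, 4, 7) else c(10, 11, 12, 13)] <- 1
    w
  }
  sal <- salient_rois(make_records(wf, K = 4, L = 1, N = 21), q = 4,
                      min_folds = 2)
  props <- network_proportions(sal, parc)
  case_p <- props[props$group == "case", ]
  expect_equal(sum(case_p$fraction), 1, tolerance = 1e-9)
  # case set {1,2,4,7}: networks visual x2, somatomotor, dorsal_attention
  expect_equal(case_p$fraction[case_p$network == "visual"], 0.5)
  expect_equal(case_p$fraction[case_p$network == "somatomotor"], 0.25)
  expect_equal(case_p$fraction[case_p$network == "dorsal_attention"], 0.25)
  ctrl_p <- props[props$group == "control", ]
  # control set {10,11,12,13}: 10-12 in one network, 13 in the next
  expect_setequal(ctrl_p$fraction[ctrl_p$fraction > 0], c(0.75, 0.25))

  empty <- salient_rois(make_records(function(f, k, g) runif(21),
                                     K = 4, L = 1, N = 21),
                        q = 2, min_folds = 4)
  expect_identical(nrow(empty), 0L)
  expect_error(network_proportions(empty, parc), "empty")

  bad <- sal
  bad$roi_id[1] <- 99L
  expect_error(network_proportions(bad, parc), "not in parcellation")
})
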