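rand_fc <- function(n, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * n, sd = 0.3), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  braingin:::new_fc_matrix(z, sprintf("fc%d", seed))
}

test_that("density thresholding retains round(M% of all candidate pairs)", {
  fc <- rand_fc(200, 1)
  g <- build_graph(fc, label = 1, density = 25)
  expect_identical(nrow(g$edges), 4975L)           # round(0.25 * 19900)
  expect_identical(length(g$weights), 4975L)
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
  expect_identical(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])), 0L)

  # full density on an all-nonzero matrix: the complete graph
  fc9 <- rand_fc(9, 2)
  g100 <- build_graph(fc9, density = 100)
  expect_identical(nrow(g100$edges), 36L)
})

test_that("the strongest connections survive, by brute-force comparison", {
  z <- matrix(0, 4, 4)
  vals <- c(0.9, 0.8, 0.1, 0.05, 0.04, 0.03)
  z[upper.tri(z)] <- vals
  z <- z + t(z)
  fc <- braingin:::new_fc_matrix(z, "toy")
  g <- build_graph(fc, density = 50)
  expect_identical(nrow(g$edges), 3L)
  expect_equal(sort(g$weights, decreasing = TRUE), c(0.9, 0.8, 0.1))
})

test_that("the three edge-weight conventions transform weights as specified", {
  fc <- rand_fc(20, 3)
  g_abs <- build_graph(fc, density = 25, case = "abs")
  g_sgn <- build_graph(fc, density = 25, case = "signed")
  # same ranking key (|z|) -> same edge set; weights differ only in sign
  expect_identical(g_abs$edges, g_sgn$edges)
  expect_equal(g_abs$weights, abs(g_sgn$weights))
  expect_true(all(g_abs$weights > 0))
  expect_true(any(g_sgn$weights < 0))

  g_pos <- build_graph(fc, density = 25, case = "positive_only")
  w_pos <- fc$z[g_pos$edges]
  expect_true(all(w_pos > 0))
  expect_equal(g_pos$weights, w_pos)
})

test_that("positive-only graphs fall back to all positive edges with a warning", {
  z <- matrix(-abs(rnorm(64, sd = 0.3)), 8, 8)
  z[1, 2] <- z[2, 1] <- 0.5
  z[3, 4] <- z[4, 3] <- 0.2
  diag(z) <- 0
  z <- (z + t(z)) / 2
  fc <- braingin:::new_fc_matrix(z, "mostly_negative")
  expect_warning(g <- build_graph(fc, density = 50, case = "positive_only"),
                 "positive connections")
  expect_identical(nrow(g$edges), 2L)
})

test_that("graph construction commutes with node relabeling", {
  for (seed in 1:5) {
    fc <- rand_fc(10, seed + 10)
    set.seed(seed)
    perm <- sample(10)
    zp <- fc$z[order(perm), order(perm)]   # permuted-ROI matrix
    g1 <- permute_graph(build_graph(fc, density = 40), perm)
    g2 <- build_graph(braingin:::new_fc_matrix(zp, "p"), density = 40)
    key1 <- sprintf("%d-%d", g1$edges[, 1], g1$edges[, 2])
    key2 <- sprintf("%d-%d", g2$edges[, 1], g2$edges[, 2])
    expect_identical(key1, key2)
    expect_equal(g1$weights, g2$weights)
  }
})

test_that("tie-breaking at the cutoff is deterministic", {
  z <- matrix(0, 4, 4)
  z[upper.tri(z)] <- c(0.5, 0.3, 0.3, 0.3, 0.3, 0.1)
  z <- z + t(z)
  fc <- braingin:::new_fc_matrix(z, "ties")
  g1 <- build_graph(fc, density = 50)  # keeps 3 of 6 candidates
  g2 <- build_graph(fc, density = 50)
  expect_identical(g1$edges, g2$edges)
  expect_identical(nrow(g1$edges), 3L)
  # among the tied 0.3 edges, the lexicographically smallest pairs win
  tied <- g1$edges[g1$weights == 0.3, , drop = FALSE]
  all_tied <- which(fc$z == 0.3 & upper.tri(fc$z), arr.ind = TRUE)
  all_tied <- all_tied[order(all_tied[, 1], all_tied[, 2]), , drop = FALSE]
  expect_equal(unname(tied), unname(all_tied[seq_len(nrow(tied)), , drop = FALSE]))
})

test_that("realized density is within one edge of the requested density", {
  for (seed in 1:4) {
    n <- sample(20:60, 1)
    fc <- rand_fc(n, seed + 40)
    dens <- runif(1, 5, 95)
    g <- build_graph(fc, density = dens)
    n_pairs <- n * (n - 1) / 2
    expect_lte(abs(nrow(g$edges) - dens / 100 * n_pairs), 1)
  }
})

test_that("invalid graph parameters are rejected", {
  fc <- rand_fc(6, 99)
  expect_error(build_graph(fc, density = 0), "density")
  expect_error(build_graph(fc, density = 101), "density")
  expect_error(build_graph(fc, label = 2), "label")
  expect_error(permute_graph(build_graph(fc), c(1, 1, 2, 3, 4, 5)), "permutation")
})
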