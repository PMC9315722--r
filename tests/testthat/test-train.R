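test_that("a zero learning rate leaves all trainable parameters at initialization", {
  cohort <- tiny_graph_cohort(n_per_group = 5, n_rois = 10, planted = 1:3,
                              n_timepoints = 40)
  cfg <- gin_config(10, n_layers = 2, hidden_dim = 4,
                    epsilon_mode = "learnable")
  f1 <- gin_fit(cohort$graphs, config = cfg,
                control = train_control(learning_rate = 0, n_epochs = 1,
                                        batch_size = 4, seed = 3))
  f2 <- gin_fit(cohort$graphs, config = cfg,
                control = train_control(learning_rate = 0, n_epochs = 4,
                                        batch_size = 4, seed = 3))
  expect_identical(trainable_params(f1$state), trainable_params(f2$state))
})

test_that("training separates a strongly planted cohort", {
  cohort <- tiny_graph_cohort(n_per_group = 12, n_rois = 20, delta = 0.5,
                              planted = 1:6, n_timepoints = 120, seed = 5)
  fit <- gin_fit(cohort$graphs,
                 config = gin_config(20, hidden_dim = 8),
                 control = train_control(n_epochs = 40, batch_size = 8,
                                         seed = 1))
  train_acc <- mean(predict(fit, cohort$graphs) == cohort$labels)
  expect_gte(train_acc, 0.95)

  # smoothed loss (disjoint 5-epoch means) is non-increasing on separable data
  sm <- colMeans(matrix(fit$loss_trace, nrow = 5))
  expect_true(all(diff(sm) <= 0.02))
  expect_lt(sm[length(sm)], sm[1])
  expect_true(all(is.finite(fit$loss_trace)))
})

test_that("fits are reproducible given the seed", {
  cohort <- tiny_graph_cohort(n_per_group = 5, n_rois = 10, planted = 1:3,
                              n_timepoints = 40)
  ctl <- train_control(n_epochs = 3, batch_size = 4, seed = 11)
  f1 <- gin_fit(cohort$graphs, control = ctl,
                config = gin_config(10, n_layers = 2, hidden_dim = 4))
  f2 <- gin_fit(cohort$graphs, control = ctl,
                config = gin_config(10, n_layers = 2, hidden_dim = 4))
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(predict(f1, cohort$graphs, type = "logits"),
                   predict(f2, cohort$graphs, type = "logits"))
})

test_that("fit objects expose the classic modelling interface", {
  cohort <- tiny_graph_cohort(n_per_group = 5, n_rois = 10, planted = 1:3,
                              n_timepoints = 40)
  fit <- gin_fit(cohort$graphs,
                 config = gin_config(10, n_layers = 2, hidden_dim = 4),
                 control = train_control(n_epochs = 2, batch_size = 4))
  expect_s3_class(fit, "gin_fit")
  expect_output(print(fit), "GIN")
  expect_output(print(summary(fit)), "epsilon")
  eps <- coef(fit)
  expect_named(eps, c("epsilon_layer1", "epsilon_layer2"))
  expect_identical(unname(eps), c(0, 0))    # GIN-0 default

  pr <- predict(fit, cohort$graphs, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 10), tolerance = 1e-12)
  cl <- predict(fit, cohort$graphs)
  expect_true(all(cl %in% c(0L, 1L)))

  # single-class training sets are rejected
  expect_error(gin_fit(cohort$graphs[cohort$labels == 0]), "both classes")
})

test_that("cross-validation aggregates fold metrics and keeps folds clean", {
  cohort <- tiny_graph_cohort(n_per_group = 9, n_rois = 12, planted = 1:4,
                              n_timepoints = 60)
  cv <- gin_cv(cohort$graphs,
               config = gin_config(12, n_layers = 2, hidden_dim = 4),
               control = train_control(n_epochs = 3, batch_size = 6,
                                       n_folds = 3, seed = 2))
  expect_identical(nrow(cv$metrics), 3L)
  # aggregation identity: reported mean equals the mean of per-fold values
  for (mn in c("acc", "pre", "rec", "spe", "f1")) {
    expect_equal(cv$summary$mean[cv$summary$metric == mn],
                 mean(cv$metrics[[mn]]), tolerance = 1e-10)
    expect_equal(cv$summary$sd[cv$summary$metric == mn],
                 sd(cv$metrics[[mn]]), tolerance = 1e-10)
  }
  # every subject predicted exactly once, in its own test fold
  expect_identical(sort(cv$predictions$subject), seq_along(cohort$labels))
  for (f in seq_along(cv$folds))
    expect_length(intersect(cv$folds[[f]]$train, cv$folds[[f]]$test), 0L)
  # gate records: one complete set per fold, layer and group
  expect_length(cv$gate_records, 3L)
  for (rec in cv$gate_records) {
    expect_length(rec, 2L)   # n_layers
    for (lay in rec) {
      expect_length(lay$case, 12L)
      expect_length(lay$control, 12L)
      expect_true(all(lay$case >= 0))
    }
  }
  expect_output(print(cv), "ACC")
  expect_output(print(summary(cv)), "Per-fold")
})

test_that("cross-validation never mutates the input graphs", {
  cohort <- tiny_graph_cohort(n_per_group = 4, n_rois = 10, planted = 1:3,
                              n_timepoints = 40)
  snapshot <- lapply(cohort$graphs, unclass)
  invisible(gin_cv(cohort$graphs,
                   config = gin_config(10, n_layers = 1, hidden_dim = 4),
                   control = train_control(n_epochs = 2, batch_size = 4,
                                           n_folds = 2, seed = 1)))
  expect_identical(lapply(cohort$graphs, unclass), snapshot)
})
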