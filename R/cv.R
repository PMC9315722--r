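#' Stratified k-fold split of binary labels
#'
#' Partitions subject indices into `n_folds` test folds such that every fold
#' preserves the global class ratio to within one subject. Within each class,
#' subjects are shuffled under `seed` and dealt round-robin to folds, so the
#' split is deterministic given `(labels, n_folds, seed)`.
#'
#' @param labels integer 0/1 vector.
#' @param n_folds number of folds; must not exceed the minority class count.
#' @param seed RNG seed.
#' @return List of `n_folds` elements, each `list(train = , test = )` of
#'   integer indices. Test folds partition `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (!is_binary_label(labels)) stopf("labels must be 0/1 with no missing values")
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) stopf("both classes must be present")
  if (n_folds < 2L) stopf("n_folds must be at least 2")
  if (n_folds > min(tab))
    stopf("n_folds (%d) exceeds the minority class count (%d)", n_folds, min(tab))
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  lapply(seq_len(n_folds), function(f)
    list(train = which(assignment != f), test = which(assignment == f)))
}

# Mean node-importance scores per (layer, group) from a trained model
# applied once, in inference mode, to the given subjects.
gate_records_for <- function(state, graphs, labels, chunk_size = 64L) {
  cfg <- state$config
  L <- cfg$n_layers
  N <- cfg$input_dim
  sums <- list(case = matrix(0, N, L), control = matrix(0, N, L))
  counts <- c(case = 0L, control = 0L)
  trips <- lapply(graphs, graph_triplets)
  starts <- seq(1L, length(graphs), by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, length(graphs))
    batch <- make_batch(trips[idx], cfg$input_dim)
    fw <- forward_batch(state, batch, training = FALSE, collect_gates = TRUE)
    grp <- ifelse(labels[idx] == 1L, "case", "control")
    for (k in seq_len(L)) {
      v <- colMeans(fw$gates[[k]])         # per-node scalar score (gates are d x M)
      dim(v) <- c(N, length(idx))          # nodes x subjects in this chunk
      for (g in c("case", "control")) {
        sel <- grp == g
        if (any(sel)) sums[[g]][, k] <- sums[[g]][, k] + rowSums(v[, sel, drop = FALSE])
      }
    }
    counts["case"] <- counts["case"] + sum(grp == "case")
    counts["control"] <- counts["control"] + sum(grp == "control")
  }
  lapply(seq_len(L), function(k)
    list(case = if (counts["case"] > 0) sums$case[, k] / counts["case"],
         control = if (counts["control"] > 0) sums$control[, k] / counts["control"]))
}

#' Cross-validated training and evaluation of the GIN classifier
#'
#' Runs stratified k-fold cross-validation: one model is trained per fold on
#' its training split (with a fold-specific RNG stream derived from
#' `control$seed`) and evaluated on the held-out split with the five metrics
#' of [classification_metrics()]. Each fold's final model is applied once, in
#' inference mode, to that fold's *training* subjects — separated by
#' diagnostic group — to record the per-layer node attention scores consumed
#' by [salient_rois()]. Graph construction happens before the split with
#' global constants only, so no learned state ever derives from test
#' subjects.
#'
#' @inheritParams gin_fit
#' @param keep_fits retain the per-fold fitted models in the result?
#' @param verbose print per-fold progress?
#' @return An object of class `gin_cv`: list with `metrics` (per-fold
#'   data.frame of the five metrics in percent), `summary` (mean and SD per
#'   metric over folds), `predictions` (per-subject truth/prediction/fold),
#'   `gate_records` (`[[fold]][[layer]]$case/$control` node-score vectors),
#'   `folds`, `fits` (if kept), `config`, `control`.
#' @export
gin_cv <- function(graphs, labels = NULL, config = NULL,
                   control = train_control(), keep_fits = TRUE,
                   verbose = FALSE) {
  n_nodes <- check_graphs(graphs)
  labels <- graph_labels(graphs, labels)
  if (is.null(config)) config <- gin_config(input_dim = n_nodes)
  folds <- stratified_folds(labels, control$n_folds, control$seed)
  K <- length(folds)

  metrics <- vector("list", K)
  fits <- if (keep_fits) vector("list", K)
  records <- vector("list", K)
  pred_df <- vector("list", K)
  for (f in seq_len(K)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    ctrl_f <- control
    ctrl_f$seed <- control$seed + 1000L * f   # disjoint per-fold RNG stream
    fit <- gin_fit(graphs[tr], labels[tr], config = config, control = ctrl_f)
    pred <- predict(fit, graphs[te], type = "class")
    m <- classification_metrics(confusion_counts(labels[te], pred))
    metrics[[f]] <- data.frame(fold = f, acc = m$acc, pre = m$pre,
                               rec = m$rec, spe = m$spe, f1 = m$f1)
    records[[f]] <- gate_records_for(fit$state, graphs[tr], labels[tr])
    pred_df[[f]] <- data.frame(subject = te, fold = f, truth = labels[te],
                               predicted = pred)
    if (keep_fits) fits[[f]] <- fit
    if (verbose)
      message(sprintf("fold %2d/%d  ACC %.1f%%", f, K, m$acc))
  }
  metrics <- do.call(rbind, metrics)
  summ <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(mn) mean(metrics[[mn]]), numeric(1)),
    sd = vapply(metric_names, function(mn) stats::sd(metrics[[mn]]), numeric(1)),
    row.names = NULL
  )
  structure(
    list(metrics = metrics, summary = summ,
         predictions = do.call(rbind, pred_df),
         gate_records = records, folds = folds,
         fits = fits, config = config, control = control,
         labels = labels, n_nodes = n_nodes, call = match.call()),
    class = "gin_cv"
  )
}

#' @exportS3Method base::print
print.gin_cv <- function(x, ...) {
  cat(sprintf("GIN cross-validation: %d folds, %d subjects (%d control / %d case)\n",
              length(x$folds), length(x$labels),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %6.2f%% +/- %.2f\n", toupper(s$metric[i]), s$mean[i], s$sd[i]))
  invisible(x)
}

#' @exportS3Method base::summary
summary.gin_cv <- function(object, ...) {
  out <- list(summary = object$summary, metrics = object$metrics,
              n_folds = length(object$folds),
              n_subjects = length(object$labels),
              config = object$config, control = object$control)
  class(out) <- "summary.gin_cv"
  out
}

#' @exportS3Method base::print
print.summary.gin_cv <- function(x, ...) {
  cat(sprintf("Cross-validated GIN performance (%d folds, %d subjects)\n",
              x$n_folds, x$n_subjects))
  s <- x$summary
  cat("\nMetric  mean +/- SD over folds\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s  %6.2f%% +/- %5.2f\n", toupper(s$metric[i]), s$mean[i], s$sd[i]))
  cat("\nPer-fold values (%):\n")
  print(round(x$metrics, 2), row.names = FALSE)
  invisible(x)
}

#' Per-fold metric plot
#'
#' Dot plot of the five metrics across folds, with fold means.
#'
#' @param x a [gin_cv()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gin_cv <- function(x, ...) {
  m <- x$metrics[, metric_names]
  graphics::plot(NA, xlim = c(0.5, 5.5), ylim = c(0, 100), xaxt = "n",
                 xlab = "", ylab = "percent", main = "Cross-validated metrics", ...)
  graphics::axis(1, at = 1:5, labels = toupper(metric_names))
  for (i in seq_along(metric_names)) {
    graphics::points(rep(i, nrow(m)), m[[i]], pch = 1, col = "grey40")
    graphics::points(i, mean(m[[i]]), pch = 19, cex = 1.3)
  }
  invisible(x)
}
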