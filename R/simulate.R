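#' Configuration of a synthetic two-group connectome cohort
#'
#' Defines the generative model for synthetic cohorts used to exercise the
#' whole pipeline without any imaging data. Control subjects' ROI time series
#' are drawn from a zero-mean multivariate normal whose correlation matrix
#' has a latent community structure: `n_blocks` contiguous blocks (mimicking
#' the seven functional networks) with within-block correlation `r0` and
#' zero correlation across blocks. Case subjects are identical except that
#' the pairwise correlations among the `planted_rois` are raised by `delta`,
#' planting a discriminative subnetwork of known membership.
#'
#' Both target correlation matrices must be positive definite; this is
#' checked at construction and a violation reports the offending eigenvalue.
#'
#' @param n_per_group subjects per group (cohort size is twice this).
#' @param n_rois number of ROIs `N`.
#' @param n_timepoints time-series length `T`.
#' @param delta added correlation among planted ROIs in the case group
#'   (dimensionless).
#' @param planted_rois integer ids of the planted subnetwork.
#' @param r0 baseline within-block correlation.
#' @param noise_sd marginal signal standard deviation (arbitrary units).
#' @param n_blocks number of latent communities (<= 7 so the toy
#'   parcellation can label them).
#' @param seed RNG seed for cohort generation.
#' @return An object of class `sim_config`; includes the exact target
#'   correlation matrices `sigma_control`, `sigma_case`.
#' @export
sim_config <- function(n_per_group = 150L, n_rois = 200L, n_timepoints = 200L,
                       delta = 0.25, planted_rois = 1:20, r0 = 0.2,
                       noise_sd = 1, n_blocks = 7L, seed = 1L) {
  stopifnot(n_per_group >= 1L, n_rois >= n_blocks, n_timepoints >= 3L,
            noise_sd > 0, n_blocks >= 1L, n_blocks <= 7L)
  planted_rois <- as.integer(planted_rois)
  if (length(planted_rois) && (min(planted_rois) < 1L || max(planted_rois) > n_rois))
    stopf("planted_rois must lie in 1..%d", n_rois)

  blocks <- block_assignment(n_rois, n_blocks)
  sigma0 <- outer(blocks, blocks, `==`) * r0
  diag(sigma0) <- 1
  sigma1 <- sigma0
  if (length(planted_rois) >= 2L) {
    p <- planted_rois
    sigma1[p, p] <- sigma1[p, p] + delta
    diag(sigma1)[p] <- 1
  }
  check_pd <- function(s, what) {
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stopf("target %s correlation matrix is not positive definite (min eigenvalue %.6g)",
            what, min(ev))
  }
  check_pd(sigma0, "control")
  check_pd(sigma1, "case")
  if (max(abs(sigma1[upper.tri(sigma1)])) >= 1)
    stopf("planted correlation r0 + delta = %.3g exceeds 1", r0 + delta)

  structure(
    list(n_per_group = as.integer(n_per_group), n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints), delta = delta,
         planted_rois = planted_rois, r0 = r0, noise_sd = noise_sd,
         n_blocks = as.integer(n_blocks), seed = as.integer(seed),
         blocks = blocks, sigma_control = sigma0, sigma_case = sigma1),
    class = "sim_config"
  )
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort config: %d + %d subjects, %d ROIs, T = %d,\n",
                     "  %d latent blocks (r0 = %g), planted subnetwork of %d ROIs (delta = %g), seed %d\n"),
              x$n_per_group, x$n_per_group, x$n_rois, x$n_timepoints,
              x$n_blocks, x$r0, length(x$planted_rois), x$delta, x$seed))
  invisible(x)
}

sample_subject_ts <- function(cfg, sigma_chol) {
  z <- matrix(stats::rnorm(cfg$n_timepoints * cfg$n_rois), cfg$n_timepoints)
  (z %*% sigma_chol) * cfg$noise_sd
}

#' Generate a synthetic cohort of ROI time series
#'
#' Draws `2 * n_per_group` subjects from the model in [sim_config()]:
#' controls first (label 0), then cases (label 1). Sampling is independent
#' across subjects and fully determined by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `timeseries` (list of `roi_timeseries`), `labels`
#'   (integer 0/1 vector) and `ground_truth` (target correlation matrices and
#'   the planted ROI set).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_group = 5, n_rois = 20,
#'                                      n_timepoints = 50, planted_rois = 1:4,
#'                                      n_blocks = 4))
#' table(cohort$labels)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ch0 <- chol(cfg$sigma_control)
  ch1 <- chol(cfg$sigma_case)
  with_seed(cfg$seed, {
    labels <- rep(c(0L, 1L), each = cfg$n_per_group)
    ts <- vector("list", 2L * cfg$n_per_group)
    for (s in seq_along(labels)) {
      x <- sample_subject_ts(cfg, if (labels[s] == 0L) ch0 else ch1)
      ts[[s]] <- roi_timeseries(x, roi_ids = seq_len(cfg$n_rois),
                                subject_id = sprintf("sub-%03d", s))
    }
    list(timeseries = ts, labels = labels,
         ground_truth = list(sigma_control = cfg$sigma_control,
                             sigma_case = cfg$sigma_case,
                             planted_rois = cfg$planted_rois,
                             delta = cfg$delta))
  })
}

#' Generate a synthetic cohort of Fisher-z FC matrices
#'
#' Shortcut that simulates each subject's time series internally and emits
#' the Fisher-z connectome directly (see [compute_fc()]), for tests and runs
#' that do not need the raw signals. Shares the ground-truth contract of
#' [simulate_cohort()].
#'
#' @inheritParams simulate_cohort
#' @return List with `fc` (list of `fc_matrix`), `labels`, `ground_truth`.
#' @export
simulate_fc_cohort <- function(cfg) {
  cohort <- simulate_cohort(cfg)
  list(fc = lapply(cohort$timeseries, compute_fc),
       labels = cohort$labels,
       ground_truth = cohort$ground_truth)
}
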