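#' ROI time-series container
#'
#' Wraps one subject's region-of-interest (ROI) mean time series: a numeric
#' matrix with timepoints in rows and ROIs in columns. Each column is the
#' average BOLD signal over the voxels of one parcel.
#'
#' @param values numeric matrix, `T` timepoints x `N` ROIs. At least 3
#'   timepoints are required (a Pearson correlation on fewer points is
#'   degenerate).
#' @param roi_ids optional character/integer vector of `N` ROI identifiers;
#'   defaults to column names of `values`, else `1:N`.
#' @param subject_id subject identifier string.
#' @return An object of class `roi_timeseries` with elements `values`,
#'   `roi_ids`, `subject_id`.
#' @export
roi_timeseries <- function(values, roi_ids = NULL, subject_id = "subject") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 3L)
    stopf("time series needs >= 3 timepoints, got %d", nrow(values))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("time series for subject '%s' contains missing or non-finite values",
          subject_id)
  if (is.null(roi_ids)) roi_ids <- colnames(values) %||% as.character(seq_len(ncol(values)))
  if (length(roi_ids) != ncol(values))
    stopf("roi_ids length (%d) does not match number of ROI columns (%d)",
          length(roi_ids), ncol(values))
  colnames(values) <- as.character(roi_ids)
  structure(
    list(values = values, roi_ids = as.character(roi_ids),
         subject_id = as.character(subject_id)),
    class = "roi_timeseries"
  )
}

#' @exportS3Method base::print
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series '%s': %d timepoints x %d ROIs\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

new_fc_matrix <- function(z, subject_id, roi_ids = NULL) {
  n <- nrow(z)
  if (is.null(roi_ids)) roi_ids <- rownames(z) %||% as.character(seq_len(n))
  dimnames(z) <- list(roi_ids, roi_ids)
  structure(
    list(subject_id = as.character(subject_id), z = z, n_rois = n,
         roi_ids = as.character(roi_ids)),
    class = "fc_matrix"
  )
}

#' Functional-connectivity matrix from ROI time series
#'
#' Computes the Pearson correlation between every pair of ROI time series and
#' applies the Fisher z (arctanh) variance-stabilizing transform, yielding the
#' subject's functional connectome. The diagonal (self-correlation) is never
#' transformed and is fixed at zero.
#'
#' Perfectly correlated pairs (`|r| = 1`) have an infinite Fisher z value.
#' With `clip = TRUE` (the default) correlations are clipped to
#' `+/- rmax` before the transform, which keeps simulated cohorts — where
#' exact collinearity can legitimately occur — finite. With `clip = FALSE`
#' such a pair is an error.
#'
#' @param ts an `roi_timeseries` object, or a plain `T x N` numeric matrix.
#' @param clip clip correlations into `[-rmax, rmax]` before arctanh?
#' @param rmax clipping bound, strictly inside (0, 1).
#' @return An object of class `fc_matrix`: list with `subject_id`, symmetric
#'   `z` matrix (zero diagonal), `n_rois`, `roi_ids`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(50 * 4), 50), subject_id = "s1")
#' fc <- compute_fc(ts)
#' fc$z[1, 2] == fc$z[2, 1]
#' @export
compute_fc <- function(ts, clip = TRUE, rmax = 1 - 1e-7) {
  if (!inherits(ts, "roi_timeseries")) ts <- roi_timeseries(ts)
  x <- ts$values
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- ts$roi_ids[which(v == 0)]
    stopf("ROI column(s) with zero variance: %s (subject '%s')",
          paste(bad, collapse = ", "), ts$subject_id)
  }
  r <- stats::cor(x)
  off <- row(r) != col(r)
  if (clip) {
    stopifnot(rmax > 0, rmax < 1)
    r[off] <- pmin(pmax(r[off], -rmax), rmax)
  } else if (any(abs(r[off]) >= 1)) {
    idx <- which(abs(r) >= 1 & off, arr.ind = TRUE)[1L, ]
    stopf(paste0("|r| = 1 between ROIs '%s' and '%s': Fisher z is infinite ",
                 "(enable clipping to proceed)"),
          ts$roi_ids[idx[1L]], ts$roi_ids[idx[2L]])
  }
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # cor() is symmetric; guard against rounding asymmetry
  new_fc_matrix(z, ts$subject_id, ts$roi_ids)
}

#' @exportS3Method base::print
print.fc_matrix <- function(x, ...) {
  cat(sprintf("Fisher-z FC matrix '%s': %d x %d ROIs\n",
              x$subject_id, x$n_rois, x$n_rois))
  invisible(x)
}

#' Group-average functional connectome
#'
#' Entrywise mean of a list of Fisher-z FC matrices, e.g. all subjects of one
#' diagnostic group. Symmetry and the zero diagonal are preserved.
#'
#' @param fcs non-empty list of `fc_matrix` objects sharing `n_rois`.
#' @param subject_id identifier for the averaged matrix.
#' @return An `fc_matrix`.
#' @export
group_average_fc <- function(fcs, subject_id = NULL) {
  if (length(fcs) == 0L) stopf("cannot average an empty list of FC matrices")
  if (!all(vapply(fcs, inherits, logical(1), "fc_matrix")))
    stopf("all elements must be fc_matrix objects")
  n <- fcs[[1L]]$n_rois
  sizes <- vapply(fcs, `[[`, integer(1), "n_rois")
  if (any(sizes != n))
    stopf("mismatched n_rois: %s", paste(unique(sizes), collapse = ", "))
  zbar <- Reduce(`+`, lapply(fcs, `[[`, "z")) / length(fcs)
  new_fc_matrix(zbar, subject_id %||% sprintf("group_average(n=%d)", length(fcs)),
                fcs[[1L]]$roi_ids)
}
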