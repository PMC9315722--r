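# Readers and writers for the delimited-text formats shared by the CLI and
# the analysis functions. ROI ids are 1-based in all files; matrices are
# headerless CSV; every reader returns an invariant-checked object.

#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.csv(as.data.frame(ts$values, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write ROI time series
#'
#' One CSV per subject: header row of ROI identifiers, one row per
#' timepoint.
#'
#' @param ts an `roi_timeseries` (writer).
#' @param path file path.
#' @param subject_id subject identifier to attach (reader); defaults to the
#'   file name.
#' @return The reader returns an `roi_timeseries`.
#' @export
read_timeseries <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric entries in time series file '%s'", path)
  roi_timeseries(m, roi_ids = colnames(df),
                 subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_fc_matrix
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  utils::write.table(fc$z, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write Fisher-z FC matrices
#'
#' Headerless `N x N` CSV. On read, the matrix must be finite and symmetric
#' to within `tol`; it is then exactly symmetrized and the diagonal forced
#' to zero.
#'
#' @param fc an `fc_matrix` (writer).
#' @param path file path.
#' @param subject_id subject identifier to attach (reader).
#' @param n_rois if given, the expected matrix dimension.
#' @param tol maximum tolerated asymmetry.
#' @return The reader returns an `fc_matrix`.
#' @export
read_fc_matrix <- function(path, subject_id = NULL, n_rois = NULL,
                           tol = 1e-8) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stopf("non-numeric entries in FC file '%s'", path)
  if (nrow(m) != ncol(m))
    stopf("FC matrix in '%s' is %d x %d, not square", path, nrow(m), ncol(m))
  if (!is.null(n_rois) && nrow(m) != n_rois)
    stopf("FC matrix in '%s' is %d x %d but %d ROIs expected",
          path, nrow(m), ncol(m), n_rois)
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stopf("non-finite FC entry at (%d, %d) in '%s'", idx[1L], idx[2L], path)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    stopf("FC matrix in '%s' is asymmetric (max |z - t(z)| = %.3g > %.1g)",
          path, asym, tol)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new_fc_matrix(m, subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_parcellation
#' @export
write_parcellation <- function(parc, path) {
  utils::write.csv(validate_parcellation(parc), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a parcellation lookup table
#'
#' CSV with columns `roi_id`, `roi_name`, `network`, `x`, `y`, `z`
#' (coordinates in mm, MNI convention). Network labels must come from the
#' closed seven-network set ([yeo7_networks]).
#'
#' @param parc parcellation data.frame (writer).
#' @param path file path.
#' @param n_rois if given, the expected number of rows.
#' @return The reader returns a validated data.frame ordered by `roi_id`.
#' @export
read_parcellation <- function(path, n_rois = NULL) {
  validate_parcellation(utils::read.csv(path, stringsAsFactors = FALSE), n_rois)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a subject manifest
#'
#' CSV with required columns `subject_id`, `file`, `label` (0/1) and
#' optional extra columns (e.g. `group`, `site`). Relative file paths are
#' resolved against the manifest's directory. Duplicate subject ids,
#' non-binary labels and missing files are errors that name the offending
#' row.
#'
#' @param manifest data.frame to write (writer).
#' @param path manifest path.
#' @param check_files verify that every referenced file exists?
#' @return data.frame with an added `path` column of resolved file paths.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "file", "label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("manifest '%s' is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stopf("manifest '%s' has no rows", path)
  lab <- suppressWarnings(as.integer(df$label))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad))
    stopf("manifest row %d: label '%s' is not 0 or 1", bad[1L], df$label[bad[1L]])
  df$label <- lab
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stopf("duplicated subject_id in manifest: %s", paste(unique(dup), collapse = ", "))
  base <- dirname(path)
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$file), df$file,
                     file.path(base, df$file))
  if (check_files) {
    miss <- which(!file.exists(resolved))
    if (length(miss))
      stopf("manifest row %d: file '%s' does not exist", miss[1L], df$file[miss[1L]])
  }
  df$path <- resolved
  df
}

#' @rdname read_graphs
#' @export
write_graphs <- function(graphs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    fname <- sprintf("%s_edges.csv", g$subject_id)
    utils::write.csv(data.frame(i = g$edges[, 1L], j = g$edges[, 2L],
                                weight = g$weights),
                     file.path(dir, fname), row.names = FALSE)
    rows[[i]] <- data.frame(subject_id = g$subject_id, file = fname,
                            label = g$label, n_nodes = g$n_nodes,
                            density = g$density, case = g$case)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "graphs_manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read / write thresholded brain graphs
#'
#' A graph directory holds one `<subject>_edges.csv` per subject (columns
#' `i`, `j`, `weight`, 1-based node ids, `i < j`) plus a
#' `graphs_manifest.csv` carrying `subject_id`, `file`, `label`, `n_nodes`,
#' `density`, `case`.
#'
#' @param graphs list of brain graphs (writer).
#' @param dir directory path.
#' @return The reader returns a list of `brain_graph` objects.
#' @export
read_graphs <- function(dir) {
  man_path <- file.path(dir, "graphs_manifest.csv")
  if (!file.exists(man_path)) stopf("no graphs_manifest.csv in '%s'", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    e <- utils::read.csv(file.path(dir, man$file[i]))
    n <- man$n_nodes[i]
    if (nrow(e) && (max(e$i, e$j) > n || min(e$i, e$j) < 1L))
      stopf("edge endpoints outside 1..%d in '%s'", n, man$file[i])
    new_brain_graph(man$subject_id[i], man$label[i], n,
                    edges = cbind(e$i, e$j), weights = e$weight,
                    density = man$density[i] %||% NA_real_,
                    case = man$case[i] %||% NA_character_)
  })
}

#' @rdname read_gin_model
#' @export
write_gin_model <- function(x, path) {
  if (!inherits(x, c("gin_fit", "gin_state")))
    stopf("x must be a gin_fit or gin_state object")
  saveRDS(list(schema_version = "braingin/1",
               kind = class(x)[1L], object = x), path)
  invisible(path)
}

#' Model checkpointing
#'
#' Serializes a fitted model (or bare parameter state) together with its
#' configuration and a schema version into a single checkpoint file, and
#' restores it bit-exactly: logits computed before and after a round trip
#' are identical.
#'
#' @param x a [gin_fit()] result or `gin_state` (writer).
#' @param path checkpoint path.
#' @return The reader returns the stored object.
#' @export
read_gin_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$schema_version, "braingin/1"))
    stopf("'%s' is not a braingin model checkpoint (schema braingin/1)", path)
  obj$object
}
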