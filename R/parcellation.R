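#' The seven canonical cortical functional networks
#'
#' Closed set of network labels used throughout the package: visual,
#' somatomotor, dorsal attention, ventral attention, limbic, frontoparietal
#' control and default mode.
#'
#' @format Character vector of length 7.
#' @export
yeo7_networks <- c("visual", "somatomotor", "dorsal_attention",
                   "ventral_attention", "limbic", "frontoparietal",
                   "default_mode")

validate_parcellation <- function(parc, n_rois = NULL) {
  required <- c("roi_id", "roi_name", "network", "x", "y", "z")
  missing <- setdiff(required, names(parc))
  if (length(missing))
    stopf("parcellation is missing column(s): %s", paste(missing, collapse = ", "))
  parc$roi_id <- as.integer(parc$roi_id)
  if (anyDuplicated(parc$roi_id))
    stopf("parcellation has duplicated roi_id values")
  if (!is.null(n_rois)) {
    if (nrow(parc) != n_rois)
      stopf("parcellation has %d rows but %d ROIs expected", nrow(parc), n_rois)
    if (!setequal(parc$roi_id, seq_len(n_rois)))
      stopf("parcellation roi_id must cover 1..%d", n_rois)
  }
  bad <- setdiff(unique(parc$network), yeo7_networks)
  if (length(bad))
    stopf("unknown network label(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(yeo7_networks, collapse = ", "))
  parc[order(parc$roi_id), , drop = FALSE]
}

#' Toy parcellation for simulated cohorts
#'
#' A deterministic lookup table assigning each of `n_rois` regions a name,
#' one of the seven canonical functional networks (in contiguous,
#' near-equal-sized blocks matching the latent community structure of
#' [simulate_cohort()]), and pseudo-MNI coordinates. It stands in for a real
#' cortical parcellation so that network-level saliency summaries can be
#' exercised on synthetic data; it is synthetic and carries no anatomical
#' meaning.
#'
#' @param n_rois number of regions.
#' @param n_networks number of networks (at most 7).
#' @return data.frame with columns `roi_id`, `roi_name`, `network`,
#'   `x`, `y`, `z`.
#' @export
toy_parcellation <- function(n_rois, n_networks = 7L) {
  stopifnot(n_rois >= n_networks, n_networks >= 1L, n_networks <= 7L)
  blocks <- block_assignment(n_rois, n_networks)
  # deterministic pseudo-MNI coordinates on a coarse helix through the head
  t <- seq_len(n_rois) / n_rois
  data.frame(
    roi_id = seq_len(n_rois),
    roi_name = sprintf("ROI_%03d", seq_len(n_rois)),
    network = yeo7_networks[blocks],
    x = round(60 * cos(11 * pi * t), 1),
    y = round(80 * sin(7 * pi * t) - 10, 1),
    z = round(50 * sin(5 * pi * t) + 10, 1),
    stringsAsFactors = FALSE
  )
}

# contiguous near-equal blocks: block index per ROI
block_assignment <- function(n_rois, n_blocks) {
  sizes <- rep(n_rois %/% n_blocks, n_blocks)
  extra <- n_rois %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_blocks), times = sizes)
}
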