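#' Compute imaging biomarkers from a segmentation
#'
#' Two biomarkers per analysis unit: the number of segmented objects
#' (cells) and their total fluorescence. For the GFP keratinocyte channel
#' the analysis unit is the whole construct; for the RFP tumor channel each
#' tumor ROI is a unit, with every object assigned to the ROI containing
#' its centroid and objects outside every ROI collected in an
#' `"unassigned"` bucket.
#'
#' @param seg a `segmentation_result` computed on the registered,
#'   normalized stack.
#' @param channel `"GFP_488"` or `"RFP_532"`.
#' @param timepoint `"pre"` or `"post"`.
#' @param sample_id sample identifier.
#' @param rois list of [tumor_roi()] (used for the RFP channel). Supplying
#'   ROIs for the GFP channel raises a warning and they are ignored.
#' @return A data.frame of class `biomarker_measurement` with columns
#'   `sample_id`, `timepoint`, `channel`, `roi_id`, `n_objects`,
#'   `total_fluorescence`.
#' @export
measure <- function(seg, channel, timepoint, sample_id = "sample",
                    rois = list()) {
  stopifnot(inherits(seg, "segmentation_result"))
  channel <- match.arg(channel, .channels)
  timepoint <- match.arg(timepoint, .timepoints)
  obj <- seg$objects
  row1 <- function(roi_id, idx) data.frame(
    sample_id = sample_id, timepoint = timepoint, channel = channel,
    roi_id = roi_id, n_objects = length(idx),
    total_fluorescence = if (length(idx)) sum(obj$total_fluorescence[idx]) else 0)
  if (channel == "GFP_488") {
    if (length(rois))
      warning("tumor ROIs supplied for the GFP channel are ignored; ",
              "keratinocyte biomarkers are whole-sample")
    out <- row1("WHOLE_SAMPLE", seq_len(nrow(obj)))
  } else {
    if (!rois_disjoint(rois)) stop("tumor ROIs must be pairwise disjoint")
    assigned <- rep(NA_character_, nrow(obj))
    if (nrow(obj)) {
      cen <- cbind(obj$centroid_z, obj$centroid_y, obj$centroid_x)
      for (r in rois) {
        inside <- which(is.na(assigned) &
                          apply(cen, 1, function(p) roi_contains(r, p)))
        assigned[inside] <- r$roi_id
      }
    }
    parts <- lapply(rois, function(r) row1(r$roi_id, which(assigned == r$roi_id)))
    parts[[length(parts) + 1]] <- row1("unassigned", which(is.na(assigned)))
    out <- do.call(rbind, parts)
  }
  class(out) <- c("biomarker_measurement", class(out))
  out
}

#' Treatment effect as post-treatment percent of pre-treatment value
#'
#' For a matched pair of biomarker measurements, computes
#' `percent_of_pre = 100 * post / pre` per metric (`n_objects` and
#' `total_fluorescence`). Units with a zero pre-treatment baseline are
#' excluded with an informative condition.
#'
#' @param pre,post single rows of a `biomarker_measurement` table with
#'   matching sample, channel and ROI.
#' @param metric `"n_objects"` or `"total_fluorescence"`.
#' @return A one-row data.frame with `sample_id`, `channel`, `roi_id`,
#'   `metric`, `pre_value`, `post_value`, `percent_of_pre`.
#' @export
treatment_effect <- function(pre, post,
                             metric = c("n_objects", "total_fluorescence")) {
  metric <- match.arg(metric)
  if (pre$sample_id != post$sample_id || pre$channel != post$channel ||
      pre$roi_id != post$roi_id)
    stop("pre and post measurements must match on sample, channel and ROI")
  if (pre$timepoint != "pre" || post$timepoint != "post")
    stop("arguments must be a pre and a post measurement, in that order")
  pv <- pre[[metric]]; qv <- post[[metric]]
  if (pv <= 0)
    stop("undefined baseline: pre-treatment ", metric, " is zero for ",
         pre$sample_id, "/", pre$roi_id,
         "; the unit must be excluded from treatment-effect analysis")
  data.frame(sample_id = pre$sample_id, channel = pre$channel,
             roi_id = pre$roi_id, metric = metric,
             pre_value = pv, post_value = qv,
             percent_of_pre = 100 * qv / pv)
}

#' Bleed-through quality-control check
#'
#' Flags a sample when too many of its GFP objects colocalize with RFP
#' objects: bleed-through of the tumor fluorophore into the keratinocyte
#' detection channel makes tumor cells appear in both segmentations at the
#' same positions. A GFP object colocalizes when its centroid lies within
#' one cell radius (physical distance) of an RFP object centroid. Flagged
#' samples are excluded from group statistics, mirroring the exclusion of
#' affected acquisition batches in practice.
#'
#' @param seg_gfp,seg_rfp `segmentation_result`s of the two channels,
#'   computed in the same (registered) frame.
#' @param voxel_size_um numeric `(z, y, x)` voxel size in micrometers.
#' @param cell_radius_um colocalization radius (default 5).
#' @param threshold flag when the colocalized fraction of GFP objects
#'   exceeds this value (default 0.5).
#' @return A list with `flagged` (logical), `fraction_colocalized`, and
#'   counts of objects in each channel.
#' @export
qc_bleedthrough <- function(seg_gfp, seg_rfp,
                            voxel_size_um = c(3.1, 1.1, 1.1),
                            cell_radius_um = 5, threshold = 0.5) {
  g <- seg_gfp$objects; r <- seg_rfp$objects
  if (nrow(g) == 0 || nrow(r) == 0) {
    return(list(flagged = FALSE, fraction_colocalized = 0,
                n_gfp = nrow(g), n_rfp = nrow(r)))
  }
  gz <- g$centroid_z * voxel_size_um[1]
  gy <- g$centroid_y * voxel_size_um[2]
  gx <- g$centroid_x * voxel_size_um[3]
  rz <- r$centroid_z * voxel_size_um[1]
  ry <- r$centroid_y * voxel_size_um[2]
  rx <- r$centroid_x * voxel_size_um[3]
  coloc <- vapply(seq_len(nrow(g)), function(i) {
    min((rz - gz[i])^2 + (ry - gy[i])^2 + (rx - gx[i])^2) <= cell_radius_um^2
  }, logical(1))
  frac <- mean(coloc)
  list(flagged = frac > threshold, fraction_colocalized = frac,
       n_gfp = nrow(g), n_rfp = nrow(r))
}
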