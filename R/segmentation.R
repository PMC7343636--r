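#' Segmentation parameters
#'
#' Defaults reproduce the published pipeline settings: Gaussian smoothing
#' with a kernel size of 8 voxels, removal of connected components of 4 or
#' fewer voxels, and 26-connectivity. "Kernel size" is interpreted as the
#' truncated window width in voxels; the Gaussian sigma defaults to a
#' quarter of the window (2.0 voxels). Both are independently settable.
#'
#' @param smoothing_kernel_size truncated window width in voxels
#'   (default 8; taps span `2 * floor(size / 2) + 1` voxels).
#' @param smoothing_sigma Gaussian sigma in voxels
#'   (default `smoothing_kernel_size / 4`).
#' @param min_object_voxels smallest object kept (default 5, i.e. objects
#'   of 4 or fewer voxels are removed).
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners
#'   connect voxels).
#' @param histogram_bins number of equal-width histogram bins for Otsu's
#'   method (default 256).
#' @param per_slice if `TRUE`, smooth each z-slice independently instead of
#'   in 3D (default `FALSE`; provided for strongly anisotropic stacks).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_kernel_size = 8,
                                smoothing_sigma = smoothing_kernel_size / 4,
                                min_object_voxels = 5,
                                connectivity = 26,
                                histogram_bins = 256,
                                per_slice = FALSE) {
  if (smoothing_kernel_size < 1) stop("kernel size must be >= 1")
  if (min_object_voxels < 1) stop("min_object_voxels must be >= 1")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (histogram_bins < 2) stop("histogram_bins must be >= 2")
  structure(list(smoothing_kernel_size = smoothing_kernel_size,
                 smoothing_sigma = smoothing_sigma,
                 min_object_voxels = min_object_voxels,
                 connectivity = as.integer(connectivity),
                 histogram_bins = as.integer(histogram_bins),
                 per_slice = per_slice),
            class = "segmentation_params")
}

gaussian_kernel_1d <- function(size, sigma) {
  r <- floor(size / 2)
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' 3D Gaussian smoothing
#'
#' Separable truncated-Gaussian convolution with mirror padding at the
#' borders. The kernel is normalized, so total intensity is conserved away
#' from borders and constant volumes are left unchanged.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param params a [segmentation_params()].
#' @return The smoothed stack, same type as the input.
#' @export
gaussian_smooth <- function(stack, params = segmentation_params()) {
  is_stack <- inherits(stack, "image_stack")
  vox <- if (is_stack) stack$voxels else stack
  d <- dim(vox)
  k <- gaussian_kernel_1d(params$smoothing_kernel_size, params$smoothing_sigma)
  axes <- if (params$per_slice) c(1L, 2L) else c(0L, 1L, 2L)
  out <- as.numeric(vox)
  for (ax in axes) out <- conv3d_axis(out, d, k, ax)
  out <- array(out, dim = d)
  if (is_stack) {
    stack$voxels <- out
    stack
  } else out
}

#' Otsu threshold
#'
#' Histogram thresholding over `histogram_bins` equal-width bins spanning
#' `[min, max]`: the cut maximizing the between-class variance is selected
#' and the upper edge of its bin is returned. Voxels strictly greater than
#' the threshold are foreground. On ties the lowest maximizing cut is used.
#'
#' @param stack an [image_stack()] or numeric array/vector with at least
#'   two distinct values.
#' @param params a [segmentation_params()] (only `histogram_bins` is used).
#' @return The threshold intensity (scalar).
#' @export
otsu_threshold <- function(stack, params = segmentation_params()) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("degenerate input: constant stack has no Otsu threshold")
  nb <- params$histogram_bins
  edges <- seq(lo, hi, length.out = nb + 1)
  # left-open bins (lo + (i-1)w, lo + i*w], so a value sitting exactly on
  # the selected bin's upper edge stays in class 0, consistent with the
  # strict "> threshold" foreground rule
  idx <- pmin(pmax(ceiling((v - lo) / (hi - lo) * nb), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  # per-bin means from the actual intensity sums (not bin midpoints), so
  # the histogram objective agrees with the exact between-class variance
  # whenever distinct values land in distinct bins
  bin_sums <- numeric(nb)
  agg <- rowsum(v, idx)
  bin_sums[as.integer(rownames(agg))] <- agg
  w <- counts / length(v)
  mu <- bin_sums / length(v)
  omega0 <- cumsum(w)            # class 0 = bins 1..k
  mu0 <- cumsum(mu)
  mu_t <- mu0[nb]
  omega1 <- 1 - omega0
  between <- (mu_t * omega0 - mu0)^2 / (omega0 * omega1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-nb])   # a cut must leave both classes non-empty
  edges[k + 1]
}

#' Label connected components of a binary volume
#'
#' Maximal connected voxel sets under 6-, 18- or 26-connectivity.
#' Components are labeled 1, 2, ... in the scan order of each component's
#' first voxel, making the labeling deterministic. Per-object voxel counts,
#' centroids (1-based (z, y, x)) and summed intensities are tabulated from
#' `intensity` (which should be the normalized, pre-smoothing stack, so
#' that quantification reflects measured signal).
#'
#' @param mask logical or 0/1 3D array.
#' @param connectivity 6, 18 or 26.
#' @param intensity optional numeric array of the same shape used for
#'   per-object summed fluorescence; defaults to the mask itself.
#' @return A list of class `segmentation_result`: `label_volume` (integer
#'   array, 0 = background) and `objects` (data.frame with `label`,
#'   `voxel_count`, `centroid_z/y/x`, `total_fluorescence`).
#' @export
label_components <- function(mask, connectivity = 26, intensity = NULL) {
  vox <- if (inherits(mask, "image_stack")) mask$voxels else mask
  d <- dim(vox)
  if (is.null(intensity)) intensity <- vox
  ivox <- if (inherits(intensity, "image_stack")) intensity$voxels else intensity
  labels <- label3d(as.logical(vox != 0), d, as.integer(connectivity))
  n_labels <- if (length(labels)) max(labels) else 0L
  objects <- empty_object_table()
  if (n_labels > 0) {
    st <- label_stats(labels, d, as.numeric(ivox), n_labels)
    objects <- data.frame(label = seq_len(n_labels),
                          voxel_count = as.integer(st[, 1]),
                          centroid_z = st[, 2] / st[, 1],
                          centroid_y = st[, 3] / st[, 1],
                          centroid_x = st[, 4] / st[, 1],
                          total_fluorescence = st[, 5])
  }
  structure(list(label_volume = array(labels, dim = d), objects = objects),
            class = "segmentation_result")
}

empty_object_table <- function() {
  data.frame(label = integer(0), voxel_count = integer(0),
             centroid_z = numeric(0), centroid_y = numeric(0),
             centroid_x = numeric(0), total_fluorescence = numeric(0))
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d object(s), %d foreground voxel(s)\n",
              nrow(x$objects), sum(x$objects$voxel_count)))
  invisible(x)
}

#' Write a segmentation result to disk
#'
#' The label volume goes to a 16-bit multi-page TIFF (labels as intensity;
#' at most 65535 objects) and the object table to a CSV with one row per
#' object.
#'
#' @param result a `segmentation_result`.
#' @param label_path output TIFF path for the label volume.
#' @param table_path output CSV path for the object table.
#' @return `label_path`, invisibly.
#' @export
write_segmentation <- function(result, label_path, table_path) {
  stopifnot(inherits(result, "segmentation_result"))
  if (nrow(result$objects) > 65535)
    stop("more than 65535 objects cannot be stored in a 16-bit label TIFF")
  lv <- result$label_volume
  nz <- dim(lv)[1]
  pages <- lapply(seq_len(nz), function(z) lv[z, , ] / 65535)
  tiff::writeTIFF(pages, label_path, bits.per.sample = 16L,
                  compression = "none")
  write.csv(result$objects, table_path, row.names = FALSE)
  invisible(label_path)
}

#' Remove small objects from a segmentation
#'
#' Deletes every component with fewer than `min_object_voxels` voxels and
#' relabels survivors consecutively in their original order.
#'
#' @param result a `segmentation_result`.
#' @param min_object_voxels smallest surviving size (default 5, i.e.
#'   objects of 4 or fewer voxels are removed).
#' @return A filtered `segmentation_result`.
#' @export
remove_small_objects <- function(result, min_object_voxels = 5) {
  stopifnot(inherits(result, "segmentation_result"))
  keep <- result$objects$voxel_count >= min_object_voxels
  old <- result$objects$label[keep]
  remap <- integer(if (length(result$objects$label)) max(result$objects$label) else 0)
  remap[old] <- seq_along(old)
  lv <- result$label_volume
  nz <- lv != 0
  lv[nz] <- remap[lv[nz]]
  objects <- result$objects[keep, , drop = FALSE]
  if (nrow(objects)) {
    objects$label <- seq_len(nrow(objects))
    rownames(objects) <- NULL
  }
  structure(list(label_volume = lv, objects = objects),
            class = "segmentation_result")
}

#' Segment fluorescent cells in a 3D stack
#'
#' The full chain: Gaussian smoothing, Otsu binarization of the smoothed
#' volume, connected-component labeling, and small-object removal.
#' Per-object `total_fluorescence` is summed over the normalized
#' *pre-smoothing* intensities, so quantification reflects measured signal
#' while smoothing serves detection only.
#'
#' @param stack a normalized [image_stack()] (or 3D array).
#' @param params a [segmentation_params()].
#' @return A `segmentation_result`.
#' @export
segment <- function(stack, params = segmentation_params()) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (min(vox) == max(vox)) {
    # constant (typically all-zero) volume: nothing to segment
    return(structure(list(label_volume = array(0L, dim = dim(vox)),
                          objects = empty_object_table()),
                     class = "segmentation_result"))
  }
  smoothed <- gaussian_smooth(vox, params)
  thr <- otsu_threshold(smoothed, params)
  res <- label_components(smoothed > thr, params$connectivity, intensity = vox)
  remove_small_objects(res, params$min_object_voxels)
}
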