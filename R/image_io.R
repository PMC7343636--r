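#' Acquisition metadata for one confocal stack
#'
#' Describes how a single 3D stack was acquired: excitation channel,
#' modality (reflectance vs fluorescence), instrument settings that must be
#' normalized out before cross-batch comparison, and voxel geometry.
#'
#' @param channel `"GFP_488"` or `"RFP_532"`.
#' @param modality `"reflectance"` or `"fluorescence"`.
#' @param laser_power laser power in instrument units; strictly positive.
#' @param detector_gain photomultiplier gain in instrument units; strictly
#'   positive.
#' @param lateral_pixel_um lateral pixel pitch in micrometers.
#' @param z_spacing_um axial slice spacing in micrometers; must lie in
#'   `[1, 6]`, a sanity band around typical confocal stack spacings.
#' @param batch_id identifier of the acquisition batch.
#' @param timepoint `"pre"` or `"post"` (relative to treatment).
#'
#' @return A list of class `acquisition_metadata`.
#' @export
acquisition_metadata <- function(channel = c("GFP_488", "RFP_532"),
                                 modality = c("fluorescence", "reflectance"),
                                 laser_power = 100,
                                 detector_gain = 50,
                                 lateral_pixel_um = 1.1,
                                 z_spacing_um = 3.1,
                                 batch_id = "batch01",
                                 timepoint = c("pre", "post")) {
  channel <- match.arg(channel)
  modality <- match.arg(modality)
  timepoint <- match.arg(timepoint)
  if (!is.numeric(laser_power) || laser_power <= 0)
    stop("laser_power must be strictly positive")
  if (!is.numeric(detector_gain) || detector_gain <= 0)
    stop("detector_gain must be strictly positive")
  if (z_spacing_um < 1 || z_spacing_um > 6)
    stop("z_spacing_um must lie in [1, 6] um")
  if (lateral_pixel_um <= 0)
    stop("lateral_pixel_um must be positive")
  structure(
    list(channel = channel, modality = modality,
         laser_power = laser_power, detector_gain = detector_gain,
         lateral_pixel_um = lateral_pixel_um, z_spacing_um = z_spacing_um,
         batch_id = batch_id, timepoint = timepoint),
    class = "acquisition_metadata"
  )
}

#' A 3D image stack with acquisition metadata
#'
#' The atomic imaging object: a non-negative voxel intensity array with
#' dimensions `(z, y, x)` plus the [acquisition_metadata()] describing how
#' it was collected.
#'
#' @param voxels numeric 3D array, dimensions `(nz, ny, nx)`, all values
#'   finite and non-negative.
#' @param metadata an [acquisition_metadata()] object.
#'
#' @return A list of class `image_stack` with elements `voxels` and
#'   `metadata`.
#' @export
image_stack <- function(voxels, metadata) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array (z, y, x)")
  if (!inherits(metadata, "acquisition_metadata"))
    stop("metadata must be an acquisition_metadata object")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("voxel intensities must all be finite")
  if (min(voxels) < 0)
    stop("voxel intensities must be non-negative")
  structure(list(voxels = voxels, metadata = metadata), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x) | %s %s | %s | power %g gain %g\n",
              d[1], d[2], d[3], x$metadata$channel, x$metadata$modality,
              x$metadata$timepoint, x$metadata$laser_power,
              x$metadata$detector_gain))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Pair of simultaneously acquired reflectance and fluorescence stacks
#'
#' Each fluorescence stack is acquired together with a reflectance confocal
#' (RCM) stack of the same field of view; the reflectance stack is the
#' substrate for inter-channel registration.
#'
#' @param reflectance,fluorescence [image_stack()] objects of identical
#'   voxel dimensions and geometry, same channel and timepoint.
#'
#' @return A list of class `bimodal_acquisition`.
#' @export
bimodal_acquisition <- function(reflectance, fluorescence) {
  stopifnot(inherits(reflectance, "image_stack"),
            inherits(fluorescence, "image_stack"))
  if (!identical(dim(reflectance$voxels), dim(fluorescence$voxels)))
    stop("reflectance and fluorescence stacks must have identical dimensions")
  mr <- reflectance$metadata; mf <- fluorescence$metadata
  if (mr$channel != mf$channel || mr$timepoint != mf$timepoint)
    stop("the two stacks of a bimodal acquisition must share channel and timepoint")
  if (mr$lateral_pixel_um != mf$lateral_pixel_um ||
      mr$z_spacing_um != mf$z_spacing_um)
    stop("the two stacks of a bimodal acquisition must share voxel geometry")
  structure(list(reflectance = reflectance, fluorescence = fluorescence),
            class = "bimodal_acquisition")
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages are stacked along z. Only single-sample (grayscale) pages are
#' supported; RGB or multi-sample TIFFs are rejected.
#'
#' @param path path to a multi-page TIFF file.
#' @param metadata the [acquisition_metadata()] to attach (plain TIFFs carry
#'   no acquisition settings; the manifest is the metadata source).
#'
#' @return An [image_stack()].
#' @export
read_stack <- function(path, metadata) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop("unsupported format: RGB/multi-sample TIFF pages in ", path)
  shapes <- vapply(pages, dim, integer(2))
  if (ncol(shapes) > 1 && any(shapes[, -1] != shapes[, 1]))
    stop("malformed TIFF: pages of differing sizes in ", path)
  nz <- length(pages); ny <- shapes[1, 1]; nx <- shapes[2, 1]
  vox <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) vox[z, , ] <- pages[[z]]
  image_stack(vox, metadata)
}

#' Write an image stack as a 16-bit multi-page grayscale TIFF
#'
#' Intensities must fit the 16-bit unsigned range; the round trip through
#' [read_stack()] is lossless for integer-valued volumes.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  vox <- stack$voxels
  if (max(vox) > 65535)
    stop("intensities exceed the 16-bit range")
  nz <- dim(vox)[1]
  pages <- lapply(seq_len(nz), function(z) vox[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Axis-aligned tumor region of interest
#'
#' A voxel box delimiting one tumor spheroid, with 1-based inclusive bounds
#' `z0:z1`, `y0:y1`, `x0:x1` in the registered (GFP-frame) coordinate
#' system.
#'
#' @param roi_id identifier.
#' @param z0,z1,y0,y1,x0,x1 1-based inclusive voxel bounds.
#' @return A list of class `tumor_roi`.
#' @export
tumor_roi <- function(roi_id, z0, z1, y0, y1, x0, x1) {
  b <- c(z0 = z0, z1 = z1, y0 = y0, y1 = y1, x0 = x0, x1 = x1)
  if (any(b < 1) || z1 < z0 || y1 < y0 || x1 < x0)
    stop("ROI bounds must be 1-based with hi >= lo on every axis")
  structure(list(roi_id = as.character(roi_id), bounds = b),
            class = "tumor_roi")
}

roi_contains <- function(roi, zyx) {
  b <- roi$bounds
  zyx[1] >= b["z0"] && zyx[1] <= b["z1"] &&
    zyx[2] >= b["y0"] && zyx[2] <= b["y1"] &&
    zyx[3] >= b["x0"] && zyx[3] <= b["x1"]
}

rois_disjoint <- function(rois) {
  if (length(rois) < 2) return(TRUE)
  for (i in seq_along(rois)[-1]) for (j in seq_len(i - 1)) {
    a <- rois[[i]]$bounds; b <- rois[[j]]$bounds
    if (a["z0"] <= b["z1"] && b["z0"] <= a["z1"] &&
        a["y0"] <= b["y1"] && b["y0"] <= a["y1"] &&
        a["x0"] <= b["x1"] && b["x0"] <= a["x1"]) return(FALSE)
  }
  TRUE
}

.groups <- c("control", "treated_1x", "treated_2x")
.channels <- c("GFP_488", "RFP_532")
.timepoints <- c("pre", "post")

manifest_columns <- c("sample_id", "group", "timepoint", "channel",
                      "reflectance_path", "fluorescence_path",
                      "laser_power", "detector_gain",
                      "lateral_pixel_um", "z_spacing_um",
                      "batch_id", "rois_path")

#' Write a sample manifest
#'
#' The manifest is a plain CSV with one row per (sample, timepoint, channel)
#' acquisition, carrying stack paths, acquisition settings and the path of a
#' per-sample JSON file of tumor ROIs. It round-trips losslessly through
#' [load_manifest()].
#'
#' @param rows a data.frame with the columns `sample_id`, `group`,
#'   `timepoint`, `channel`, `reflectance_path`, `fluorescence_path`,
#'   `laser_power`, `detector_gain`, `lateral_pixel_um`, `z_spacing_um`,
#'   `batch_id`, `rois_path`. An empty (0-row) manifest is valid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(rows, path) {
  if (nrow(rows) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)),
                                        length(manifest_columns)),
                                    manifest_columns))
    write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  missing_cols <- setdiff(manifest_columns, names(rows))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  rows <- rows[, manifest_columns]
  key <- paste(rows$sample_id, rows$timepoint, rows$channel)
  if (anyDuplicated(key))
    stop("duplicate sample/timepoint/channel entries in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  bad <- setdiff(unique(rows$group), .groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Load a sample manifest into sample records
#'
#' Validates the schema written by [write_manifest()]: known group labels,
#' a pre and a post acquisition for every channel a sample has, and
#' resolvable stack paths (relative paths are resolved against the manifest
#' directory).
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every referenced stack file exists
#'   (default `TRUE`).
#' @return A list of `sample_record` objects, each with `sample_id`,
#'   `group`, a data.frame `acquisitions` of manifest rows, `tumor_rois`
#'   (list of [tumor_roi()]), and `qc_flags`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  rows <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character",
                                  batch_id = "character"))
  if (nrow(rows) == 0) return(list())
  missing_cols <- setdiff(manifest_columns, names(rows))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(rows$group), .groups)
  if (length(bad))
    stop("unknown group label(s) in manifest: ", paste(bad, collapse = ", "))
  rows$rois_path[is.na(rows$rois_path)] <- ""
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(p == "" | grepl("^/", p), p,
                                file.path(base, p))
  rows$reflectance_path <- resolve(rows$reflectance_path)
  rows$fluorescence_path <- resolve(rows$fluorescence_path)
  rows$rois_path <- resolve(rows$rois_path)

  records <- lapply(split(rows, rows$sample_id), function(rr) {
    sid <- rr$sample_id[1]
    if (length(unique(rr$group)) != 1)
      stop("sample ", sid, " appears under multiple groups")
    for (ch in unique(rr$channel)) {
      tps <- rr$timepoint[rr$channel == ch]
      miss <- setdiff(.timepoints, tps)
      if (length(miss))
        stop("sample ", sid, " lacks its ", paste(miss, collapse = "/"),
             " acquisition for channel ", ch)
    }
    if (check_paths) {
      paths <- c(rr$reflectance_path, rr$fluorescence_path)
      gone <- paths[!file.exists(paths)]
      if (length(gone))
        stop("sample ", sid, ": missing stack file(s): ",
             paste(gone, collapse = ", "))
    }
    rois <- list()
    rp <- unique(rr$rois_path)
    rp <- rp[rp != ""]
    if (length(rp)) {
      if (length(rp) > 1)
        stop("sample ", sid, " references more than one ROI file")
      rois <- read_rois(rp)
    }
    structure(list(sample_id = sid, group = rr$group[1],
                   acquisitions = rr, tumor_rois = rois,
                   qc_flags = character(0)),
              class = "sample_record")
  })
  unname(records[unique(rows$sample_id)])
}

#' Read tumor ROIs from a JSON file
#' @param path JSON file of objects with fields roi_id, z0, z1, y0, y1, x0, x1.
#' @return list of [tumor_roi()].
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such ROI file: ", path)
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0 || (is.data.frame(df) && nrow(df) == 0)) return(list())
  rois <- lapply(seq_len(nrow(df)), function(i)
    tumor_roi(df$roi_id[i], df$z0[i], df$z1[i], df$y0[i], df$y1[i],
              df$x0[i], df$x1[i]))
  if (!rois_disjoint(rois))
    stop("tumor ROIs in ", path, " overlap; they must be pairwise disjoint")
  rois
}

#' Write tumor ROIs to JSON
#' @param rois list of [tumor_roi()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(roi_id = r$roi_id, z0 = r$bounds["z0"], z1 = r$bounds["z1"],
               y0 = r$bounds["y0"], y1 = r$bounds["y1"],
               x0 = r$bounds["x0"], x1 = r$bounds["x1"],
               row.names = NULL)))
  if (is.null(df)) df <- data.frame()
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
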