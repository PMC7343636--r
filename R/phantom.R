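#' Phantom configuration
#'
#' Parameters of a synthetic bimodal two-channel confocal acquisition of a
#' bioprinted skin construct carrying cSCC tumor spheroids: tdT-RFP tumor
#' cells arranged as spherical shells around a dark (necrotic) core, a
#' sparse population of Zs-GFP-labeled keratinocytes (1% spike-in by
#' default), a stratified reflectance texture, per-channel acquisition
#' scale factors, a small rigid inter-channel misregistration, optional
#' bleed-through, and Poisson-Gaussian sensor noise. Cells are isotropic
#' Gaussian blobs in physical units and therefore anisotropic in voxels,
#' matching the anisotropic acquisition geometry (z spacing coarser than
#' the lateral pitch).
#'
#' The treatment effect removes `kill_fraction_*` of each population
#' between the pre and post acquisitions: exactly
#' `round(kill_fraction * n)` cells drawn uniformly without replacement.
#'
#' @param volume_shape integer (nz, ny, nx); every axis must be >= 16.
#' @param lateral_pixel_um lateral pixel pitch (default 1.1).
#' @param z_spacing_um axial spacing (default 3.1; valid range 1.5–5.3).
#' @param n_spheroids tumor spheroids per construct (default 5).
#' @param spheroid_radius_um spheroid radius (default 20).
#' @param necrotic_core_fraction dark-core radius as a fraction of the
#'   spheroid radius (default 0.5); tumor cells occupy the shell outside it.
#' @param n_cells_per_spheroid tumor cells per spheroid (default 12).
#' @param n_keratinocytes total keratinocytes in the construct
#'   (default 2000); only the labeled subset fluoresces.
#' @param gfp_labeled_fraction fraction of keratinocytes carrying the GFP
#'   label (default 0.01, the 1% spike-in design).
#' @param cell_radius_um cell radius (default 5); blobs are rendered with
#'   `sigma = cell_radius_um / 2`.
#' @param cell_spacing_um minimum lateral-equivalent distance between
#'   rendered cell centers (default 15). The spacing is enforced in
#'   resolution-normalized coordinates: axial distances are down-weighted
#'   by the ratio of the axial to the lateral post-smoothing resolution, so
#'   that cells which the segmentation's fixed smoothing would fuse along z
#'   are kept apart just as they are laterally. Distinct cells then resolve
#'   as distinct objects.
#' @param kill_fraction_tumor,kill_fraction_keratinocyte fraction of each
#'   population removed by treatment, in [0, 1] (defaults 0).
#' @param laser_power_factor,detector_gain_factor per-stack scale factors;
#'   either a single number or a named vector over
#'   `{GFP_488, RFP_532} x {pre, post}` (names like `"GFP_488.pre"`).
#' @param misregistration a [rigid_transform()] giving the displacement of
#'   the RFP channel relative to the GFP channel (default 1 degree,
#'   (2, -1.5) voxels).
#' @param noise list with `photon_scale` (photons per intensity unit;
#'   `Inf` disables shot noise) and `read_noise_sd` (additive Gaussian SD
#'   in intensity units). Default `list(photon_scale = 0.2,
#'   read_noise_sd = 8)`; use [noise_off()] for a noise-free phantom.
#' @param bleed_through_coefficient fraction of the RFP scene leaking into
#'   the GFP detection channel (default 0).
#' @param cell_amplitude peak blob intensity before scaling (default 3000).
#' @param background fluorescence background level (default 100).
#' @param base_laser_power,base_detector_gain reference instrument settings
#'   recorded in metadata (defaults 100 and 50); actual settings are the
#'   base values times the injected factors.
#' @param batch_id batch identifier recorded in metadata.
#' @param rng_seed integer seed; identical seed and config give
#'   bit-identical phantoms.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(28, 240, 240),
                           lateral_pixel_um = 1.1,
                           z_spacing_um = 3.1,
                           n_spheroids = 5,
                           spheroid_radius_um = 32,
                           necrotic_core_fraction = 0.5,
                           n_cells_per_spheroid = 10,
                           n_keratinocytes = 2000,
                           gfp_labeled_fraction = 0.01,
                           cell_radius_um = 5,
                           cell_spacing_um = 15,
                           kill_fraction_tumor = 0,
                           kill_fraction_keratinocyte = 0,
                           laser_power_factor = 1,
                           detector_gain_factor = 1,
                           misregistration = rigid_transform(1, 2, -1.5),
                           noise = list(photon_scale = 0.2, read_noise_sd = 8),
                           bleed_through_coefficient = 0,
                           cell_amplitude = 3000,
                           background = 100,
                           base_laser_power = 100,
                           base_detector_gain = 50,
                           batch_id = "phantom",
                           rng_seed = 1L) {
  fractions <- c(necrotic_core_fraction, gfp_labeled_fraction,
                 kill_fraction_tumor, kill_fraction_keratinocyte,
                 bleed_through_coefficient)
  if (any(fractions < 0 | fractions > 1))
    stop("all fractions must lie in [0, 1]")
  if (length(volume_shape) != 3 || any(volume_shape < 16))
    stop("volume_shape must have three axes of at least 16 voxels each")
  if (z_spacing_um < 1.5 || z_spacing_um > 5.3)
    stop("z_spacing_um must lie in [1.5, 5.3] um")
  expand_factor <- function(f) {
    keys <- c("GFP_488.pre", "GFP_488.post", "RFP_532.pre", "RFP_532.post")
    if (length(f) == 1 && is.null(names(f))) f <- setNames(rep(f, 4), keys)
    if (!all(keys %in% names(f)))
      stop("scale factors need names ", paste(keys, collapse = ", "),
           " (or a single unnamed value)")
    f[keys]
  }
  cfg <- list(volume_shape = as.integer(volume_shape),
              lateral_pixel_um = lateral_pixel_um,
              z_spacing_um = z_spacing_um,
              n_spheroids = n_spheroids,
              spheroid_radius_um = spheroid_radius_um,
              necrotic_core_fraction = necrotic_core_fraction,
              n_cells_per_spheroid = n_cells_per_spheroid,
              n_keratinocytes = n_keratinocytes,
              gfp_labeled_fraction = gfp_labeled_fraction,
              cell_radius_um = cell_radius_um,
              cell_spacing_um = cell_spacing_um,
              kill_fraction_tumor = kill_fraction_tumor,
              kill_fraction_keratinocyte = kill_fraction_keratinocyte,
              laser_power_factor = expand_factor(laser_power_factor),
              detector_gain_factor = expand_factor(detector_gain_factor),
              misregistration = misregistration,
              noise = noise,
              bleed_through_coefficient = bleed_through_coefficient,
              cell_amplitude = cell_amplitude,
              background = background,
              base_laser_power = base_laser_power,
              base_detector_gain = base_detector_gain,
              batch_id = batch_id,
              rng_seed = as.integer(rng_seed))
  structure(cfg, class = "phantom_config")
}

#' Noise settings for a noise-free phantom
#' @return A noise list disabling shot and read noise.
#' @export
noise_off <- function() list(photon_scale = Inf, read_noise_sd = 0)

# --- placement helpers (physical um coordinates, (z, y, x)) ---------------

# minimum-distance check in resolution-normalized coordinates: per-axis
# differences are divided by `scale` before the Euclidean test, so an
# anisotropic point-spread turns into an isotropic spacing requirement.
pairwise_min_ok <- function(p, pts, min_dist, scale = c(1, 1, 1)) {
  if (nrow(pts) == 0) return(TRUE)
  d2 <- ((pts[, 1] - p[1]) / scale[1])^2 + ((pts[, 2] - p[2]) / scale[2])^2 +
    ((pts[, 3] - p[3]) / scale[3])^2
  all(d2 >= min_dist^2)
}

place_points <- function(n, lo, hi, min_dist, scale = c(1, 1, 1),
                         reject = NULL, max_tries = 20000, what = "points") {
  pts <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (nrow(pts) < n) {
    if (tries > max_tries)
      stop("could not place ", n, " ", what, " with spacing ", min_dist,
           " um inside bounds [", paste(signif(lo, 3), collapse = ","), "] - [",
           paste(signif(hi, 3), collapse = ","),
           "] um: the volume is too small for the requested geometry")
    tries <- tries + 1
    p <- lo + runif(3) * (hi - lo)
    if (!is.null(reject) && reject(p)) next
    if (!pairwise_min_ok(p, pts, min_dist, scale)) next
    pts <- rbind(pts, p)
  }
  pts
}

# spheroid centers: random nodes of a jittered lateral grid (mirroring
# spheroids pipetted onto the tissue surface), guaranteeing the lateral
# Chebyshev separation that keeps the axis-aligned tumor ROI boxes
# pairwise disjoint; z is uniform within its bounds.
place_spheroids <- function(n, lo, hi, r_sph, lateral_sep) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  span <- hi - lo
  if (any(span < 0))
    stop("volume too small to place spheroids of radius ", r_sph, " um")
  k <- ceiling(sqrt(n))
  if (k > 1 && (k - 1) * lateral_sep > min(span[2], span[3]))
    stop("could not place ", n, " spheroids of radius ", r_sph,
         " um with disjoint ROI boxes (lateral clearance ", lateral_sep,
         " um): the field of view is too small for the requested geometry")
  step_y <- if (k > 1) span[2] / (k - 1) else 0
  step_x <- if (k > 1) span[3] / (k - 1) else 0
  jit_y <- max(0, (step_y - lateral_sep) / 2)
  jit_x <- max(0, (step_x - lateral_sep) / 2)
  nodes <- expand.grid(gy = seq_len(k) - 1, gx = seq_len(k) - 1)
  pick <- nodes[sample.int(nrow(nodes), n), , drop = FALSE]
  y <- pmin(pmax(lo[2] + pick$gy * step_y + runif(n, -jit_y, jit_y), lo[2]),
            hi[2])
  x <- pmin(pmax(lo[3] + pick$gx * step_x + runif(n, -jit_x, jit_x), lo[3]),
            hi[3])
  cbind(lo[1] + runif(n) * span[1], y, x)
}

# sample points uniformly in a spherical shell [r_in, r_out] around center
place_shell_cells <- function(center, r_in, r_out, n, min_dist,
                              scale = c(1, 1, 1), lo, hi, max_tries = 20000) {
  pts <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (nrow(pts) < n) {
    if (tries > max_tries)
      stop("could not place ", n, " tumor cells with spacing ", min_dist,
           " um in a shell of radii [", r_in, ", ", r_out,
           "] um: reduce n_cells_per_spheroid or the spacing")
    tries <- tries + 1
    u <- runif(3)
    rad <- (r_in^3 + (r_out^3 - r_in^3) * u[1])^(1 / 3)
    cth <- 2 * u[2] - 1
    phi <- 2 * pi * u[3]
    sth <- sqrt(1 - cth^2)
    p <- center + rad * c(cth, sth * cos(phi), sth * sin(phi))
    if (any(p < lo) || any(p > hi)) next
    if (!pairwise_min_ok(p, pts, min_dist, scale)) next
    pts <- rbind(pts, p)
  }
  pts
}

# add Gaussian blobs (separable evaluation) to a (z,y,x) volume;
# centers in continuous 1-based voxel coordinates, sigma in voxels.
add_blobs <- function(vol, centers, sigma_vox, amplitudes) {
  d <- dim(vol)
  r <- ceiling(4 * sigma_vox)
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]
    zi <- max(1, floor(c0[1] - r[1])):min(d[1], ceiling(c0[1] + r[1]))
    yi <- max(1, floor(c0[2] - r[2])):min(d[2], ceiling(c0[2] + r[2]))
    xi <- max(1, floor(c0[3] - r[3])):min(d[3], ceiling(c0[3] + r[3]))
    wz <- exp(-(zi - c0[1])^2 / (2 * sigma_vox[1]^2))
    wy <- exp(-(yi - c0[2])^2 / (2 * sigma_vox[2]^2))
    wx <- exp(-(xi - c0[3])^2 / (2 * sigma_vox[3]^2))
    vol[zi, yi, xi] <- vol[zi, yi, xi] +
      amplitudes[i] * (wz %o% wy %o% wx)
  }
  vol
}

# smooth 2D random field via separable Gaussian filtering of white noise
smooth_field2d <- function(ny, nx, sigma_y, sigma_x) {
  f <- matrix(rnorm(ny * nx), ny, nx)
  smooth1 <- function(m, sigma, along_rows) {
    if (sigma <= 0) return(m)
    r <- ceiling(3 * sigma)
    k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
    n <- if (along_rows) nrow(m) else ncol(m)
    pad <- function(i) pmin(pmax(i, 1), n)  # clamp padding
    acc <- 0
    for (j in -r:r) {
      idx <- pad(seq_len(n) + j)
      acc <- acc + k[j + r + 1] * (if (along_rows) m[idx, , drop = FALSE]
                                   else m[, idx, drop = FALSE])
    }
    acc
  }
  f <- smooth1(f, sigma_y, TRUE)
  f <- smooth1(f, sigma_x, FALSE)
  (f - mean(f)) / (sd(f) + .Machine$double.eps)
}

# stratified-skin reflectance scene: bright superficial band, honeycomb
# mid band (dark nuclei on bright cytoplasm), fibrous (anisotropically
# streaked) lower band. One static scene per phantom.
render_reflectance <- function(d, lateral_um) {
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  corneum <- 2200 + 500 * smooth_field2d(ny, nx, 6 / lateral_um, 6 / lateral_um)
  honey <- smooth_field2d(ny, nx, 5 / lateral_um, 5 / lateral_um)
  spinosum <- 1500 - 700 * pmax(honey, 0) + 200 * smooth_field2d(ny, nx, 2, 2)
  dermis <- 1000 + 450 * smooth_field2d(ny, nx, 1.2, 10 / lateral_um)
  vol <- array(0, dim = d)
  zfrac <- (seq_len(nz) - 0.5) / nz
  for (z in seq_len(nz)) {
    w_c <- exp(-((zfrac[z] - 0.08) / 0.10)^2)
    w_s <- exp(-((zfrac[z] - 0.40) / 0.22)^2)
    w_d <- exp(-((zfrac[z] - 0.85) / 0.25)^2)
    tot <- w_c + w_s + w_d
    vol[z, , ] <- (w_c * corneum + w_s * spinosum + w_d * dermis) / tot
  }
  pmax(vol, 0)
}

apply_sensor_noise <- function(vol, noise) {
  array(sensor_noise(as.numeric(vol), noise$photon_scale,
                     noise$read_noise_sd), dim = dim(vol))
}

um_to_vox <- function(p_um, pitch) {
  cbind(p_um[, 1, drop = FALSE] / pitch[1] + 0.5,
        p_um[, 2, drop = FALSE] / pitch[2] + 0.5,
        p_um[, 3, drop = FALSE] / pitch[3] + 0.5)
}

#' Generate a bimodal two-channel phantom with ground truth
#'
#' Renders four stacks per timepoint (reflectance + fluorescence for each
#' of the GFP and RFP channels) before and after a simulated treatment that
#' removes a configured fraction of each cell population. The RFP channel
#' is displaced by the configured misregistration; intensities are scaled
#' by the injected laser/gain factors; optional bleed-through adds a
#' fraction of the RFP scene into the GFP channel; Poisson shot noise and
#' Gaussian read noise are applied last.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `pre` and `post` (each a list of
#'   [bimodal_acquisition()] keyed by channel), and `truth`, a
#'   `phantom_ground_truth` list carrying per-population cell centers
#'   (continuous 1-based voxel coordinates) pre and post, the labeled
#'   keratinocyte flags, the injected transform and scale factors, the
#'   configured kill fractions, and tumor ROIs derived from the spheroid
#'   geometry.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$rng_seed)

  d <- config$volume_shape
  pitch <- c(config$z_spacing_um, config$lateral_pixel_um,
             config$lateral_pixel_um)
  extent <- d * pitch
  sigma_um <- config$cell_radius_um / 2
  sigma_vox <- sigma_um / pitch

  # --- geometry ------------------------------------------------------------
  # post-smoothing resolution per axis (blob sigma convolved with the
  # segmentation default of 2 voxels); cell spacing is enforced in these
  # normalized units so axial proximity is penalized like lateral proximity
  smooth_sigma_um <- 2 * pitch
  res_um <- sqrt(sigma_um^2 + smooth_sigma_um^2)
  spacing_scale <- res_um / res_um[2]

  r_sph <- config$spheroid_radius_um
  roi_margin <- config$cell_radius_um + 3
  margin <- r_sph + config$cell_radius_um
  lo_s <- c(margin, margin, margin)
  hi_s <- extent - margin
  if (any(hi_s <= lo_s))
    stop("volume too small to place spheroids of radius ", r_sph,
         " um: axis extents are ", paste(signif(extent, 3), collapse = " x "),
         " um but ", 2 * margin, " um of clearance is needed per axis")
  sph_centers <- place_spheroids(config$n_spheroids, lo_s, hi_s, r_sph,
                                 lateral_sep = 2 * (r_sph + roi_margin) + 2)

  # cells stay clear of the stack borders by one blob extent plus the
  # axial smoothing reach, so every rendered cell is fully resolvable
  border <- c(config$cell_radius_um + 2 * config$z_spacing_um,
              config$cell_radius_um, config$cell_radius_um)
  cell_lo <- border
  cell_hi <- extent - border
  r_core <- config$necrotic_core_fraction * r_sph
  tumor <- do.call(rbind, lapply(seq_len(config$n_spheroids), function(i) {
    pts <- place_shell_cells(sph_centers[i, ], r_core, r_sph,
                             config$n_cells_per_spheroid,
                             config$cell_spacing_um, spacing_scale,
                             cell_lo, cell_hi)
    cbind(pts, spheroid = i)
  }))
  if (is.null(tumor)) tumor <- matrix(numeric(0), ncol = 4)

  n_lab <- round(config$gfp_labeled_fraction * config$n_keratinocytes)
  outside_spheroids <- function(p) {
    if (nrow(sph_centers) == 0) return(FALSE)
    d2 <- (sph_centers[, 1] - p[1])^2 + (sph_centers[, 2] - p[2])^2 +
      (sph_centers[, 3] - p[3])^2
    any(d2 < (r_sph + config$cell_radius_um)^2)  # TRUE => reject
  }
  ker_lab <- place_points(n_lab, cell_lo, cell_hi, config$cell_spacing_um,
                          scale = spacing_scale,
                          reject = outside_spheroids, what = "keratinocytes")
  n_unlab <- config$n_keratinocytes - n_lab
  ker_unlab <- matrix(numeric(0), ncol = 3)
  if (n_unlab > 0) {
    ker_unlab <- matrix(runif(3 * n_unlab), ncol = 3)
    ker_unlab <- sweep(sweep(ker_unlab, 2, cell_hi - cell_lo, "*"),
                       2, cell_lo, "+")
  }
  ker <- rbind(ker_lab, ker_unlab)
  labeled <- c(rep(TRUE, n_lab), rep(FALSE, n_unlab))

  # --- treatment: exact uniform removal ------------------------------------
  n_t <- nrow(tumor)
  kill_t <- round(config$kill_fraction_tumor * n_t)
  keep_t <- rep(TRUE, n_t)
  if (kill_t > 0) keep_t[sample.int(n_t, kill_t)] <- FALSE
  n_k <- nrow(ker)
  kill_k <- round(config$kill_fraction_keratinocyte * n_k)
  keep_k <- rep(TRUE, n_k)
  if (kill_k > 0) keep_k[sample.int(n_k, kill_k)] <- FALSE

  # per-cell brightness, fixed across timepoints
  amp_t <- config$cell_amplitude * exp(rnorm(n_t, sd = 0.1))
  amp_k <- config$cell_amplitude * exp(rnorm(max(n_k, 0), sd = 0.1))

  # --- scenes in the GFP (fixed) frame -------------------------------------
  refl_scene <- render_reflectance(d, config$lateral_pixel_um)
  tumor_vox <- um_to_vox(tumor[, 1:3, drop = FALSE], pitch)
  ker_vox <- um_to_vox(ker, pitch)

  render_fluor <- function(centers_vox, amps, keep) {
    vol <- array(config$background, dim = d)
    sel <- which(keep)
    if (length(sel))
      vol <- add_blobs(vol, centers_vox[sel, , drop = FALSE], sigma_vox,
                       amps[sel])
    vol
  }
  rfp <- list(pre = render_fluor(tumor_vox, amp_t, rep(TRUE, n_t)),
              post = render_fluor(tumor_vox, amp_t, keep_t))
  gfp <- list(pre = render_fluor(ker_vox, amp_k, labeled),
              post = render_fluor(ker_vox, amp_k, labeled & keep_k))
  if (config$bleed_through_coefficient > 0) {
    bt <- config$bleed_through_coefficient
    gfp$pre <- gfp$pre + bt * (rfp$pre - config$background)
    gfp$post <- gfp$post + bt * (rfp$post - config$background)
  }

  # --- assemble per-channel stacks -----------------------------------------
  t_mis <- config$misregistration
  mk_meta <- function(channel, modality, tp) {
    key <- paste(channel, tp, sep = ".")
    acquisition_metadata(
      channel = channel, modality = modality,
      laser_power = config$base_laser_power * config$laser_power_factor[[key]],
      detector_gain = config$base_detector_gain *
        config$detector_gain_factor[[key]],
      lateral_pixel_um = config$lateral_pixel_um,
      z_spacing_um = config$z_spacing_um,
      batch_id = config$batch_id, timepoint = tp)
  }
  mk_tp <- function(tp) {
    out <- list()
    for (ch in c("GFP_488", "RFP_532")) {
      key <- paste(ch, tp, sep = ".")
      fac <- config$laser_power_factor[[key]] *
        config$detector_gain_factor[[key]]
      fl <- if (ch == "GFP_488") gfp[[tp]] else rfp[[tp]]
      rf <- refl_scene
      if (ch == "RFP_532") {
        fl <- apply_transform(fl, t_mis)
        rf <- apply_transform(rf, t_mis)
      }
      out[[ch]] <- bimodal_acquisition(
        image_stack(apply_sensor_noise(rf, config$noise),
                    mk_meta(ch, "reflectance", tp)),
        image_stack(apply_sensor_noise(fl * fac, config$noise),
                    mk_meta(ch, "fluorescence", tp)))
    }
    out
  }
  pre <- mk_tp("pre")
  post <- mk_tp("post")

  # --- ground truth ---------------------------------------------------------
  centers_df <- function(vox, extra = NULL) {
    df <- data.frame(z = vox[, 1], y = vox[, 2], x = vox[, 3])
    if (!is.null(extra)) df <- cbind(df, extra)
    df
  }
  rois <- lapply(seq_len(config$n_spheroids), function(i) {
    cvox <- um_to_vox(sph_centers[i, , drop = FALSE], pitch)
    rv <- (r_sph + roi_margin) / pitch
    tumor_roi(sprintf("tumor%02d", i),
              max(1, floor(cvox[1] - rv[1])), min(d[1], ceiling(cvox[1] + rv[1])),
              max(1, floor(cvox[2] - rv[2])), min(d[2], ceiling(cvox[2] + rv[2])),
              max(1, floor(cvox[3] - rv[3])), min(d[3], ceiling(cvox[3] + rv[3])))
  })
  truth <- structure(list(
    tumor_cell_centers_pre = centers_df(tumor_vox,
                                        data.frame(spheroid = tumor[, 4])),
    tumor_cell_centers_post = centers_df(tumor_vox[keep_t, , drop = FALSE],
                                         data.frame(spheroid = tumor[keep_t, 4])),
    keratinocyte_centers_pre = centers_df(ker_vox,
                                          data.frame(labeled = labeled)),
    keratinocyte_centers_post = centers_df(ker_vox[keep_k, , drop = FALSE],
                                           data.frame(labeled = labeled[keep_k])),
    true_transform = t_mis,
    true_scale_factors = list(laser_power = config$laser_power_factor,
                              detector_gain = config$detector_gain_factor),
    true_kill_fractions = c(tumor = config$kill_fraction_tumor,
                            keratinocyte = config$kill_fraction_keratinocyte),
    spheroid_centers_vox = centers_df(um_to_vox(sph_centers, pitch)),
    tumor_rois = rois,
    config = config), class = "phantom_ground_truth")

  list(pre = pre, post = post, truth = truth)
}

#' Default treatment-arm kill fractions
#'
#' The fractions of tumor cells and keratinocytes removed per study arm,
#' chosen to match the reductions reported for the real assay: untreated
#' controls lose about 13% of tumor objects over the imaging interval,
#' 1 uM 5FU about 52%, and keratinocytes about 11% under treatment; the
#' double-dose arm uses the dose-response reduction of about 72%.
#'
#' @return A named list of `c(tumor, keratinocyte)` kill fractions per
#'   group.
#' @export
default_kill_fractions <- function() {
  list(control = c(tumor = 0.13, keratinocyte = 0.00),
       treated_1x = c(tumor = 0.52, keratinocyte = 0.11),
       treated_2x = c(tumor = 0.718, keratinocyte = 0.15))
}

#' Simulate a phantom study and write it to disk
#'
#' Generates one phantom per sample, writes every stack as a 16-bit
#' multi-page TIFF, per-sample ROI and ground-truth JSON files, and a
#' sample manifest. Samples are grouped into acquisition batches of
#' `batch_size` sharing laser/gain factors, which the manifest records so
#' the pipeline can normalize them out; settings are consistent between the
#' pre and post acquisitions of a sample.
#'
#' @param outdir output directory (created if needed).
#' @param groups named integer vector of samples per group, e.g.
#'   `c(control = 2, treated_1x = 2)`.
#' @param kill_fractions named list of `c(tumor, keratinocyte)` kill
#'   fractions per group; defaults to [default_kill_fractions()].
#' @param base_config a [phantom_config()] providing everything except the
#'   kill fractions, seeds and scale factors.
#' @param batch_size samples per acquisition batch (default 6).
#' @param vary_settings draw per-batch laser/gain factors (default `TRUE`).
#' @param seed integer seed for the study-level randomization.
#' @return Path of the manifest file, invisibly.
#' @export
simulate_dataset <- function(outdir,
                             groups = c(control = 2, treated_1x = 2),
                             kill_fractions = default_kill_fractions(),
                             base_config = phantom_config(),
                             batch_size = 6,
                             vary_settings = TRUE,
                             seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  sample_groups <- rep(names(groups), groups)
  n <- length(sample_groups)
  rows <- list()
  for (i in seq_len(n)) {
    grp <- sample_groups[i]
    kf <- kill_fractions[[grp]]
    if (is.null(kf)) stop("no kill fractions configured for group ", grp)
    batch <- sprintf("batch%02d", (i - 1) %/% batch_size + 1)
    if (vary_settings) {
      pf <- runif(2, 0.7, 1.3)   # per (batch-slot, channel); pre == post
      gf <- runif(2, 0.8, 1.25)
    } else {
      pf <- c(1, 1); gf <- c(1, 1)
    }
    lp <- c(GFP_488.pre = pf[1], GFP_488.post = pf[1],
            RFP_532.pre = pf[2], RFP_532.post = pf[2])
    dg <- c(GFP_488.pre = gf[1], GFP_488.post = gf[1],
            RFP_532.pre = gf[2], RFP_532.post = gf[2])
    cfg <- base_config
    cfg$kill_fraction_tumor <- unname(kf["tumor"])
    cfg$kill_fraction_keratinocyte <- unname(kf["keratinocyte"])
    cfg$laser_power_factor <- lp
    cfg$detector_gain_factor <- dg
    cfg$batch_id <- batch
    cfg$rng_seed <- seed + i
    ph <- generate_phantom(cfg)

    sid <- sprintf("S%03d", i)
    rois_path <- file.path(outdir, paste0(sid, "_rois.json"))
    write_rois(ph$truth$tumor_rois, rois_path)
    write_truth(ph$truth, file.path(outdir, paste0(sid, "_truth.json")))
    for (tp in c("pre", "post")) {
      for (ch in c("GFP_488", "RFP_532")) {
        acq <- ph[[tp]][[ch]]
        rp <- file.path(outdir, sprintf("%s_%s_%s_refl.tif", sid, tp, ch))
        fp <- file.path(outdir, sprintf("%s_%s_%s_fluo.tif", sid, tp, ch))
        write_stack(acq$reflectance, rp)
        write_stack(acq$fluorescence, fp)
        m <- acq$fluorescence$metadata
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, group = grp, timepoint = tp, channel = ch,
          reflectance_path = basename(rp), fluorescence_path = basename(fp),
          laser_power = m$laser_power, detector_gain = m$detector_gain,
          lateral_pixel_um = m$lateral_pixel_um,
          z_spacing_um = m$z_spacing_um,
          batch_id = batch, rois_path = basename(rois_path))
      }
    }
  }
  manifest <- file.path(outdir, "manifest.csv")
  write_manifest(do.call(rbind, rows), manifest)
  invisible(manifest)
}

#' Write phantom ground truth to JSON
#' @param truth a `phantom_ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    tumor_cell_centers_pre = truth$tumor_cell_centers_pre,
    tumor_cell_centers_post = truth$tumor_cell_centers_post,
    keratinocyte_centers_pre = truth$keratinocyte_centers_pre,
    keratinocyte_centers_post = truth$keratinocyte_centers_post,
    true_transform = list(rotation_deg = truth$true_transform$rotation_deg,
                          dy = unname(truth$true_transform$translation["dy"]),
                          dx = unname(truth$true_transform$translation["dx"])),
    true_scale_factors = lapply(truth$true_scale_factors, as.list),
    true_kill_fractions = as.list(truth$true_kill_fractions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
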