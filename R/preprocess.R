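#' Normalization reference settings
#'
#' Fluorescence intensities are put on a common scale by rescaling each
#' stack to a reference laser power and detector gain ("standard image"
#' settings). The gain response is modeled as a power law with a
#' configurable exponent; the default exponent of 1 treats the detector as
#' linear in its gain setting.
#'
#' @param reference_laser_power,reference_detector_gain strictly positive
#'   instrument units.
#' @param gain_exponent exponent of the gain power law (default 1).
#' @return A list of class `normalization_reference`.
#' @export
normalization_reference <- function(reference_laser_power = 100,
                                    reference_detector_gain = 50,
                                    gain_exponent = 1.0) {
  if (reference_laser_power <= 0 || reference_detector_gain <= 0)
    stop("reference power and gain must be strictly positive")
  structure(list(reference_laser_power = reference_laser_power,
                 reference_detector_gain = reference_detector_gain,
                 gain_exponent = gain_exponent),
            class = "normalization_reference")
}

#' Normalize a fluorescence stack for laser power and detector gain
#'
#' Voxel-wise rescaling
#' `out = in * (ref_power / power) * (ref_gain / gain)^gain_exponent`.
#' The stack's metadata is updated to the reference settings, so the
#' operation is idempotent.
#'
#' @param stack an [image_stack()] whose metadata carries positive
#'   `laser_power` and `detector_gain`.
#' @param ref a [normalization_reference()].
#' @return The normalized [image_stack()].
#' @export
normalize_stack <- function(stack, ref) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(ref, "normalization_reference"))
  m <- stack$metadata
  if (m$laser_power <= 0 || m$detector_gain <= 0)
    stop("stack metadata must carry positive laser_power and detector_gain")
  scale <- (ref$reference_laser_power / m$laser_power) *
    (ref$reference_detector_gain / m$detector_gain)^ref$gain_exponent
  m$laser_power <- ref$reference_laser_power
  m$detector_gain <- ref$reference_detector_gain
  out <- stack
  out$voxels <- stack$voxels * scale
  out$metadata <- m
  out
}

#' z-sum projection of a stack
#'
#' Collapses a 3D stack to 2D by summing along the optical axis; the
#' projection of the reflectance stack is the registration substrate.
#'
#' @param stack an [image_stack()] or a 3D array.
#' @return A numeric matrix of shape `(ny, nx)`.
#' @export
zsum_projection <- function(stack) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (length(vox) == 0) stop("empty stack")
  colSums(vox, dims = 1)
}

#' In-plane rigid transform
#'
#' Rotation about the image center followed by translation, mapping input
#' coordinates to output coordinates:
#' `p' = R(theta) (p - c) + c + (dy, dx)` with `p = (y, x)` and `c` the
#' image center.
#'
#' @param rotation_deg rotation angle in degrees (counter-clockwise in
#'   (y, x) index coordinates).
#' @param dy,dx translation in voxels.
#' @return A list of class `rigid_transform2d`.
#' @export
rigid_transform <- function(rotation_deg = 0, dy = 0, dx = 0) {
  structure(list(rotation_deg = rotation_deg,
                 translation = c(dy = dy, dx = dx)),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> rotation %.3f deg, translation (dy=%.3f, dx=%.3f)\n",
              x$rotation_deg, x$translation["dy"], x$translation["dx"]))
  invisible(x)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(t) {
  th <- -t$rotation_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  tr <- -as.numeric(R %*% t$translation)
  rigid_transform(-t$rotation_deg, tr[1], tr[2])
}

#' Compose two rigid transforms
#' @param t2,t1 [rigid_transform()] objects; the result applies `t1` first.
#' @return The composed transform `t2 o t1`.
#' @export
compose_transforms <- function(t2, t1) {
  th2 <- t2$rotation_deg * pi / 180
  R2 <- matrix(c(cos(th2), -sin(th2), sin(th2), cos(th2)), 2, 2, byrow = TRUE)
  tr <- as.numeric(R2 %*% t1$translation) + t2$translation
  rigid_transform(t1$rotation_deg + t2$rotation_deg, tr[1], tr[2])
}

# Resample a 2D image under a rigid transform by inverse warping with
# bilinear interpolation; out-of-bounds samples are 0.
warp2d <- function(img, t) {
  d <- c(1L, nrow(img), ncol(img))
  matrix(warp_stack(as.numeric(img), d, t$rotation_deg,
                    t$translation[["dy"]], t$translation[["dx"]]),
         nrow(img), ncol(img))
}

#' Apply a rigid transform slice-wise to a stack
#'
#' Every z-slice is resampled under the same in-plane transform with
#' bilinear interpolation; voxels mapped from outside the field of view are
#' filled with 0. No intensity crosses slices.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param t a [rigid_transform()].
#' @return The transformed stack, same type as the input.
#' @export
apply_transform <- function(stack, t) {
  is_stack <- inherits(stack, "image_stack")
  vox <- if (is_stack) stack$voxels else stack
  if (t$rotation_deg == 0 && all(t$translation == 0)) {
    out <- vox
  } else {
    out <- array(warp_stack(as.numeric(vox), dim(vox), t$rotation_deg,
                            t$translation[["dy"]], t$translation[["dx"]]),
                 dim = dim(vox))
  }
  if (is_stack) {
    stack$voxels <- out
    stack
  } else out
}

# FFT cross-correlation of mean-subtracted, Hann-tapered images. Returns the
# best circular shift (moving relative to fixed) with parabolic sub-pixel
# refinement, plus a normalized score.
xcorr_shift <- function(fixed, moving) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  w <- outer(hann(ny), hann(nx))
  f <- (fixed - mean(fixed)) * w
  m <- (moving - mean(moving)) * w
  cc <- Re(fft(fft(m) * Conj(fft(f)), inverse = TRUE)) / length(f)
  peak <- arrayInd(which.max(cc), dim(cc))
  py <- peak[1]; px <- peak[2]
  # parabolic refinement on the circular neighborhood of the peak
  wrap <- function(i, n) ((i - 1) %% n) + 1
  sub <- function(vm1, v0, vp1) {
    d <- (vm1 - 2 * v0 + vp1)
    if (d == 0) 0 else 0.5 * (vm1 - vp1) / d
  }
  ddy <- sub(cc[wrap(py - 1, ny), px], cc[py, px], cc[wrap(py + 1, ny), px])
  ddx <- sub(cc[py, wrap(px - 1, nx)], cc[py, px], cc[py, wrap(px + 1, nx)])
  shift_y <- (py - 1) + ddy; shift_x <- (px - 1) + ddx
  if (shift_y > ny / 2) shift_y <- shift_y - ny
  if (shift_x > nx / 2) shift_x <- shift_x - nx
  score <- max(cc) / (sqrt(sum(f^2)) * sqrt(sum(m^2)) + .Machine$double.eps)
  list(dy = shift_y, dx = shift_x, score = score)
}

#' Estimate the rigid misalignment between two 2D projections
#'
#' Finds the in-plane rigid transform `t` such that
#' `moving ~ apply_transform(fixed, t)` — i.e. `t` is the displacement of
#' the moving image relative to the fixed one; registration applies
#' [invert_transform()] of the result to the moving channel. The search
#' maximizes windowed normalized cross-correlation over a coarse rotation
#' grid with FFT translation recovery, then refines the rotation locally.
#'
#' @param fixed,moving numeric matrices of identical shape, non-constant.
#' @param max_rotation_deg half-width of the rotation search range
#'   (default 6).
#' @param coarse_step_deg,fine_step_deg rotation grid steps (default 1 and
#'   0.1 degrees).
#' @return A [rigid_transform()].
#' @export
estimate_rigid_transform <- function(fixed, moving,
                                     max_rotation_deg = 6,
                                     coarse_step_deg = 1,
                                     fine_step_deg = 0.1) {
  if (!all(dim(fixed) == dim(moving)))
    stop("fixed and moving images must have the same shape")
  if (sd(fixed) == 0 || sd(moving) == 0)
    stop("degenerate input: constant image cannot be registered")

  eval_theta <- function(theta) {
    # un-rotate moving by theta about center; residual shift s satisfies
    # tau = R(theta) s for the injected translation tau
    m2 <- if (theta == 0) moving else
      warp2d(moving, rigid_transform(-theta, 0, 0))
    r <- xcorr_shift(fixed, m2)
    th <- theta * pi / 180
    dy <- cos(th) * r$dy - sin(th) * r$dx
    dx <- sin(th) * r$dy + cos(th) * r$dx
    list(theta = theta, dy = dy, dx = dx, score = r$score)
  }

  thetas <- seq(-max_rotation_deg, max_rotation_deg, by = coarse_step_deg)
  coarse <- lapply(thetas, eval_theta)
  best <- coarse[[which.max(vapply(coarse, `[[`, numeric(1), "score"))]]
  fine_range <- seq(best$theta - coarse_step_deg, best$theta + coarse_step_deg,
                    by = fine_step_deg)
  fine_range <- fine_range[abs(fine_range) <= max_rotation_deg + 1e-9]
  fine <- lapply(fine_range, eval_theta)
  best <- fine[[which.max(vapply(fine, `[[`, numeric(1), "score"))]]
  rigid_transform(best$theta, best$dy, best$dx)
}
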