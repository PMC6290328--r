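# Organ segmentation from the nuclear channel: anisotropic median filter,
# plane-by-plane rolling-ball background subtraction, grayscale ellipsoidal
# closing (filling the gaps between cells), then hysteresis thresholding.
# All kernel sizes are given in micrometres and converted per axis using
# the volume's voxel spacing.

#' Segmentation parameters
#'
#' Physical-unit parameters of the enhancement + thresholding pipeline.
#' Defaults are the standard protocol values: a 3.3 x 3.3 x 4.3 um median
#' kernel (x, y, z), 66.4 um rolling-ball radius, 20 um closing radius.
#' Hysteresis thresholds default to an automatic rule (high = Otsu
#' threshold of the enhanced volume, low = `low_fraction` x high); both can
#' be overridden with absolute intensities.
#'
#' @param median_kernel_um median kernel extent per axis, `(z, y, x)` um.
#' @param rolling_ball_um rolling-ball radius (um), applied per z plane on
#'   the in-plane axes.
#' @param closing_um radius of the ellipsoidal grayscale closing element
#'   (um, converted per axis).
#' @param low,high absolute hysteresis thresholds; `NULL` uses the
#'   automatic rule. If both are given, `low <= high` is required.
#' @param low_fraction low = `low_fraction` x high under the automatic rule.
#' @param rolling_ball_mode `"subtract"` (default: remove the rolling-ball
#'   background, keep the signal) or `"background"` (keep the smooth
#'   background estimate instead; the historical wording is ambiguous about
#'   which component feeds the closing step).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(median_kernel_um = c(z = 4.3, y = 3.3, x = 3.3),
                                rolling_ball_um = 66.4,
                                closing_um = 20,
                                low = NULL, high = NULL,
                                low_fraction = 0.5,
                                rolling_ball_mode = c("subtract", "background")) {
  median_kernel_um <- as_zyx(median_kernel_um, "median_kernel_um")
  check_positive(median_kernel_um, "median_kernel_um")
  check_positive(rolling_ball_um, "rolling_ball_um")
  check_positive(closing_um, "closing_um")
  check_positive(low_fraction, "low_fraction")
  if (!is.null(low) && !is.null(high) && low > high)
    stopf("hysteresis low threshold (%g) must be <= high (%g)", low, high)
  structure(list(median_kernel_um = median_kernel_um,
                 rolling_ball_um = rolling_ball_um,
                 closing_um = closing_um, low = low, high = high,
                 low_fraction = low_fraction,
                 rolling_ball_mode = match.arg(rolling_ball_mode)),
            class = "segmentation_params")
}

#' Organ mask
#'
#' Boolean voxel grid on the source volume's grid, with the resolved
#' parameters used to produce it.
#'
#' @param mask logical 3D array (z, y, x).
#' @param params provenance: resolved parameters (list) or `NULL`.
#' @param specimen_id source specimen id.
#' @return object of class `organ_mask`.
#' @export
organ_mask <- function(mask, params = NULL, specimen_id = NA_character_) {
  if (!is.logical(mask) || length(dim(mask)) != 3)
    stopf("'mask' must be a logical 3D array")
  structure(list(mask = mask, params = params, specimen_id = specimen_id),
            class = "organ_mask")
}

#' @export
print.organ_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<organ_mask> %d x %d x %d, %d foreground voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Otsu threshold of a numeric array
#'
#' Maximizes between-class variance over a 256-bin histogram; returns the
#' intensity at the optimal bin boundary.
#'
#' @param v numeric vector or array.
#' @param nbins histogram bins.
#' @return threshold value.
#' @export
otsu_threshold <- function(v, nbins = 256) {
  v <- as.numeric(v)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(v, edges, all.inside = TRUE), nbins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b[-nbins])
  edges[k + 1]
}

#' Enhance the nuclear channel
#'
#' Applies, in order: (1) 3D median filter with a per-axis kernel of the
#' nearest odd voxel count to `median_kernel_um / spacing` (minimum 1; if
#' the kernel is below one voxel on every axis the median step is skipped
#' with a warning); (2) per-z-plane rolling-ball background estimation with
#' the ball radius converted on the in-plane axes, subtracted by default;
#' (3) grayscale morphological closing with an ellipsoidal structuring
#' element of the closing radius converted per axis, filling the gaps
#' between cells.
#'
#' @param volume a [confocal_volume()] with a nuclear-role channel.
#' @param params a [segmentation_params()].
#' @return enhanced 3D array with attribute `"resolved"` recording all
#'   voxel-unit parameters actually used.
#' @export
enhance_nuclear_channel <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "confocal_volume"),
            inherits(params, "segmentation_params"))
  ch <- get_channel(volume, "nuclear")
  sp <- volume$spacing_um
  dims <- dim(ch)

  kvox <- um_to_odd_voxels(params$median_kernel_um, sp)
  if (all(params$median_kernel_um < sp)) {
    warnf("median kernel below one voxel on every axis; skipping median step")
    med <- ch
  } else {
    med <- array(cpp_median3d(as.numeric(ch), dims, (kvox - 1L) %/% 2L), dims)
  }

  ball_vox <- c(y = unname(params$rolling_ball_um / sp["y"]),
                x = unname(params$rolling_ball_um / sp["x"]))
  rb <- med
  for (z in seq_len(dims[1])) {
    plane <- med[z, , ]
    bg <- cpp_rolling_ball_bg(plane, ball_vox["y"], ball_vox["x"])
    rb[z, , ] <- if (params$rolling_ball_mode == "subtract") plane - bg else bg
  }

  close_vox <- um_to_voxels(rep(params$closing_um, 3), sp)
  dil <- cpp_morph_ellipsoid(as.numeric(rb), dims, as.numeric(close_vox), TRUE)
  out <- array(cpp_morph_ellipsoid(dil, dims, as.numeric(close_vox), FALSE),
               dims)
  attr(out, "resolved") <- list(median_kernel_vox = kvox,
                                rolling_ball_vox = ball_vox,
                                closing_vox = close_vox,
                                rolling_ball_mode = params$rolling_ball_mode)
  out
}

#' Segment the organ by hysteresis thresholding
#'
#' Enhances the nuclear channel, zeroes any manual exclusion region
#' (representing observer removal of residual abdominal-wall tissue), then
#' applies hysteresis thresholding: voxels at or above the high threshold
#' seed the mask, and voxels at or above the low threshold are kept iff
#' 26-connected to a seed. If no voxel reaches the high threshold an empty
#' mask is returned with a warning (not an error).
#'
#' @param volume a [confocal_volume()].
#' @param params a [segmentation_params()].
#' @param exclusion_mask optional logical array on the same grid marking
#'   voxels to remove before segmentation; no output voxel ever lies inside
#'   it.
#' @return an [organ_mask()]; its `params` record the resolved voxel-unit
#'   parameters and the thresholds actually used.
#' @export
segment_organ <- function(volume, params = segmentation_params(),
                          exclusion_mask = NULL) {
  enh <- enhance_nuclear_channel(volume, params)
  dims <- dim(enh)
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dims))
      stopf("exclusion mask shape differs from the volume grid")
    enh[exclusion_mask] <- 0
  }
  if (diff(range(enh)) == 0 && is.null(params$high)) {
    warnf("enhanced volume has no contrast; returning an empty mask")
    return(organ_mask(array(FALSE, dims),
                      params = attr(enh, "resolved"),
                      specimen_id = volume$metadata$specimen_id %||% NA_character_))
  }
  high <- params$high %||% otsu_threshold(enh)
  low <- params$low %||% (params$low_fraction * high)
  if (low > high) stopf("resolved low threshold (%g) exceeds high (%g)", low, high)
  if (!any(enh >= high)) {
    warnf("no voxel reaches the high threshold (%g); returning an empty mask", high)
    mask <- array(FALSE, dims)
  } else {
    mask <- array(cpp_hysteresis3d(as.numeric(enh), dims, low, high), dims)
  }
  if (!is.null(exclusion_mask)) mask[exclusion_mask] <- FALSE
  organ_mask(mask,
             params = c(attr(enh, "resolved"),
                        list(low = low, high = high,
                             excluded_voxels = if (is.null(exclusion_mask)) 0L
                                               else sum(exclusion_mask))),
             specimen_id = volume$metadata$specimen_id %||% NA_character_)
}

#' Dice overlap of two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return 2|A and B| / (|A| + |B|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
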