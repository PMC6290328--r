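# Tip/core partition of the segmented organ and regional quantification of
# the raw AR stain. The tip is the region between the gubernacular cord and
# the dense muscular layer, identified in real data by a masked observer
# (supplied here as an explicit tip-mask input); `core` names the rest of
# the organ. Regional means are always computed on the RAW AR channel,
# never on the enhanced one.

#' Region labels
#'
#' Integer label grid on the organ's voxel grid: 0 = outside organ,
#' 1 = core, 2 = tip. Tip and core are disjoint and together cover the
#' organ mask.
#'
#' @param labels 3D integer array with values in `{0, 1, 2}`.
#' @param provenance list describing how the partition was produced
#'   (observer id, landmark, or `"synthetic"`).
#' @return object of class `region_labels`.
#' @export
region_labels <- function(labels, provenance = list()) {
  if (length(dim(labels)) != 3) stopf("'labels' must be a 3D array")
  if (!all(labels %in% 0:2)) stopf("region labels must be 0, 1 or 2")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, provenance = provenance),
            class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  cat(sprintf("<region_labels> core: %d voxels, tip: %d voxels\n",
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' Build region labels from an observer-supplied tip mask
#'
#' Labels organ voxels intersecting the tip mask as tip and the remaining
#' organ voxels as core. A tip mask entirely outside the organ mask is an
#' observer/grid mismatch and errors.
#'
#' @param mask an [organ_mask()].
#' @param tip_mask logical array on the same grid.
#' @param provenance provenance list (e.g. observer id).
#' @return a [region_labels()].
#' @export
load_region_labels <- function(mask, tip_mask,
                               provenance = list(observer = "manual")) {
  stopifnot(inherits(mask, "organ_mask"))
  if (is.list(tip_mask) && !is.null(tip_mask$labels))
    tip_mask <- tip_mask$labels > 0
  if (!identical(dim(tip_mask), dim(mask$mask)))
    stopf("tip mask grid differs from the organ mask grid")
  tip <- tip_mask & mask$mask
  if (!any(tip))
    stopf("tip mask does not intersect the organ mask (observer/grid mismatch?)")
  labels <- array(0L, dim(mask$mask))
  labels[mask$mask] <- 1L
  labels[tip] <- 2L
  region_labels(labels, provenance)
}

#' Geometric tip/core partition from a cord landmark
#'
#' Stand-in for the manual observer on synthetic pipelines: the organ's
#' principal axis is found by PCA of the mask voxel coordinates (in um),
#' oriented toward the cord landmark, and the tip is the organ voxels
#' within `fraction` of the organ's extent nearest the landmark along that
#' axis.
#'
#' @param mask an [organ_mask()].
#' @param landmark_um cord landmark `(z, y, x)` in um.
#' @param fraction tip fraction of the principal-axis extent, in \[0, 1\].
#' @param spacing_um voxel spacing `(z, y, x)` um.
#' @param max_landmark_dist_um error if the landmark is farther than this
#'   from the mask.
#' @return a [region_labels()].
#' @export
default_tip_partition <- function(mask, landmark_um, fraction, spacing_um,
                                  max_landmark_dist_um = 50) {
  stopifnot(inherits(mask, "organ_mask"))
  if (fraction < 0 || fraction > 1) stopf("fraction must lie in [0, 1]")
  spacing_um <- as_zyx(spacing_um, "spacing_um")
  landmark_um <- as_zyx(landmark_um, "landmark_um")
  idx <- which(mask$mask, arr.ind = TRUE)
  if (!nrow(idx)) stopf("empty organ mask")
  coords <- cbind((idx[, 1] - 0.5) * spacing_um["z"],
                  (idx[, 2] - 0.5) * spacing_um["y"],
                  (idx[, 3] - 0.5) * spacing_um["x"])
  d2 <- (coords[, 1] - landmark_um["z"])^2 +
    (coords[, 2] - landmark_um["y"])^2 + (coords[, 3] - landmark_um["x"])^2
  if (sqrt(min(d2)) > max_landmark_dist_um)
    stopf("cord landmark lies %.1f um from the organ mask (limit %.1f um)",
          sqrt(min(d2)), max_landmark_dist_um)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  axis1 <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  # orient the axis toward the landmark
  if (sum((landmark_um - ctr) * axis1) < 0) axis1 <- -axis1
  proj <- as.vector(cc %*% axis1)
  ext <- range(proj)
  labels <- array(0L, dim(mask$mask))
  labels[mask$mask] <- 1L
  if (fraction > 0) {
    # proj is in the same (column-major) order as labels[mask$mask]
    tip_sel <- proj >= ext[2] - fraction * diff(ext)
    labels[mask$mask][tip_sel] <- 2L
  }
  region_labels(labels, provenance = list(observer = "geometric",
                                          landmark_um = landmark_um,
                                          fraction = fraction))
}

#' Regional summary of raw AR intensity
#'
#' Per-region mean of the raw AR channel over the labeled voxels, plus the
#' tip:core ratio. Empty regions are reported as `NA` (undefined), never
#' zero, and the ratio is defined only when both regions are non-empty.
#'
#' @param volume a [confocal_volume()] with an AR channel.
#' @param labels a [region_labels()].
#' @param specimen_id,strain,day metadata overrides (default: taken from
#'   the volume metadata).
#' @return one-row data frame: `specimen_id`, `strain`, `day`, `tip_mean`,
#'   `core_mean`, `tip_n`, `core_n`, `tip_core_ratio`.
#' @export
summarize_regions <- function(volume, labels, specimen_id = NULL,
                              strain = NULL, day = NULL) {
  stopifnot(inherits(volume, "confocal_volume"),
            inherits(labels, "region_labels"))
  ar <- get_channel(volume, "ar")
  if (!identical(dim(ar), dim(labels$labels)))
    stopf("label grid differs from the volume grid")
  tip_v <- ar[labels$labels == 2L]
  core_v <- ar[labels$labels == 1L]
  tip_mean <- if (length(tip_v)) mean(tip_v) else NA_real_
  core_mean <- if (length(core_v)) mean(core_v) else NA_real_
  ratio <- if (length(tip_v) && length(core_v)) tip_mean / core_mean else NA_real_
  md <- volume$metadata
  data.frame(specimen_id = specimen_id %||% (md$specimen_id %||% NA_character_),
             strain = strain %||% (md$strain %||% NA_character_),
             day = day %||% (md$day %||% NA_character_),
             tip_mean = tip_mean, core_mean = core_mean,
             tip_n = length(tip_v), core_n = length(core_v),
             tip_core_ratio = ratio)
}

#' Compare tip vs core intensity within strain/day groups
#'
#' Paired comparison of per-specimen tip and core means within each
#' (strain, day) group: paired t by default (the test is two-sided; the
#' underlying study does not state sidedness), or an exact sign-flip
#' permutation test. Groups with fewer than 2 usable specimens are skipped
#' with a warning.
#'
#' @param summaries data frame of [summarize_regions()] rows.
#' @param method `"t"` or `"permutation"`.
#' @param alpha significance level.
#' @return named list of [group_comparison()], keyed `"strain:day"`.
#' @export
compare_regions <- function(summaries, method = c("t", "permutation"),
                            alpha = 0.05) {
  method <- match.arg(method)
  s <- as.data.frame(summaries)
  out <- list()
  for (st in unique(s$strain)) for (d in unique(s$day[s$strain == st])) {
    sub <- s[s$strain == st & s$day == d, ]
    sub <- sub[is.finite(sub$tip_mean) & is.finite(sub$core_mean), ]
    key <- paste(st, d, sep = ":")
    if (nrow(sub) < 2) {
      warnf("group %s skipped: fewer than 2 specimens with defined regions", key)
      next
    }
    out[[key]] <- paired_comparison(sub$tip_mean, sub$core_mean,
                                    method = method, alpha = alpha)
  }
  out
}
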