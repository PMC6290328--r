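# Synthetic confocal phantom: a gubernaculum-shaped organ (ellipsoidal body
# with a cylindrical cord appendage) filled with nucleus-localized signal.
# The nuclear channel carries bright nuclei everywhere in the organ; the AR
# channel carries per-nucleus intensity at the generative mean of the
# nucleus's region (AR-enriched tip, mesenchymal core, AR-poor muscle
# shell). Ground-truth organ mask and tip/core labels are returned
# voxel-exactly, together with the exact noise-free regional means.
#
# Nuclei are placed by stratified sampling (one jittered nucleus per cubic
# lattice cell of volume 1000/density um^3), emulating the near-uniform
# packing of confluent fetal mesenchyme; a Poisson point process would give
# unrealistically large per-region count fluctuations at tissue densities.

#' Specification of a confocal volume phantom
#'
#' Defaults describe a fetal gubernaculum imaged at 25x: an elongated
#' ellipsoidal body (semi-axes 55 x 38 x 38 um) with an 18 um cord, densely
#' packed nuclei (2 per 1000 um^3, radius 3.5 um), an AR-enriched tip
#' (tip:core generative contrast 1.5), an AR-poor outer muscle shell, and
#' additive Gaussian camera noise at 5 percent of the core AR level on a
#' 16-bit-like intensity scale. Voxel spacing defaults to
#' 1.1 x 1.1 x 2.15 um (x, y, z), a plausible confocal sampling at which the
#' standard 3.3 x 3.3 x 4.3 um median kernel maps to 3 x 3 x 3 voxels.
#'
#' @param shape grid size in voxels, `(z, y, x)`.
#' @param spacing_um voxel spacing in um, `(z, y, x)`.
#' @param organ_semiaxes_um ellipsoid semi-axes of the organ body, `(z,y,x)`.
#' @param organ_center_um body centre in um, `(z, y, x)`; default centres the
#'   body in-plane and leaves room for the cord above.
#' @param cord_length_um,cord_radius_um cylindrical cord appendage attached
#'   at the +z pole.
#' @param tip_fraction fraction of total organ height (cord end downwards)
#'   labeled as the AR-enriched tip, in (0, 1).
#' @param nuclear_density nuclei per 1000 um^3 of organ.
#' @param nucleus_radius_um nucleus radius in um.
#' @param nucleus_shape `"sphere"` (solid) or `"gaussian"` blobs.
#' @param ar_levels named vector: per-nucleus AR intensity means for
#'   `core`, `tip`, `muscle` nuclei plus the `background` level of both
#'   channels (arbitrary units, >= 0).
#' @param nuclear_intensity brightness of nuclei in the nuclear channel.
#' @param muscle_shell_um thickness of the AR-poor muscle shell on the body
#'   surface (0 disables it).
#' @param cytoplasm_fraction optional cytoplasmic AR fraction painted in a
#'   1.6-radius shell around each nucleus (default 0: purely nuclear).
#' @param noise_sigma additive Gaussian noise sd (intensity units). Noise is
#'   not clipped at zero (detector-offset convention), so region means stay
#'   unbiased.
#' @param poisson_scale optional Poisson noise: intensities are replaced by
#'   `rpois(v / scale) * scale` before Gaussian noise. `NULL` disables.
#' @param calibrate_ratio optional numeric target: after painting, the
#'   noise-free AR intensities of the tip region are rescaled so the
#'   generative regional-mean tip:core ratio equals this value exactly.
#'   The regional contrast -- not the per-nucleus contrast -- is what the
#'   imaging experiment defines, and without calibration the realized
#'   regional ratio wanders around the per-nucleus one through discrete
#'   nucleus-count and boundary-clipping effects in the small tip. `NULL`
#'   (default) disables calibration.
#' @param strain,day,specimen_id metadata labels carried into the volume.
#' @param seed integer RNG seed; identical spec + seed reproduces the
#'   volume bit for bit.
#' @return object of class `volume_phantom_spec`.
#' @export
volume_phantom_spec <- function(shape = c(z = 64L, y = 128L, x = 128L),
                                spacing_um = c(z = 2.15, y = 1.1, x = 1.1),
                                organ_semiaxes_um = c(z = 55, y = 38, x = 38),
                                organ_center_um = NULL,
                                cord_length_um = 18,
                                cord_radius_um = 7,
                                tip_fraction = 0.25,
                                nuclear_density = 2.0,
                                nucleus_radius_um = 3.5,
                                nucleus_shape = c("sphere", "gaussian"),
                                ar_levels = c(core = 1500, tip = 2250,
                                              muscle = 450, background = 100),
                                nuclear_intensity = 3000,
                                muscle_shell_um = 10,
                                cytoplasm_fraction = 0,
                                noise_sigma = 75,
                                poisson_scale = NULL,
                                calibrate_ratio = NULL,
                                strain = "LE/wt", day = "E17",
                                specimen_id = NULL,
                                seed = 1L) {
  shape <- as_zyx(shape, "shape")
  spacing_um <- as_zyx(spacing_um, "spacing_um")
  organ_semiaxes_um <- as_zyx(organ_semiaxes_um, "organ_semiaxes_um")
  check_positive(shape, "shape"); check_positive(spacing_um, "spacing_um")
  check_positive(organ_semiaxes_um, "organ_semiaxes_um")
  check_positive(cord_length_um, "cord_length_um")
  check_positive(cord_radius_um, "cord_radius_um")
  check_positive(nucleus_radius_um, "nucleus_radius_um")
  if (!is.numeric(tip_fraction) || tip_fraction <= 0 || tip_fraction >= 1)
    stopf("tip_fraction must lie in (0, 1)")
  if (nuclear_density < 0) stopf("nuclear_density must be >= 0")
  stopifnot(all(c("core", "tip", "muscle", "background") %in% names(ar_levels)))
  if (any(ar_levels < 0) || nuclear_intensity < 0)
    stopf("intensity means must be >= 0")
  if (muscle_shell_um < 0) stopf("muscle_shell_um must be >= 0")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  extent <- shape * spacing_um
  if (is.null(organ_center_um)) {
    organ_center_um <- c(z = unname(organ_semiaxes_um["z"]) + 4,
                         y = unname(extent["y"]) / 2,
                         x = unname(extent["x"]) / 2)
  }
  organ_center_um <- as_zyx(organ_center_um, "organ_center_um")
  lo <- organ_center_um - organ_semiaxes_um
  hi <- organ_center_um + organ_semiaxes_um
  hi["z"] <- hi["z"] + cord_length_um
  for (ax in c("z", "y", "x")) {
    if (lo[ax] < 0 || hi[ax] > extent[ax])
      stopf("organ geometry exceeds the grid on the %s axis (needs [%.1f, %.1f] um of %.1f um)",
            ax, lo[ax], hi[ax], extent[ax])
  }
  structure(list(shape = as.integer(shape), spacing_um = spacing_um,
                 organ_semiaxes_um = organ_semiaxes_um,
                 organ_center_um = organ_center_um,
                 cord_length_um = cord_length_um,
                 cord_radius_um = cord_radius_um,
                 tip_fraction = tip_fraction,
                 nuclear_density = nuclear_density,
                 nucleus_radius_um = nucleus_radius_um,
                 nucleus_shape = match.arg(nucleus_shape),
                 ar_levels = ar_levels,
                 nuclear_intensity = nuclear_intensity,
                 muscle_shell_um = muscle_shell_um,
                 cytoplasm_fraction = cytoplasm_fraction,
                 noise_sigma = noise_sigma, poisson_scale = poisson_scale,
                 calibrate_ratio = calibrate_ratio,
                 strain = strain, day = day,
                 specimen_id = specimen_id %||% sprintf("phantom-%d", seed),
                 seed = as.integer(seed)),
            class = "volume_phantom_spec")
}

## continuous-space membership tests -----------------------------------------

phantom_rho2 <- function(spec, z, y, x) {
  c0 <- spec$organ_center_um; s <- spec$organ_semiaxes_um
  ((z - c0["z"]) / s["z"])^2 + ((y - c0["y"]) / s["y"])^2 +
    ((x - c0["x"]) / s["x"])^2
}

phantom_in_cord <- function(spec, z, y, x) {
  c0 <- spec$organ_center_um
  ztop <- c0["z"] + spec$organ_semiaxes_um["z"] + spec$cord_length_um
  ((y - c0["y"])^2 + (x - c0["x"])^2 <= spec$cord_radius_um^2) &
    z >= c0["z"] & z <= ztop
}

#' Generate a ground-truthed confocal phantom
#'
#' @param spec a [volume_phantom_spec()].
#' @return list with elements `volume` (a [confocal_volume()] with nuclear
#'   and AR channels), `organ_mask` (an [organ_mask()] of the exact organ),
#'   `region_labels` (a [region_labels()] tip/core partition), and `truth`
#'   (list: nucleus table, exact noise-free per-region AR means,
#'   `tip_core_ratio`, tip boundary height, cord landmark in um).
#' @export
generate_confocal_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_phantom_spec"))
  with_seed(spec$seed, {
    nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
    sp <- spec$spacing_um
    zc <- (seq_len(nz) - 0.5) * sp["z"]
    yc <- (seq_len(ny) - 0.5) * sp["y"]
    xc <- (seq_len(nx) - 0.5) * sp["x"]
    c0 <- spec$organ_center_um; ax <- spec$organ_semiaxes_um

    tz <- ((zc - c0["z"]) / ax["z"])^2
    ty <- ((yc - c0["y"]) / ax["y"])^2
    tx <- ((xc - c0["x"]) / ax["x"])^2
    rho2 <- outer(outer(tz, ty, "+"), tx, "+")
    body <- rho2 <= 1
    cord_xy <- outer((yc - c0["y"])^2, (xc - c0["x"])^2, "+") <=
      spec$cord_radius_um^2
    ztop <- c0["z"] + ax["z"] + spec$cord_length_um
    cord_z <- zc >= c0["z"] & zc <= ztop
    cord <- outer(cord_z, cord_xy, "&")
    organ <- body | cord

    # tip = organ voxels within tip_fraction of the organ's z extent,
    # measured from the cord end downwards (includes the cord itself)
    zpresent <- apply(organ, 1, any)
    if (!any(zpresent)) stopf("degenerate phantom: empty organ")
    zrange <- range(zc[zpresent])
    tip_z <- zrange[2] - spec$tip_fraction * diff(zrange)
    tip <- organ & array(zc >= tip_z, dim = c(nz, ny, nx))

    shell_frac <- spec$muscle_shell_um / mean(ax)
    muscle <- body & (rho2 > (1 - shell_frac)^2) & !tip

    bg <- unname(spec$ar_levels["background"])
    # voxel-wise AR level: each voxel carries its own region's generative
    # mean (tip / muscle / core, extended outside the organ by tip height),
    # so nuclei straddling a region boundary do not cross-contaminate the
    # regional means
    level_vox <- array(unname(spec$ar_levels["core"]), c(nz, ny, nx))
    level_vox[muscle] <- unname(spec$ar_levels["muscle"])
    level_vox[array(zc >= tip_z, dim = c(nz, ny, nx))] <-
      unname(spec$ar_levels["tip"])
    # nucleus profile in [0, 1]: 1 inside a solid nucleus, Gaussian falloff
    # for the "gaussian" shape; the AR profile adds the optional cytoplasmic
    # halo
    profile <- array(0, c(nz, ny, nx))
    ar_profile <- array(0, c(nz, ny, nx))

    nuclei <- NULL
    if (spec$nuclear_density > 0) {
      d <- (1000 / spec$nuclear_density)^(1 / 3)
      gz <- seq(max(0, c0["z"] - ax["z"]), ztop, by = d)
      gy <- seq(c0["y"] - ax["y"], c0["y"] + ax["y"], by = d)
      gx <- seq(c0["x"] - ax["x"], c0["x"] + ax["x"], by = d)
      grid <- expand.grid(z = gz, y = gy, x = gx)
      n <- nrow(grid)
      pz <- grid$z + runif(n, 0, d)
      py <- grid$y + runif(n, 0, d)
      px <- grid$x + runif(n, 0, d)
      inside <- phantom_rho2(spec, pz, py, px) <= 1 |
        phantom_in_cord(spec, pz, py, px)
      pz <- pz[inside]; py <- py[inside]; px <- px[inside]
      region <- ifelse(pz >= tip_z, "tip",
                       ifelse(phantom_rho2(spec, pz, py, px) >
                                (1 - shell_frac)^2 & shell_frac > 0,
                              "muscle", "core"))
      nuclei <- data.frame(z_um = pz, y_um = py, x_um = px, region = region,
                           ar_level = unname(spec$ar_levels[region]))
      r <- spec$nucleus_radius_um
      for (i in seq_len(nrow(nuclei))) {
        iz <- which(abs(zc - pz[i]) <= 2 * r)
        iy <- which(abs(yc - py[i]) <= 2 * r)
        ix <- which(abs(xc - px[i]) <= 2 * r)
        if (!length(iz) || !length(iy) || !length(ix)) next
        d2 <- outer(outer((zc[iz] - pz[i])^2, (yc[iy] - py[i])^2, "+"),
                    (xc[ix] - px[i])^2, "+")
        g <- if (spec$nucleus_shape == "sphere") (d2 <= r^2) * 1
             else exp(-d2 / (2 * (r / 2)^2))
        ga <- if (spec$cytoplasm_fraction > 0)
          pmax(g, (d2 <= (1.6 * r)^2) * spec$cytoplasm_fraction) else g
        profile[iz, iy, ix] <- pmax(profile[iz, iy, ix], g)
        ar_profile[iz, iy, ix] <- pmax(ar_profile[iz, iy, ix], ga)
      }
    }
    nuc_ch <- bg + (spec$nuclear_intensity - bg) * profile
    ar_ch <- bg + (level_vox - bg) * ar_profile

    labels <- array(0L, c(nz, ny, nx))
    labels[organ] <- 1L
    labels[tip] <- 2L

    core_vox <- labels == 1L
    if (!is.null(spec$calibrate_ratio) && any(tip) && any(core_vox)) {
      realized <- mean(ar_ch[tip]) / mean(ar_ch[core_vox])
      if (is.finite(realized) && realized > 0)
        ar_ch[tip] <- ar_ch[tip] * (spec$calibrate_ratio / realized)
    }
    truth <- list(
      n_nuclei = if (is.null(nuclei)) 0L else nrow(nuclei),
      nuclei = nuclei,
      tip_mean = if (any(tip)) mean(ar_ch[tip]) else NA_real_,
      core_mean = if (any(core_vox)) mean(ar_ch[core_vox]) else NA_real_,
      tip_z_um = tip_z,
      cord_landmark_um = c(z = unname(ztop - 1), y = unname(c0["y"]),
                           x = unname(c0["x"])))
    truth$tip_core_ratio <- truth$tip_mean / truth$core_mean

    if (!is.null(spec$poisson_scale)) {
      sc <- spec$poisson_scale
      nuc_ch[] <- rpois(length(nuc_ch), pmax(0, nuc_ch) / sc) * sc
      ar_ch[] <- rpois(length(ar_ch), pmax(0, ar_ch) / sc) * sc
    }
    if (spec$noise_sigma > 0) {
      nuc_ch <- nuc_ch + array(rnorm(length(nuc_ch), 0, spec$noise_sigma),
                               dim = dim(nuc_ch))
      ar_ch <- ar_ch + array(rnorm(length(ar_ch), 0, spec$noise_sigma),
                             dim = dim(ar_ch))
    }

    vol <- confocal_volume(list(nuc_ch, ar_ch), c("nuclear", "ar"),
                           spec$spacing_um,
                           metadata = list(specimen_id = spec$specimen_id,
                                           strain = spec$strain,
                                           day = spec$day))
    list(volume = vol,
         organ_mask = organ_mask(organ, params = list(source = "synthetic"),
                                 specimen_id = spec$specimen_id),
         region_labels = region_labels(labels,
                                       provenance = list(observer = "synthetic",
                                                         tip_z_um = tip_z)),
         truth = truth)
  })
}

#' Phantom preset for contrast-recovery experiments
#'
#' A phantom whose exact generative tip:core regional-mean ratio equals the
#' requested contrast: AR background and muscle shell are removed so no
#' dilution term enters the regional means, the tip intensities are
#' calibrated so the generative regional ratio is exactly `ratio` (see
#' `calibrate_ratio` in [volume_phantom_spec()]), and noise is set to the
#' stated fraction of the core level.
#'
#' @param ratio nominal tip:core contrast.
#' @param core_level per-nucleus core AR mean.
#' @param noise_frac Gaussian noise sd as a fraction of `core_level`.
#' @param seed RNG seed.
#' @param ... passed to [volume_phantom_spec()].
#' @return a [volume_phantom_spec()].
#' @export
contrast_phantom_spec <- function(ratio = 1.5, core_level = 1500,
                                  noise_frac = 0.10, seed = 1L, ...) {
  volume_phantom_spec(
    ar_levels = c(core = core_level, tip = core_level * ratio,
                  muscle = core_level, background = 0),
    muscle_shell_um = 0,
    noise_sigma = noise_frac * core_level,
    calibrate_ratio = ratio,
    seed = seed, ...)
}
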