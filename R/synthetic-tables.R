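# Tabular synthetic data: aspiration cohorts drawn through the forward
# mechanical model, summary-level regional-intensity cohorts, and fiber
# morphometry tables with debris contamination. All generators are pure
# functions of (spec, seed).

#' Default true-modulus design
#'
#' Field-plausible apparent moduli (kPa) for a two-strain, two-day,
#' three-position design: wild-type organs have a midportion 1.5x stiffer
#' than base/tip and stiffen 1.5x between E19 and E21; the cryptorchid-model
#' strain is spatially and temporally flat. Values are a stated world for
#' recovery experiments, not measured tissue values (the source figures are
#' graphical only).
#'
#' @return data frame with columns `strain`, `day`, `position`,
#'   `modulus_kpa`.
#' @export
default_modulus_table <- function() {
  expand <- expand.grid(position = c("base", "midportion", "tip"),
                        day = c("E19", "E21"),
                        strain = c("LE/wt", "LE/orl"),
                        stringsAsFactors = FALSE)
  base_mod <- ifelse(expand$strain == "LE/wt",
                     ifelse(expand$day == "E19", 2.0, 3.0), 2.5)
  mid_boost <- ifelse(expand$strain == "LE/wt" &
                        expand$position == "midportion", 1.5, 1.0)
  expand$modulus_kpa <- base_mod * mid_boost
  expand[c("strain", "day", "position", "modulus_kpa")]
}

#' Specification of a synthetic aspiration cohort
#'
#' @param moduli data frame of true moduli per (strain, day, position); see
#'   [default_modulus_table()]. All moduli must be positive.
#' @param n_per_group specimens per design cell (>= 1).
#' @param pipette_radius_um mean/sd of the pipette inner radius (the
#'   protocol trims pipettes to roughly 80 um diameter).
#' @param wall_thickness_um pipette wall thickness (um).
#' @param pressure_kpa aspiration pressure magnitude (the protocol applies
#'   70 kPa of suction; stored as a positive magnitude).
#' @param noise_rel relative sd of multiplicative noise on the aspirated
#'   length (0 = noise-free forward model).
#' @param phi_form wall-function reading used by the forward model.
#' @param seed RNG seed.
#' @return object of class `aspiration_cohort_spec`.
#' @export
aspiration_cohort_spec <- function(moduli = default_modulus_table(),
                                   n_per_group = 15,
                                   pipette_radius_um = c(mean = 40, sd = 2),
                                   wall_thickness_um = 8,
                                   pressure_kpa = 70,
                                   noise_rel = 0.15,
                                   phi_form = c("product", "ratio"),
                                   seed = 1L) {
  moduli <- as.data.frame(moduli)
  stopifnot(all(c("strain", "day", "position", "modulus_kpa") %in% names(moduli)))
  if (any(!is.finite(moduli$modulus_kpa)) || any(moduli$modulus_kpa <= 0))
    stopf("all true moduli must be positive")
  check_positive(pressure_kpa, "pressure_kpa")
  check_positive(wall_thickness_um, "wall_thickness_um")
  check_positive(pipette_radius_um[["mean"]], "pipette_radius_um mean")
  if (n_per_group < 1) stopf("n_per_group must be >= 1")
  if (noise_rel < 0) stopf("noise_rel must be >= 0")
  structure(list(moduli = moduli, n_per_group = as.integer(n_per_group),
                 pipette_radius_um = pipette_radius_um,
                 wall_thickness_um = wall_thickness_um,
                 pressure_kpa = pressure_kpa, noise_rel = noise_rel,
                 phi_form = match.arg(phi_form), seed = as.integer(seed)),
            class = "aspiration_cohort_spec")
}

position_band <- function(position) {
  switch(position, base = c(0, 0.25), midportion = c(0.40, 0.60),
         tip = c(0.75, 1), stopf("unknown position '%s'", position))
}

#' Generate an aspiration cohort through the forward mechanical model
#'
#' For every specimen the aspirated length is computed by inverting the
#' half-space model at the group's true modulus,
#' `L = 3 a dp / (2 pi E_true Phi(a, w))`, then perturbed by multiplicative
#' Gaussian noise of relative sd `noise_rel` (resampled if non-positive, so
#' every generated L is > 0).
#'
#' @param spec an [aspiration_cohort_spec()].
#' @return data frame with one row per measurement: `specimen_id`, `strain`,
#'   `day`, `position`, `height_fraction`, `a_um`, `w_um`, `dp_kpa`, `L_um`
#'   and the hidden `true_modulus_kpa`.
#' @export
generate_aspiration_cohort <- function(spec) {
  stopifnot(inherits(spec, "aspiration_cohort_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (g in seq_len(nrow(spec$moduli))) {
      grp <- spec$moduli[g, ]
      band <- position_band(grp$position)
      for (i in seq_len(spec$n_per_group)) {
        a <- 0
        while (a <= spec$wall_thickness_um / 8)
          a <- rnorm(1, spec$pipette_radius_um[["mean"]],
                     spec$pipette_radius_um[["sd"]])
        w <- spec$wall_thickness_um
        phi <- wall_function(a, w, spec$phi_form)
        L0 <- 3 * a * spec$pressure_kpa /
          (2 * pi * grp$modulus_kpa * phi)
        mult <- 0
        while (mult <= 0) mult <- 1 + rnorm(1, 0, spec$noise_rel)
        if (spec$noise_rel == 0) mult <- 1
        rows[[length(rows) + 1]] <- data.frame(
          specimen_id = sprintf("%s-%s-%s-%02d", gsub("/", "", grp$strain),
                                grp$day, grp$position, i),
          strain = grp$strain, day = grp$day, position = grp$position,
          height_fraction = runif(1, band[1], band[2]),
          a_um = a, w_um = w, dp_kpa = spec$pressure_kpa,
          L_um = L0 * mult, true_modulus_kpa = grp$modulus_kpa)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a summary-level regional-intensity cohort
#'
#' Emulates the per-specimen output of the imaging pipeline (tip and core
#' mean AR intensity per specimen) without rendering full volumes:
#' specimen-level baselines vary log-normally (biological variability) and
#' each regional mean carries multiplicative measurement noise.
#'
#' @param n_specimens specimens in the cohort.
#' @param core_mean population core-region mean intensity (a.u.).
#' @param tip_core_ratio true tip:core contrast (1 = null).
#' @param noise_rel relative measurement noise per regional mean.
#' @param biological_rel log-sd of the specimen-level baseline.
#' @param strain,day metadata labels.
#' @param seed RNG seed.
#' @return data frame shaped like [summarize_regions()] output rows.
#' @export
generate_intensity_cohort <- function(n_specimens = 8, core_mean = 1500,
                                      tip_core_ratio = 1.5, noise_rel = 0.10,
                                      biological_rel = 0.2,
                                      strain = "LE/wt", day = "E21",
                                      seed = 1L) {
  if (n_specimens < 1) stopf("n_specimens must be >= 1")
  with_seed(seed, {
    base <- core_mean * rlnorm(n_specimens, 0, biological_rel)
    core_obs <- base * (1 + rnorm(n_specimens, 0, noise_rel))
    tip_obs <- base * tip_core_ratio * (1 + rnorm(n_specimens, 0, noise_rel))
    data.frame(specimen_id = sprintf("sim-%02d", seq_len(n_specimens)),
               strain = strain, day = day,
               tip_mean = tip_obs, core_mean = core_obs,
               tip_n = NA_integer_, core_n = NA_integer_,
               tip_core_ratio = tip_obs / core_obs)
  })
}

#' Specification of a synthetic fiber table
#'
#' True fibers are long, large objects (log-normal area, aspect >= 5 by
#' construction via a shifted log-normal); debris objects are small and
#' round-ish with area and aspect distributions crossing the filtering
#' cutoffs, so the table exercises the background-exclusion rule.
#'
#' @param n_fibers,n_debris object counts (>= 0).
#' @param fiber_area_lnorm `c(meanlog, sdlog)` of fiber area (um^2).
#' @param fiber_aspect `c(shift, meanlog, sdlog)`: aspect = shift + lnorm.
#' @param debris_area_lnorm,debris_aspect_lnorm debris distributions
#'   (debris aspect = 1 + lnorm, so the support crosses the aspect cutoff).
#' @param fill_factor area / (feret_max x feret_min) packing factor used to
#'   derive feret diameters from area and aspect.
#' @param strain,treatment,organ_id metadata labels.
#' @param seed RNG seed.
#' @return object of class `fiber_table_spec`.
#' @export
fiber_table_spec <- function(n_fibers = 60, n_debris = 120,
                             fiber_area_lnorm = c(meanlog = log(1500), sdlog = 0.5),
                             fiber_aspect = c(shift = 5, meanlog = log(4), sdlog = 0.5),
                             debris_area_lnorm = c(meanlog = log(250), sdlog = 0.9),
                             debris_aspect_lnorm = c(meanlog = log(2), sdlog = 0.6),
                             fill_factor = 0.8,
                             strain = "LE/wt", treatment = "control",
                             organ_id = NA_character_, seed = 1L) {
  if (n_fibers < 0 || n_debris < 0) stopf("object counts must be >= 0")
  check_positive(fill_factor, "fill_factor")
  structure(list(n_fibers = as.integer(n_fibers),
                 n_debris = as.integer(n_debris),
                 fiber_area_lnorm = fiber_area_lnorm,
                 fiber_aspect = fiber_aspect,
                 debris_area_lnorm = debris_area_lnorm,
                 debris_aspect_lnorm = debris_aspect_lnorm,
                 fill_factor = fill_factor, strain = strain,
                 treatment = treatment, organ_id = organ_id,
                 seed = as.integer(seed)),
            class = "fiber_table_spec")
}

#' Generate a synthetic fiber table
#'
#' @param spec a [fiber_table_spec()].
#' @return data frame with columns `object_id`, `area_um2`, `feret_min_um`,
#'   `feret_max_um`, `aspect`, `strain`, `treatment`, `organ_id` and the
#'   hidden `true_class` (`"fiber"` / `"debris"`) kept for testing.
#' @export
generate_fiber_table <- function(spec) {
  stopifnot(inherits(spec, "fiber_table_spec"))
  with_seed(spec$seed, {
    mk <- function(n, area_ln, aspect_fun, cls) {
      if (n == 0) return(NULL)
      area <- rlnorm(n, area_ln[["meanlog"]], area_ln[["sdlog"]])
      aspect <- aspect_fun(n)
      fmax <- sqrt(area * aspect / spec$fill_factor)
      fmin <- fmax / aspect
      data.frame(area_um2 = area, feret_min_um = fmin, feret_max_um = fmax,
                 aspect = aspect, true_class = cls)
    }
    fib <- mk(spec$n_fibers, spec$fiber_area_lnorm,
              function(n) spec$fiber_aspect[["shift"]] +
                rlnorm(n, spec$fiber_aspect[["meanlog"]],
                       spec$fiber_aspect[["sdlog"]]), "fiber")
    deb <- mk(spec$n_debris, spec$debris_area_lnorm,
              function(n) 1 + rlnorm(n, spec$debris_aspect_lnorm[["meanlog"]],
                                     spec$debris_aspect_lnorm[["sdlog"]]),
              "debris")
    out <- rbind(fib, deb)
    if (is.null(out))
      out <- data.frame(area_um2 = numeric(0), feret_min_um = numeric(0),
                        feret_max_um = numeric(0), aspect = numeric(0),
                        true_class = character(0))
    out <- cbind(data.frame(object_id = seq_len(nrow(out))), out)
    out$strain <- rep(spec$strain, nrow(out))
    out$treatment <- rep(spec$treatment, nrow(out))
    out$organ_id <- rep(spec$organ_id, nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Generate a multi-organ fiber cohort
#'
#' One fiber table per organ, with a log-normal organ-level size effect
#' (shared shift of the area distribution) capturing between-organ
#' biological variability.
#'
#' @param groups data frame with columns `strain`, `treatment`, `n_organs`.
#' @param base_spec template [fiber_table_spec()] shared by all organs.
#' @param organ_scale_sd log-sd of the per-organ area scale effect.
#' @param seed RNG seed.
#' @return combined data frame across organs, with `organ_id` filled in.
#' @export
generate_fiber_cohort <- function(groups, base_spec = fiber_table_spec(),
                                  organ_scale_sd = 0.15, seed = 1L) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("strain", "treatment", "n_organs") %in% names(groups)))
  with_seed(seed, {
    out <- list()
    for (g in seq_len(nrow(groups))) {
      for (o in seq_len(groups$n_organs[g])) {
        sp <- base_spec
        sp$strain <- groups$strain[g]
        sp$treatment <- groups$treatment[g]
        sp$organ_id <- sprintf("%s-%s-organ%02d", gsub("/", "", sp$strain),
                               sp$treatment, o)
        sp$fiber_area_lnorm[["meanlog"]] <-
          base_spec$fiber_area_lnorm[["meanlog"]] + rnorm(1, 0, organ_scale_sd)
        sp$seed <- sample.int(2^30, 1)
        out[[length(out) + 1]] <- generate_fiber_table(sp)
      }
    }
    do.call(rbind, out)
  })
}
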