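# Micropipette-aspiration mechanics: the elastic half-space model that maps
# an aspirated-length measurement to an apparent elastic modulus,
#
#   E_app = 3 a dp / (2 pi L Phi(a, w)),
#
# where a is the pipette inner radius, dp the aspiration pressure magnitude,
# L the aspirated tissue length and Phi a dimensionless wall-geometry
# correction depending only on w/a (w = pipette wall thickness). Pressures
# are stored as positive magnitudes throughout (the protocol applies suction,
# nominally 70 kPa through an ~80 um pipette).

#' Pipette wall function
#'
#' Dimensionless correction for pipette wall geometry. The default
#' (`"product"`) reading is
#' \deqn{\Phi = \tfrac{1}{2}\,(1 + w/a)\,(1 + w/(2a))\,\ln(8a/w),}
#' which takes values around 2.1-2.6 over realistic wall-to-radius ratios,
#' consistent with published half-space wall corrections. Because the
#' source typography is ambiguous, an alternative `"ratio"` reading
#' \eqn{\Phi = (1 + w/(2a))\ln(8a/w) / (2(1 + w/a))} is also provided.
#'
#' @param a pipette inner radius (um), > 0.
#' @param w pipette wall thickness (um), 0 < w < 8a (else the logarithm
#'   argument drops below 1 and the model is invalid).
#' @param form which algebraic reading to evaluate.
#' @return numeric vector of wall-function values; scale-invariant in
#'   (a, w) -> (ka, kw).
#' @export
wall_function <- function(a, w, form = c("product", "ratio")) {
  form <- match.arg(form)
  if (any(!is.finite(a)) || any(!is.finite(w)) || any(a <= 0) || any(w <= 0))
    stopf("wall_function requires a > 0 and w > 0")
  if (any(w >= 8 * a))
    stopf("wall_function requires w < 8a (log(8a/w) must be positive)")
  r <- w / a
  lg <- log(8 / r)
  if (form == "product") 0.5 * (1 + r) * (1 + r / 2) * lg
  else (1 + r / 2) * lg / (2 * (1 + r))
}

#' Apparent elastic modulus from aspiration measurements
#'
#' Applies the half-space model to a table of aspiration records. Units:
#' with `a_um` and `L_um` in micrometres (any shared length unit works) and
#' `dp_kpa` in kPa, the modulus is in kPa.
#'
#' @param measurements data frame with columns `a_um`, `w_um`, `dp_kpa`,
#'   `L_um` and optionally `position` or `height_fraction` (positions are
#'   filled in from height fractions via [assign_position()] when absent),
#'   plus any metadata columns which are carried through.
#' @param phi_form passed to [wall_function()].
#' @return the input data frame with added columns `phi` and `E_app_kpa`
#'   (and `position` when derivable).
#' @export
apparent_modulus <- function(measurements, phi_form = c("product", "ratio")) {
  phi_form <- match.arg(phi_form)
  m <- as.data.frame(measurements)
  for (col in c("a_um", "w_um", "dp_kpa", "L_um")) {
    if (is.null(m[[col]])) stopf("missing column '%s'", col)
    check_positive(m[[col]], col)
  }
  m$phi <- wall_function(m$a_um, m$w_um, phi_form)
  m$E_app_kpa <- 3 * m$a_um * m$dp_kpa / (2 * pi * m$L_um * m$phi)
  if (is.null(m$position) && !is.null(m$height_fraction))
    m$position <- assign_position(m$height_fraction)
  m
}

#' Assign an anatomic position label from a height fraction
#'
#' Height runs from 0 at the pelvic floor to 1 at the cord. The bands are
#' base: bottom 25 percent; midportion: 40-60 percent; tip: top 25 percent.
#' Fractions between bands return `NA` ("unassigned", excluded from
#' regional analysis).
#'
#' @param height_fraction numeric in \[0, 1\].
#' @return character vector with values `"base"`, `"midportion"`, `"tip"`
#'   or `NA`.
#' @export
assign_position <- function(height_fraction) {
  h <- as.numeric(height_fraction)
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1))
    stopf("height fractions must lie in [0, 1]")
  out <- rep(NA_character_, length(h))
  out[h <= 0.25] <- "base"
  out[h >= 0.40 & h <= 0.60] <- "midportion"
  out[h >= 0.75] <- "tip"
  out
}

#' Regional and gestational comparison of apparent moduli
#'
#' Runs, per (strain, day), a one-way ANOVA of `E_app_kpa` across the three
#' anatomic positions, and per (strain, position) an independent two-sample
#' comparison across gestational days (pooled t by default, Mann-Whitney
#' optionally). After each ANOVA, Tukey-style pairwise contrasts are
#' reported descriptively; the ANOVA p is the headline. Cells with fewer
#' than 2 observations are skipped with a warning.
#'
#' @param results data frame from [apparent_modulus()] with columns
#'   `E_app_kpa`, `strain`, `day`, `position`.
#' @param day_test `"t"` or `"mann_whitney"` for the day contrast.
#' @param alpha significance level.
#' @return list with `region_tests` (named [group_comparison()] list, one
#'   per strain:day), `day_tests` (one per strain:position), and `pairwise`
#'   (data frame of Tukey-style contrasts).
#' @export
regional_analysis <- function(results, day_test = c("t", "mann_whitney"),
                              alpha = 0.05) {
  day_test <- match.arg(day_test)
  r <- as.data.frame(results)
  needed <- c("E_app_kpa", "strain", "day", "position")
  miss <- setdiff(needed, names(r))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  r <- r[!is.na(r$position), , drop = FALSE]
  region_tests <- list()
  pairwise <- list()
  for (s in unique(r$strain)) for (d in unique(r$day[r$strain == s])) {
    sub <- r[r$strain == s & r$day == d, ]
    groups <- split(sub$E_app_kpa, sub$position)
    groups <- groups[lengths(groups) >= 2]
    key <- paste(s, d, sep = ":")
    if (length(groups) < 2) {
      warnf("regional contrast %s skipped: fewer than 2 positions with n >= 2", key)
      next
    }
    aov1 <- one_way_anova(groups, alpha)
    region_tests[[key]] <- aov1
    # Tukey HSD, reported descriptively
    k <- length(groups)
    ni <- lengths(groups); mi <- vapply(groups, mean, 0)
    dfw <- sum(ni) - k
    msw <- attr(aov1, "ss_within") / dfw
    nm <- names(groups)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      diff <- mi[i] - mi[j]
      se <- sqrt(msw / 2 * (1 / ni[i] + 1 / ni[j]))
      q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
      ptk <- if (is.finite(q)) ptukey(q, k, dfw, lower.tail = FALSE)
             else 0
      pairwise[[length(pairwise) + 1]] <- data.frame(
        strain = s, day = d, contrast = paste(nm[i], "-", nm[j]),
        diff_kpa = diff, p_tukey = ptk)
    }
  }
  day_tests <- list()
  for (s in unique(r$strain)) for (p in unique(r$position[r$strain == s])) {
    sub <- r[r$strain == s & r$position == p, ]
    if (length(unique(sub$day)) < 2) next   # nothing to contrast
    days <- split(sub$E_app_kpa, sub$day)
    days <- days[lengths(days) >= 2]
    key <- paste(s, p, sep = ":")
    if (length(days) != 2) {
      warnf("day contrast %s skipped: needs exactly 2 days with n >= 2", key)
      next
    }
    day_tests[[key]] <- if (day_test == "t")
      two_sample_t(days[[1]], days[[2]], alpha = alpha)
    else mann_whitney_u(days[[1]], days[[2]], alpha = alpha)
  }
  list(region_tests = region_tests, day_tests = day_tests,
       pairwise = if (length(pairwise)) do.call(rbind, pairwise) else NULL)
}
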