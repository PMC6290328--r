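# Muscle-fiber morphometry: object measurement from labeled 2D masks
# (area, feret diameters via rotating calipers, aspect = feret max / min),
# the background-exclusion rule (objects with aspect < 5 or area < 500 um^2
# deleted), and log-scale group summaries.

#' Measure objects in a labeled 2D mask
#'
#' Per labeled object: area = pixel count x pixel area; feret minimum and
#' maximum diameters by rotating calipers over the convex hull of the
#' object's pixel outlines (each pixel treated as a unit square, so a
#' 10 x 100 px rectangle measures 10 um across, not 9); aspect =
#' feret max / feret min. Single-pixel objects are degenerate and report
#' feret min = feret max = the pixel size (aspect 1).
#'
#' @param label_mat integer matrix; 0 = background, positive values label
#'   objects.
#' @param pixel_um pixel size in um (> 0).
#' @return data frame with columns `object_id`, `area_um2`, `feret_min_um`,
#'   `feret_max_um`, `aspect`; empty mask gives an empty frame.
#' @export
measure_objects <- function(label_mat, pixel_um = 1) {
  check_positive(pixel_um, "pixel_um")
  if (!is.matrix(label_mat)) stopf("'label_mat' must be a matrix")
  ids <- sort(unique(label_mat[label_mat > 0]))
  rows <- lapply(ids, function(id) {
    px <- which(label_mat == id, arr.ind = TRUE)
    n <- nrow(px)
    area <- n * pixel_um^2
    if (n == 1) {
      return(data.frame(object_id = id, area_um2 = area,
                        feret_min_um = pixel_um, feret_max_um = pixel_um,
                        aspect = 1))
    }
    # corner cloud: 4 corners of each pixel square
    ys <- c(px[, 1] - 0.5, px[, 1] - 0.5, px[, 1] + 0.5, px[, 1] + 0.5)
    xs <- c(px[, 2] - 0.5, px[, 2] + 0.5, px[, 2] - 0.5, px[, 2] + 0.5)
    pts <- unique(cbind(xs, ys))
    hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
    f <- feret_calipers(hull)
    data.frame(object_id = id, area_um2 = area,
               feret_min_um = f[["min"]] * pixel_um,
               feret_max_um = f[["max"]] * pixel_um,
               aspect = f[["max"]] / f[["min"]])
  })
  if (!length(rows))
    return(data.frame(object_id = integer(0), area_um2 = numeric(0),
                      feret_min_um = numeric(0), feret_max_um = numeric(0),
                      aspect = numeric(0)))
  do.call(rbind, rows)
}

## rotating calipers on a convex hull (h x 2 matrix of x,y):
## feret max = hull diameter; feret min = minimal width over edge directions
feret_calipers <- function(hull) {
  h <- nrow(hull)
  dmax <- 0
  for (i in seq_len(h - 1)) {
    d <- sqrt((hull[(i + 1):h, 1] - hull[i, 1])^2 +
                (hull[(i + 1):h, 2] - hull[i, 2])^2)
    dmax <- max(dmax, d)
  }
  wmin <- Inf
  for (i in seq_len(h)) {
    j <- if (i == h) 1 else i + 1
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    # distance of all hull points from the edge's supporting line
    w <- max(abs((hull[, 1] - hull[i, 1]) * e[2] -
                   (hull[, 2] - hull[i, 2]) * e[1]) / len)
    wmin <- min(wmin, w)
  }
  if (!is.finite(wmin) || wmin == 0) wmin <- dmax  # collinear degenerate
  c(min = wmin, max = dmax)
}

#' Apply the background-exclusion rule to fiber records
#'
#' Deletes non-fiber background objects: by default a record is deleted if
#' its aspect is below `aspect_min` (5) or its area below `area_min`
#' (500 um^2); the cutoffs are strict "less than", so boundary records at
#' exactly 500 / 5 are retained. Deletion is record-wise and
#' order-preserving, and the operation is idempotent.
#'
#' @param records data frame with columns `area_um2` and `aspect`.
#' @param area_min,aspect_min deletion cutoffs.
#' @param rule `"either"` (default: delete when either criterion fails,
#'   i.e. retain aspect >= 5 AND area >= 500) or `"both"` (delete only when
#'   both fail). The source wording pairs "aspect and area" with "< 5 and
#'   500" respectively; `"either"` is the adopted reading.
#' @return the retained records, with attribute `"n_deleted"`.
#' @export
filter_fibers <- function(records, area_min = 500, aspect_min = 5,
                          rule = c("either", "both")) {
  rule <- match.arg(rule)
  r <- as.data.frame(records)
  for (col in c("area_um2", "aspect"))
    if (is.null(r[[col]])) stopf("missing column '%s'", col)
  fail_area <- r$area_um2 < area_min
  fail_aspect <- r$aspect < aspect_min
  del <- if (rule == "either") fail_area | fail_aspect else fail_area & fail_aspect
  out <- r[!del, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_deleted") <- sum(del)
  out
}

#' Group summary of fiber morphology on a log scale
#'
#' Per group (e.g. strain/treatment): geometric mean and geometric sd of
#' area, length (feret max) and aspect, plus cross-group one-way ANOVAs of
#' each log-scale endpoint at `alpha`. If an `organ_id` column is present
#' and `unit = "organ"` (default), records are first aggregated to
#' per-organ geometric means so the organ is the unit of analysis.
#'
#' @param records filtered fiber records with grouping columns.
#' @param group_cols columns defining the groups.
#' @param unit `"organ"` (aggregate per organ when organ_id is present) or
#'   `"object"`.
#' @param alpha significance level.
#' @return list: `summary` (per-group data frame), `tests` (named list of
#'   [group_comparison()] per endpoint, `NULL` when untestable), and
#'   `any_significant`.
#' @export
summarize_morphology <- function(records, group_cols = c("strain", "treatment"),
                                 unit = c("organ", "object"), alpha = 0.05) {
  unit <- match.arg(unit)
  r <- as.data.frame(records)
  group_cols <- intersect(group_cols, names(r))
  if (!length(group_cols)) stopf("no grouping columns found")
  endpoints <- c(area = "area_um2", length = "feret_max_um", aspect = "aspect")
  for (col in endpoints)
    if (is.null(r[[col]])) stopf("missing column '%s'", col)
  if (any(unlist(r[endpoints]) <= 0)) stopf("morphometry values must be positive")
  key <- interaction(r[group_cols], drop = TRUE, sep = "/")
  if (unit == "organ" && !is.null(r$organ_id) && !all(is.na(r$organ_id))) {
    agg <- stats::aggregate(r[endpoints],
                            by = c(r[group_cols], list(organ_id = r$organ_id)),
                            FUN = function(v) exp(mean(log(v))))
    r <- agg
    key <- interaction(r[group_cols], drop = TRUE, sep = "/")
  }
  gsummary <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- r[key == k, ]
    row <- data.frame(group = k, n = nrow(sub))
    for (ep in names(endpoints)) {
      lv <- log(sub[[endpoints[[ep]]]])
      row[[paste0(ep, "_gmean")]] <- exp(mean(lv))
      row[[paste0(ep, "_gsd")]] <- if (nrow(sub) > 1) exp(stats::sd(lv)) else NA_real_
    }
    row
  }))
  usable <- levels(key)[table(key)[levels(key)] >= 2]
  tests <- NULL
  if (length(usable) >= 2) {
    tests <- lapply(endpoints, function(col) {
      groups <- split(log(r[[col]]), key)[usable]
      one_way_anova(groups, alpha)
    })
    names(tests) <- names(endpoints)
  }
  any_sig <- !is.null(tests) &&
    any(vapply(tests, function(t) isTRUE(t$significant), TRUE))
  list(summary = gsummary, tests = tests, any_significant = any_sig)
}
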