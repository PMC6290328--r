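# Multi-channel 3D volume container and TIFF-backed I/O.
#
# In-memory convention: every channel is a 3D array indexed (z, y, x);
# voxel spacing is stored per axis in micrometres, also ordered (z, y, x).
# On disk a volume is a multi-page grayscale TIFF (pages ordered
# channel-major: all z planes of channel 1, then channel 2, ...) plus a
# sidecar JSON ("<path>.json") recording shape, spacing, channel roles and
# sample metadata; the same JSON is embedded as the TIFF ImageDescription so
# the file is self-describing even without the sidecar.

CHANNEL_ROLES <- c("nuclear", "ar", "myosin", "other")

#' Construct a multi-channel confocal volume
#'
#' @param channels list of 3D numeric arrays, all of one shape, indexed
#'   (z, y, x).
#' @param roles character vector, one of `"nuclear"`, `"ar"`, `"myosin"`,
#'   `"other"` per channel. Exactly one channel must carry the nuclear role
#'   (it drives segmentation) and at most one the AR role.
#' @param spacing_um voxel spacing in micrometres, `(z, y, x)`, all positive.
#' @param metadata named list of sample metadata (specimen_id, strain, day).
#' @return object of class `confocal_volume`.
#' @export
confocal_volume <- function(channels, roles, spacing_um,
                            metadata = list()) {
  if (!is.list(channels) || !length(channels))
    stopf("'channels' must be a non-empty list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stopf("every channel must be a 3D array (z, y, x)")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stopf("all channels must share one grid shape")
  roles <- match.arg(tolower(roles), CHANNEL_ROLES, several.ok = TRUE)
  if (length(roles) != length(channels))
    stopf("role map names %d channels but volume has %d",
          length(roles), length(channels))
  if (sum(roles == "nuclear") != 1)
    stopf("exactly one channel must carry the nuclear role")
  if (sum(roles == "ar") > 1)
    stopf("at most one channel may carry the AR role")
  spacing_um <- as_zyx(spacing_um, "spacing_um")
  check_positive(spacing_um, "spacing_um")
  names(channels) <- make.unique(roles)
  structure(list(channels = channels, roles = roles,
                 spacing_um = spacing_um, metadata = metadata),
            class = "confocal_volume")
}

#' @export
print.confocal_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<confocal_volume> %d x %d x %d voxels (z,y,x), %d channel(s): %s\n",
              d[1], d[2], d[3], length(x$channels),
              paste(x$roles, collapse = ", ")))
  cat(sprintf("  spacing (um): z=%.3g y=%.3g x=%.3g\n",
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  invisible(x)
}

#' Extract a channel by role
#'
#' @param volume a [confocal_volume()].
#' @param role channel role to fetch.
#' @return 3D array, or error if the role is absent.
#' @export
get_channel <- function(volume, role) {
  i <- which(volume$roles == role)
  if (!length(i)) stopf("volume has no channel with role '%s'", role)
  volume$channels[[i[1]]]
}

volume_shape <- function(volume) dim(volume$channels[[1]])

#' Normalize a raw channel array to the (z, y, x) convention
#'
#' Permutes an array whose axes arrive in a stated order into the package's
#' canonical (z, y, x) layout. Normalizing an already-normalized array is a
#' no-op, so the operation is involution-safe.
#'
#' @param arr 3D array.
#' @param axis_order character such as `"zyx"` or `"xyz"` naming the current
#'   axis order of `arr`.
#' @return array in (z, y, x) order.
#' @export
normalize_axes <- function(arr, axis_order = "zyx") {
  ax <- strsplit(axis_order, "")[[1]]
  if (length(ax) != 3 || !setequal(ax, c("z", "y", "x")))
    stopf("axis_order must be a permutation of 'zyx'")
  aperm(arr, match(c("z", "y", "x"), ax))
}

volume_sidecar <- function(volume, dtype) {
  list(shape = as.integer(volume_shape(volume)),
       n_channels = length(volume$channels),
       channels = volume$roles,
       spacing_um = unname(volume$spacing_um),
       dtype = dtype,
       metadata = volume$metadata)
}

#' Write a confocal volume to a multi-page TIFF with sidecar JSON
#'
#' Integer-valued non-negative data below 2^16 is stored losslessly as
#' uint16; anything else as float32.
#'
#' @param volume a [confocal_volume()].
#' @param path output TIFF path; a sidecar `"<path>.json"` is written too.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "confocal_volume"))
  integerish <- all(vapply(volume$channels, function(ch)
    all(ch >= 0 & ch <= 65535 & ch == round(ch)), TRUE))
  dtype <- if (integerish) "uint16" else "float32"
  pages <- list()
  for (ch in volume$channels) {
    nz <- dim(ch)[1]
    for (z in seq_len(nz)) pages[[length(pages) + 1]] <- ch[z, , ]
  }
  meta <- volume_sidecar(volume, dtype)
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  write_tiff(path, pages, dtype = dtype, description = as.character(js))
  writeLines(as.character(js), paste0(path, ".json"))
  invisible(path)
}

#' Read a confocal volume from TIFF
#'
#' Metadata is taken from the sidecar JSON (or the embedded
#' ImageDescription); explicit arguments override it. Reading fails hard if
#' no voxel spacing can be found, because every physical-unit kernel
#' downstream is undefined without it.
#'
#' @param path TIFF file path.
#' @param roles optional channel-role mapping overriding the metadata.
#' @param spacing_um optional `(z, y, x)` spacing override in micrometres.
#' @param metadata optional metadata override.
#' @param axis_order axis order of the pages' in-plane data, kept for
#'   completeness; files written by [write_volume()] are always `"zyx"`.
#' @return a [confocal_volume()].
#' @export
read_volume <- function(path, roles = NULL, spacing_um = NULL,
                        metadata = NULL, axis_order = "zyx") {
  tf <- read_tiff(path)
  side <- NULL
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    side <- jsonlite::fromJSON(paste(readLines(sidecar_path, warn = FALSE),
                                     collapse = "\n"))
  } else if (!is.null(tf$description)) {
    side <- tryCatch(jsonlite::fromJSON(tf$description),
                     error = function(e) NULL)
  }
  roles <- roles %||% side$channels
  spacing_um <- spacing_um %||% side$spacing_um
  metadata <- metadata %||% (side$metadata %||% list())
  if (is.null(spacing_um))
    stopf("no voxel spacing in metadata for '%s' and no override given; %s",
          path, "physical-unit processing is undefined without it")
  if (is.null(roles))
    stopf("no channel-role mapping in metadata for '%s' and none given", path)
  npages <- length(tf$pages)
  nch <- length(roles)
  if (npages %% nch != 0)
    stopf("role map names %d channels but file has %d pages (%.2f per channel %s)",
          nch, npages, npages / nch, "is not an integer")
  nz <- npages %/% nch
  ny <- nrow(tf$pages[[1]]); nx <- ncol(tf$pages[[1]])
  channels <- vector("list", nch)
  for (c in seq_len(nch)) {
    arr <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) arr[z, , ] <- tf$pages[[(c - 1) * nz + z]]
    channels[[c]] <- normalize_axes(arr, axis_order)
  }
  confocal_volume(channels, roles, spacing_um, as.list(metadata))
}

#' Write an integer label volume as uint16 TIFF
#'
#' @param labels 3D integer array (z, y, x); logical arrays are stored as 0/1.
#' @param path output path.
#' @param spacing_um `(z, y, x)` spacing recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path, spacing_um) {
  spacing_um <- as_zyx(spacing_um, "spacing_um")
  arr <- labels
  storage.mode(arr) <- "double"
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
  js <- jsonlite::toJSON(list(shape = as.integer(dim(arr)), n_channels = 1L,
                              channels = "labels",
                              spacing_um = unname(spacing_um),
                              dtype = "uint16"),
                         auto_unbox = TRUE)
  write_tiff(path, pages, dtype = "uint16", description = as.character(js))
  writeLines(as.character(js), paste0(path, ".json"))
  invisible(path)
}

#' Read an integer label volume written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return list with `labels` (3D integer array) and `spacing_um`.
#' @export
read_label_tiff <- function(path) {
  tf <- read_tiff(path)
  side <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  nz <- length(tf$pages)
  ny <- nrow(tf$pages[[1]]); nx <- ncol(tf$pages[[1]])
  arr <- array(0L, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- as.integer(tf$pages[[z]])
  list(labels = arr, spacing_um = side$spacing_um)
}
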