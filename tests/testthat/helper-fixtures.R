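# Shared fixture builders. All fixtures are generated in code; nothing is
# stored on disk.

# tiny phantom that renders in well under a second
small_phantom_spec <- function(seed = 1L, ...) {
  volume_phantom_spec(shape = c(z = 24, y = 48, x = 48),
                      spacing_um = c(z = 2, y = 1.5, x = 1.5),
                      organ_semiaxes_um = c(z = 18, y = 14, x = 14),
                      cord_length_um = 8, cord_radius_um = 4,
                      seed = seed, ...)
}

# solid axis-aligned ellipsoid volume in zero background, with margins
# wider than the default closing element so border truncation cannot bite
ellipsoid_volume <- function(shape = c(36, 72, 72), spacing = c(2, 1.5, 1.5),
                             semi = c(12, 16, 16), value = 1000) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  zc <- (seq_len(nz) - 0.5) * spacing[1]
  yc <- (seq_len(ny) - 0.5) * spacing[2]
  xc <- (seq_len(nx) - 0.5) * spacing[3]
  ctr <- c(mean(range(zc)), mean(range(yc)), mean(range(xc)))
  rho2 <- outer(outer(((zc - ctr[1]) / semi[1])^2,
                      ((yc - ctr[2]) / semi[2])^2, "+"),
                ((xc - ctr[3]) / semi[3])^2, "+")
  inside <- rho2 <= 1
  arr <- array(0, shape)
  arr[inside] <- value
  list(arr = arr, inside = inside, spacing = spacing)
}

make_volume <- function(arr, spacing = c(2, 1.5, 1.5), ar = NULL,
                        metadata = list(specimen_id = "fix")) {
  chans <- list(arr)
  roles <- "nuclear"
  if (!is.null(ar)) { chans <- c(chans, list(ar)); roles <- c(roles, "ar") }
  confocal_volume(chans, roles, spacing, metadata)
}

# count 26-connected components of a logical array
n_components <- function(mask) {
  lab <- array(cpp_label3d_for_tests(mask), dim(mask))
  max(lab)
}

cpp_label3d_for_tests <- function(mask) {
  getFromNamespace("cpp_label3d", "gubquant")(as.logical(mask), dim(mask))
}
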