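#' @useDynLib gubquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm rpois var pf pt pnorm ptukey
#' @importFrom grDevices chull
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Convert a physical kernel size to an odd voxel count
#'
#' Used for the median-filter kernel: the nearest odd integer to
#' `size_um / spacing_um`, never below 1, with half-integer ties rounded up
#' (so a kernel spanning exactly two voxels maps to 3).
#'
#' @param size_um physical extent in micrometres (vectorised).
#' @param spacing_um voxel spacing in micrometres on the same axes.
#' @return integer vector of odd kernel sizes.
#' @export
um_to_odd_voxels <- function(size_um, spacing_um) {
  k <- size_um / spacing_um
  m <- floor((k - 1) / 2 + 0.5)
  as.integer(pmax(1L, 2 * m + 1))
}

#' Convert a physical radius to voxels
#'
#' Nearest integer, never below 1 (half-integers round up).
#'
#' @inheritParams um_to_odd_voxels
#' @return integer vector of voxel radii.
#' @export
um_to_voxels <- function(size_um, spacing_um) {
  as.integer(pmax(1L, floor(size_um / spacing_um + 0.5)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!all(is.finite(x)) || any(x <= 0))
    stopf("'%s' must be strictly positive and finite", name)
  invisible(x)
}

## normalize a (z, y, x) numeric triple, accepting named or positional input
as_zyx <- function(x, name) {
  if (length(x) != 3) stopf("'%s' must have length 3 (z, y, x)", name)
  if (!is.null(names(x)) && all(c("z", "y", "x") %in% names(x)))
    x <- x[c("z", "y", "x")]
  x <- unname(as.numeric(x))
  names(x) <- c("z", "y", "x")
  x
}
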