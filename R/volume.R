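#' Voxel volume container
#'
#' A `voxel_volume` wraps a 3D grid of scalars or `{0,1}` labels together
#' with its per-axis voxel spacing in nanometres and, for subregions, the
#' offset of the subregion within its parent volume. The array axis order is
#' `(z, y, x)`: `data[z, , ]` is one slice, and slice index `z` increases
#' with physical z (the slicing/cutting direction of the stack).
#'
#' @param data 3D array, axis order (z, y, x). Logical arrays are stored as
#'   integer 0/1.
#' @param spacing_nm numeric length-3 voxel edge lengths in nm, order
#'   (z, y, x); all entries must be strictly positive. A single number is
#'   recycled to all three axes.
#' @param origin_vx integer length-3 offset (0-based, (z, y, x)) of this
#'   volume within its parent; `c(0, 0, 0)` for a full volume.
#' @return An object of class `voxel_volume` with fields `data`,
#'   `spacing_nm`, `origin_vx`.
#' @examples
#' v <- voxel_volume(array(0L, c(4, 4, 4)), spacing_nm = 150)
#' dim(v$data)
#' @export
voxel_volume <- function(data, spacing_nm, origin_vx = c(0L, 0L, 0L)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_ctx("`data` must be a 3D array with axis order (z, y, x)")
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  }
  if (length(spacing_nm) == 1L) spacing_nm <- rep(spacing_nm, 3L)
  spacing_nm <- as.numeric(spacing_nm)
  if (length(spacing_nm) != 3L || any(!is.finite(spacing_nm)) ||
      any(spacing_nm <= 0))
    stop_ctx("`spacing_nm` must be 3 strictly positive voxel edge lengths")
  origin_vx <- as.integer(origin_vx)
  if (length(origin_vx) != 3L || any(is.na(origin_vx)) || any(origin_vx < 0))
    stop_ctx("`origin_vx` must be 3 nonnegative integers")
  structure(
    list(data = data, spacing_nm = spacing_nm, origin_vx = origin_vx),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d (z,y,x) @ %g x %g x %g nm\n",
              d[1], d[2], d[3],
              x$spacing_nm[1], x$spacing_nm[2], x$spacing_nm[3]))
  if (any(x$origin_vx != 0L))
    cat(sprintf("  origin (z,y,x): %d %d %d\n",
                x$origin_vx[1], x$origin_vx[2], x$origin_vx[3]))
  if (is_binary_volume(x)) {
    cat(sprintf("  binary, %d foreground voxels (%.2f%%)\n",
                sum(x$data != 0), 100 * mean(x$data != 0)))
  }
  invisible(x)
}

#' Test whether a volume contains only 0/1 labels
#'
#' @param volume a [voxel_volume()].
#' @return `TRUE` when every voxel is 0 or 1.
#' @export
is_binary_volume <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  all(volume$data == 0 | volume$data == 1)
}

assert_binary <- function(volume, what = "volume") {
  if (!inherits(volume, "voxel_volume"))
    stop_ctx(what, " must be a voxel_volume")
  if (!is_binary_volume(volume))
    stop_ctx(what, " must be binary (labels in {0, 1})")
  invisible(volume)
}

#' Physical volume of a voxel grid in cubic millimetres
#'
#' The analysed subregion volume `V` entering the numerical density
#' `N_V = N_SCL / V`: the product of grid extent times spacing per axis,
#' converted from nm^3 to mm^3. A 1000^3-voxel region at 150 nm isotropic
#' spacing gives (150 um)^3 = 3.375e-3 mm^3.
#'
#' @param volume a [voxel_volume()], or a length-3 integer grid size (z, y, x)
#'   when `spacing_nm` is supplied.
#' @param spacing_nm per-axis spacing in nm; ignored when `volume` is a
#'   `voxel_volume`.
#' @return Volume in mm^3.
#' @examples
#' volume_mm3(c(1000, 1000, 1000), spacing_nm = 150)  # 0.003375
#' @export
volume_mm3 <- function(volume, spacing_nm = NULL) {
  if (inherits(volume, "voxel_volume")) {
    dims <- dim(volume$data)
    spacing_nm <- volume$spacing_nm
  } else {
    dims <- as.numeric(volume)
    if (length(spacing_nm) == 1L) spacing_nm <- rep(spacing_nm, 3L)
    if (is.null(spacing_nm) || length(spacing_nm) != 3L)
      stop_ctx("spacing_nm required when volume is given as a grid size")
  }
  prod(dims * spacing_nm) / 1e18
}
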