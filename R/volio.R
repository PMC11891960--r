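# Segmentation postprocessing: isotropic resampling, hole filling,
# largest-component selection and subregion extraction.

#' Output grid size after isotropic resampling
#'
#' Per axis, `floor(extent_nm / target_nm)` where the extent is grid size
#' times spacing. A 7500-slice stack at 80 nm z-spacing resampled to 150 nm
#' yields 4000 output slices.
#'
#' @param dims length-3 grid size (z, y, x).
#' @param spacing_nm per-axis spacing in nm.
#' @param target_nm target isotropic spacing in nm.
#' @return Integer length-3 output grid size.
#' @export
resampled_dims <- function(dims, spacing_nm, target_nm) {
  if (length(spacing_nm) == 1L) spacing_nm <- rep(spacing_nm, 3L)
  stopifnot(target_nm > 0)
  out <- as.integer(floor(as.numeric(dims) * spacing_nm / target_nm))
  if (any(out < 1L)) stop_ctx("target spacing coarser than the volume extent")
  out
}

#' Resample a volume to an isotropic voxel size
#'
#' Linear (trilinear) interpolation for grayscale data, nearest-neighbour
#' for binary masks. Output voxel `i` (0-based) samples the physical
#' position `(i + 0.5) * target_nm` per axis; the output grid size is
#' `floor(extent_nm / target_nm)` per axis. Linear interpolation on a binary
#' volume would produce values outside {0, 1} and is rejected unless
#' `threshold = TRUE`, which re-binarizes at 0.5.
#'
#' @param volume a [voxel_volume()].
#' @param target_nm target isotropic spacing in nm (> 0).
#' @param mode `"linear"` or `"nearest"`.
#' @param threshold apply a 0.5 threshold after linear interpolation
#'   (required to use `mode = "linear"` on binary input).
#' @return A [voxel_volume()] with isotropic spacing `target_nm`.
#' @export
resample_isotropic <- function(volume, target_nm,
                               mode = c("linear", "nearest"),
                               threshold = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"))
  mode <- match.arg(mode)
  if (!is.numeric(target_nm) || length(target_nm) != 1L || target_nm <= 0)
    stop_ctx("`target_nm` must be a single positive length")
  binary <- is_binary_volume(volume)
  if (mode == "linear" && binary && !threshold)
    stop_ctx("linear interpolation of a binary volume creates values ",
             "outside {0,1}; use mode = \"nearest\" or threshold = TRUE")
  dims <- dim(volume$data)
  sp <- volume$spacing_nm
  if (all(sp == target_nm)) return(volume)  # identity
  odims <- resampled_dims(dims, sp, target_nm)
  # continuous input index of each output voxel centre, per axis
  ci <- lapply(1:3, function(a) {
    ((seq_len(odims[a]) - 0.5) * target_nm) / sp[a] - 0.5
  })
  out <- if (mode == "nearest") {
    idx <- lapply(1:3, function(a)
      pmin(pmax(round(ci[[a]]), 0), dims[a] - 1) + 1)
    volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(ci[[a]]), 0), dims[a] - 1))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, dims[a] - 1))
    fr <- lapply(1:3, function(a) pmin(pmax(ci[[a]] - lo[[a]], 0), 1))
    acc <- array(0, odims)
    dat <- volume$data
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      iz <- if (cz == 0) lo[[1]] else hi[[1]]
      iy <- if (cy == 0) lo[[2]] else hi[[2]]
      ix <- if (cx == 0) lo[[3]] else hi[[3]]
      wz <- if (cz == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wx <- if (cx == 0) 1 - fr[[3]] else fr[[3]]
      w <- outer(outer(wz, wy), wx)
      acc <- acc + w * dat[iz + 1, iy + 1, ix + 1, drop = FALSE]
    }
    acc
  }
  if (mode == "linear" && threshold) {
    out <- array(as.integer(out >= 0.5), odims)
  }
  if (binary && mode == "nearest") storage.mode(out) <- "integer"
  voxel_volume(out, rep(target_nm, 3L), volume$origin_vx)
}

#' Fill enclosed background cavities in a binary volume
#'
#' Background components that do not reach the volume border are relabelled
#' foreground; foreground voxels are never modified. Connectivity follows
#' the complementary digital-topology pairing: foreground 26 (3D) / 8 (2D),
#' background 6 (3D) / 4 (2D). `per_slice_2d` fills each z-slice
#' independently, which also closes z-through tunnels whose per-slice
#' profiles are enclosed.
#'
#' @param volume a binary [voxel_volume()].
#' @param mode `"full_3d"` (default) or `"per_slice_2d"`.
#' @return A [voxel_volume()] with cavities filled. Idempotent.
#' @export
fill_holes <- function(volume, mode = c("full_3d", "per_slice_2d")) {
  assert_binary(volume)
  mode <- match.arg(mode)
  data <- volume$data
  dims <- dim(data)
  if (mode == "full_3d") {
    bg <- as.integer(data == 0)
    lab <- array(.cc_label_3d(bg, dims, 6L), dims)
    border <- unique(c(lab[c(1, dims[1]), , ], lab[, c(1, dims[2]), ],
                       lab[, , c(1, dims[3])]))
    border <- border[border > 0]
    fill <- lab > 0 & !(lab %in% border)
    data[fill] <- 1L
  } else {
    for (z in seq_len(dims[1])) {
      sl <- data[z, , ]
      lab <- .cc_label_2d(matrix(as.integer(sl == 0), dims[2], dims[3]), 4L)
      border <- unique(c(lab[c(1, dims[2]), ], lab[, c(1, dims[3])]))
      border <- border[border > 0]
      sl[lab > 0 & !(lab %in% border)] <- 1L
      data[z, , ] <- sl
    }
  }
  voxel_volume(data, volume$spacing_nm, volume$origin_vx)
}

#' Keep only the largest connected foreground component
#'
#' Mirrors the postprocessing step of removing unconnected parts of a
#' network label in 3D so that exactly one connected segmentation remains.
#' Size ties are broken deterministically in favour of the component
#' containing the lexicographically smallest (z, y, x) voxel.
#'
#' @param volume a binary [voxel_volume()] with at least one foreground
#'   voxel.
#' @param connectivity foreground connectivity: 6, 18 or 26 (default).
#' @return A [voxel_volume()] containing a single component. Idempotent.
#' @export
largest_component <- function(volume, connectivity = 26L) {
  assert_binary(volume)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_ctx("connectivity must be 6, 18 or 26")
  data <- volume$data
  dims <- dim(data)
  lab <- .cc_label_3d(as.integer(data != 0), dims, as.integer(connectivity))
  if (!any(lab > 0)) stop_ctx("volume has no foreground voxels")
  sizes <- tabulate(lab)
  winners <- which(sizes == max(sizes))
  keep <- if (length(winners) == 1L) winners else {
    # tie: component with the smallest (z, y, x) voxel, z most significant
    idx <- which(lab %in% winners)
    co <- arrayInd(idx, dims)
    ord <- order(co[, 1], co[, 2], co[, 3])
    lab[idx[ord[1]]]
  }
  out <- array(as.integer(array(lab, dims) == keep), dims)
  voxel_volume(out, volume$spacing_nm, volume$origin_vx)
}

#' Extract a rectangular subregion of a volume
#'
#' @param volume a [voxel_volume()].
#' @param origin_vx 0-based (z, y, x) corner of the subregion.
#' @param size_vx (z, y, x) subregion size in voxels.
#' @return A [voxel_volume()] whose `origin_vx` records the position within
#'   the parent (accumulating over nested extractions); its physical volume
#'   is available via [volume_mm3()].
#' @export
extract_subregion <- function(volume, origin_vx, size_vx) {
  stopifnot(inherits(volume, "voxel_volume"))
  origin_vx <- as.integer(origin_vx)
  size_vx <- as.integer(size_vx)
  dims <- dim(volume$data)
  if (length(origin_vx) != 3L || length(size_vx) != 3L ||
      any(is.na(origin_vx)) || any(is.na(size_vx)))
    stop_ctx("origin_vx and size_vx must be length-3 integer vectors")
  if (any(size_vx < 1L)) stop_ctx("size_vx must be positive")
  if (any(origin_vx < 0L) || any(origin_vx + size_vx > dims))
    stop_ctx("requested subregion [",
             paste(origin_vx, collapse = ","), "] + [",
             paste(size_vx, collapse = ","),
             "] exceeds the volume extent [",
             paste(dims, collapse = ","), "]")
  sub <- volume$data[origin_vx[1] + seq_len(size_vx[1]),
                     origin_vx[2] + seq_len(size_vx[2]),
                     origin_vx[3] + seq_len(size_vx[3]), drop = FALSE]
  voxel_volume(sub, volume$spacing_nm, volume$origin_vx + origin_vx)
}
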