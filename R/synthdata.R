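# Synthetic capillary-network phantoms with exactly known topology. A
# lattice of short tube segments around square "tissue pillars" emulates
# the sheet-like architecture of the alveolar capillary network; the sheet
# is tilted against the slicing axis so that no capillary loop lies within
# a single slice plane.

#' Planar lattice network with known topology
#'
#' Builds a rows-by-cols grid graph embedded in 3D physical coordinates.
#' The sheet initially spans the (x, y) plane and is tilted about the
#' x-axis by `orientation_deg`, so loop planes are transverse to the z
#' (slicing) axis. Edge ids enumerate all horizontal edges first (row by
#' row), then all vertical edges (column by column within each row).
#'
#' @param rows,cols lattice size, both at least 2.
#' @param pitch_nm lattice pitch (node-to-node distance) in nm; default
#'   1800 nm = 12 voxels at 150 nm spacing.
#' @param removed_edges integer edge ids to delete; the removal set must
#'   not disconnect the graph.
#' @param orientation_deg tilt of the sheet about the x-axis in degrees.
#' @param jitter_nm per-axis uniform node jitter in `[-jitter_nm, jitter_nm]`;
#'   tubes stay straight (piecewise-linear between jittered nodes).
#' @param seed RNG seed for the jitter; required when `jitter_nm > 0`.
#' @return A list with `spec` (class `network_spec`: `node_positions_nm`
#'   (n x 3, columns z, y, x), `edges` (m x 2 node indices), `lattice_dims`,
#'   `orientation_deg`, `spacing_nm` pitch) and `truth` (class
#'   `phantom_truth`: `n_nodes_true`, `n_edges_true`, `n_components_true`,
#'   `n_cycles_true`, empty event lists).
#' @examples
#' net <- make_lattice_network(5, 5)
#' net$truth$n_cycles_true  # 16 = (5-1)*(5-1)
#' @export
make_lattice_network <- function(rows, cols, pitch_nm = 1800,
                                 removed_edges = integer(),
                                 orientation_deg = 30, jitter_nm = 0,
                                 seed = NULL) {
  if (!is_count(rows) || !is_count(cols) || rows < 2 || cols < 2)
    stop_ctx("rows and cols must be integers >= 2")
  if (!is.numeric(pitch_nm) || pitch_nm <= 0)
    stop_ctx("pitch_nm must be > 0")
  rows <- as.integer(rows); cols <- as.integer(cols)
  nid <- function(i, j) (i - 1L) * cols + j
  # horizontal edges first, then vertical
  eh <- do.call(rbind, lapply(seq_len(rows), function(i)
    cbind(nid(i, seq_len(cols - 1L)), nid(i, seq_len(cols - 1L) + 1L))))
  ev <- do.call(rbind, lapply(seq_len(rows - 1L), function(i)
    cbind(nid(i, seq_len(cols)), nid(i + 1L, seq_len(cols)))))
  edges <- rbind(eh, ev)
  n_nodes <- rows * cols
  removed_edges <- as.integer(removed_edges)
  if (length(removed_edges)) {
    if (anyDuplicated(removed_edges) || any(removed_edges < 1L) ||
        any(removed_edges > nrow(edges)))
      stop_ctx("removed_edges must be distinct edge ids in 1..",
               nrow(edges))
    kept <- edges[-removed_edges, , drop = FALSE]
    if (count_components_edges(n_nodes, kept) != 1L)
      stop_ctx("removing these edges disconnects the lattice")
    edges <- kept
  }
  ij <- cbind(rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
  x <- (ij[, 2] - 1) * pitch_nm
  y0 <- (ij[, 1] - 1) * pitch_nm
  th <- orientation_deg * pi / 180
  pos <- cbind(z = y0 * sin(th), y = y0 * cos(th), x = x)
  if (jitter_nm > 0) {
    pos <- pos + with_seed(seed, matrix(runif(3 * n_nodes, -jitter_nm,
                                              jitter_nm), ncol = 3))
  }
  spec <- structure(list(node_positions_nm = pos, edges = edges,
                         lattice_dims = c(rows, cols),
                         orientation_deg = orientation_deg,
                         spacing_nm = pitch_nm),
                    class = "network_spec")
  truth <- phantom_truth(n_nodes, nrow(edges), 1L)
  list(spec = spec, truth = truth)
}

phantom_truth <- function(n_nodes, n_edges, n_components,
                          occlusion_events = list(), cavity_events = list()) {
  n_cycles <- n_edges - n_nodes + n_components
  if (n_cycles < 0) stop_ctx("inconsistent ground truth: negative cycle rank")
  structure(list(n_nodes_true = as.integer(n_nodes),
                 n_edges_true = as.integer(n_edges),
                 n_components_true = as.integer(n_components),
                 n_cycles_true = as.integer(n_cycles),
                 occlusion_events = occlusion_events,
                 cavity_events = cavity_events),
            class = "phantom_truth")
}

count_components_edges <- function(n_nodes, edges) {
  parent <- uf_new(n_nodes)
  if (nrow(edges)) for (k in seq_len(nrow(edges)))
    parent <- uf_union(parent, edges[k, 1], edges[k, 2])
  length(unique(vapply(seq_len(n_nodes), function(i) uf_find(parent, i),
                       integer(1))))
}

#' Voxelize a tube network into a binary volume
#'
#' Foreground is the union of capsules (cylinders with spherical caps) of
#' radius `radius_vx` voxels around every edge segment, plus balls at
#' isolated nodes. The network is translated so it sits strictly inside the
#' volume; geometry that would touch a volume face is rejected, because a
#' clipped tube would corrupt the phantom's known topology.
#'
#' @param spec a `network_spec` (see [make_lattice_network()]).
#' @param radius_vx tube radius in voxels (a few voxels, per the stated
#'   imaging scale).
#' @param volume_shape (z, y, x) grid size; `NULL` auto-sizes to the network
#'   extent plus a margin of `radius_vx + 3` voxels.
#' @param spacing_nm isotropic voxel spacing in nm (default 150).
#' @return A list with `volume` (binary [voxel_volume()]), `truth`
#'   (`phantom_truth`, passed through), `spec_vox` (node coordinates in
#'   0-based voxel units after placement, plus the edge table) and
#'   `radius_vx`.
#' @export
voxelize_network <- function(spec, radius_vx = 2, volume_shape = NULL,
                             spacing_nm = c(150, 150, 150)) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(spacing_nm) == 1L) spacing_nm <- rep(spacing_nm, 3L)
  if (length(unique(spacing_nm)) != 1L)
    stop_ctx("voxelize_network assumes isotropic spacing")
  if (!is.numeric(radius_vx) || radius_vx <= 0)
    stop_ctx("radius_vx must be > 0")
  n_nodes <- nrow(spec$node_positions_nm)
  if (n_nodes == 0L) {
    if (is.null(volume_shape))
      stop_ctx("volume_shape is required for an empty network")
    vol <- voxel_volume(array(0L, volume_shape), spacing_nm)
    return(list(volume = vol, truth = phantom_truth(0L, 0L, 0L),
                spec_vox = list(nodes = spec$node_positions_nm,
                                edges = spec$edges),
                radius_vx = radius_vx))
  }
  v <- sweep(spec$node_positions_nm, 2, spacing_nm, "/")  # voxel units
  margin <- radius_vx + 3
  ext <- apply(v, 2, function(c) diff(range(c)))
  if (is.null(volume_shape)) {
    volume_shape <- as.integer(ceiling(ext + 2 * margin) + 1)
    shift <- margin - apply(v, 2, min)
  } else {
    volume_shape <- as.integer(volume_shape)
    shift <- (volume_shape - 1 - ext) / 2 - apply(v, 2, min)
  }
  v <- sweep(v, 2, shift, "+")
  # strict-interior check: capsule surfaces must clear the boundary faces
  lo <- apply(v, 2, min) - radius_vx
  hi <- apply(v, 2, max) + radius_vx
  if (any(floor(lo) < 1) || any(ceiling(hi) > volume_shape - 2))
    stop_ctx("network (with radius margin) does not fit strictly inside ",
             "the volume; enlarge volume_shape")
  data <- array(FALSE, volume_shape)
  edges <- spec$edges
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
  for (k in seq_len(nrow(edges))) {
    data <- rasterize_capsule(data, v[edges[k, 1], ], v[edges[k, 2], ],
                              radius_vx)
  }
  lonely <- setdiff(seq_len(n_nodes), unique(as.vector(edges)))
  for (i in lonely) data <- rasterize_capsule(data, v[i, ], v[i, ], radius_vx)
  vol <- voxel_volume(array(as.integer(data), volume_shape), spacing_nm)
  list(volume = vol, truth = spec_truth(spec),
       spec_vox = list(nodes = v, edges = edges), radius_vx = radius_vx)
}

spec_truth <- function(spec) {
  n <- nrow(spec$node_positions_nm)
  e <- if (is.null(spec$edges)) 0L else nrow(spec$edges)
  comps <- count_components_edges(max(n, 1L),
                                  if (e) spec$edges else matrix(integer(),
                                                                ncol = 2))
  # isolated nodes each count as a component already via union-find
  phantom_truth(n, e, comps)
}

# set voxels within `r` of segment a-b (voxel units, 0-based centres)
rasterize_capsule <- function(data, a, b, r) {
  dims <- dim(data)
  lo <- pmax(floor(pmin(a, b) - r), 0)
  hi <- pmin(ceiling(pmax(a, b) + r), dims - 1)
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  g <- expand.grid(z = zz, y = yy, x = xx)
  p <- as.matrix(g)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- rowSums(sweep(p, 2, a)^2)
  } else {
    t <- pmin(pmax((sweep(p, 2, a) %*% ab) / len2, 0), 1)
    proj <- sweep(t %*% t(ab), 2, a, "+")
    d2 <- rowSums((p - proj)^2)
  }
  inside <- d2 <= r^2
  if (any(inside)) {
    idx <- p[inside, , drop = FALSE] + 1
    data[cbind(idx[, 1], idx[, 2], idx[, 3])] <- TRUE
  }
  data
}

#' Degrade a phantom segmentation with known topological effect
#'
#' Emulates the segmentation failure modes of capillary-network imaging:
#' blood cells that fully block a capillary (a mid-edge occlusion deleting
#' the tube lumen), enclosed cavities (fillable by [fill_holes()]), and
#' salt noise (isolated foreground specks removable by
#' [largest_component()]). Each occlusion's expected effect on the cycle
#' rank is recorded: deleting a cycle edge lowers the rank by one, deleting
#' a bridge edge leaves it unchanged (the stump is pruned away).
#'
#' @param phantom result of [voxelize_network()] (needed for edge
#'   geometry), or a bare binary [voxel_volume()] when only cavities/noise
#'   are requested.
#' @param occlusions list of `list(edge = id, fraction = f)`: a span of
#'   length `f * edge length`, centred at the edge midpoint, is carved out
#'   across the full tube cross-section.
#' @param cavities list of `list(center = c(z, y, x) 0-based voxel,
#'   radius_vx = r)`; each ball must be strictly enclosed by foreground
#'   (otherwise hole filling could not restore it, and the call errors).
#' @param salt_noise_rate fraction of eligible background voxels (those
#'   with no foreground 26-neighbour) turned into isolated specks.
#' @param seed RNG seed for the salt noise.
#' @return A list with `volume` (degraded binary volume) and `events`
#'   (occlusion log with `cycle_edge`/`expected_rank_delta`, cavity log,
#'   `n_salt`). With empty event lists the volume is returned unchanged.
#' @export
degrade_segmentation <- function(phantom, occlusions = list(),
                                 cavities = list(), salt_noise_rate = 0,
                                 seed = NULL) {
  if (inherits(phantom, "voxel_volume")) {
    volume <- phantom
    spec_vox <- NULL
    radius_vx <- NULL
  } else {
    volume <- phantom$volume
    spec_vox <- phantom$spec_vox
    radius_vx <- phantom$radius_vx
  }
  assert_binary(volume)
  data <- volume$data
  dims <- dim(data)
  events <- list(occlusions = list(), cavities = list(), n_salt = 0L)

  if (length(occlusions)) {
    if (is.null(spec_vox))
      stop_ctx("occlusions need edge geometry: pass the voxelize_network ",
               "result, not a bare volume")
    edges <- spec_vox$edges
    live <- rep(TRUE, nrow(edges))
    for (oc in occlusions) {
      eid <- oc$edge
      frac <- oc$fraction %||% 0.3
      if (!is_count(eid) || eid < 1 || eid > nrow(edges))
        stop_ctx("occlusion edge id out of range")
      a <- spec_vox$nodes[edges[eid, 1], ]
      b <- spec_vox$nodes[edges[eid, 2], ]
      mid <- (a + b) / 2
      half <- (b - a) * frac / 2
      mask <- array(FALSE, dims)
      mask <- rasterize_capsule(mask, mid - half, mid + half,
                                radius_vx + 1.5)
      data[mask] <- 0L
      # does the remaining graph still connect the edge's endpoints?
      live[eid] <- FALSE
      rest <- edges[live, , drop = FALSE]
      cyc <- count_components_edges(nrow(spec_vox$nodes), rest) ==
        count_components_edges(nrow(spec_vox$nodes),
                               edges[live | seq_along(live) == eid, ,
                                     drop = FALSE])
      events$occlusions[[length(events$occlusions) + 1L]] <-
        list(edge = eid, fraction = frac, cycle_edge = cyc,
             expected_rank_delta = if (cyc) -1L else 0L)
    }
  }

  for (cv in cavities) {
    ctr <- as.numeric(cv$center)
    r <- cv$radius_vx
    ball <- array(FALSE, dims)
    ball <- rasterize_capsule(ball, ctr, ctr, r)
    # enclosure shell: hole filling uses 6-connected background, so the
    # ball plus all face-neighbours of its voxels must be foreground
    shell <- array(FALSE, dims)
    shell <- rasterize_capsule(shell, ctr, ctr, r + 1)
    if (any(data[shell] == 0))
      stop_ctx("cavity at (", paste(round(ctr), collapse = ","),
               ") is not fully enclosed by foreground")
    data[ball] <- 0L
    events$cavities[[length(events$cavities) + 1L]] <-
      list(center = ctr, radius_vx = r, n_voxels = sum(ball))
  }

  if (salt_noise_rate > 0) {
    nb <- .neighbor_count_26(as.integer(data != 0), dims)
    eligible <- which(data == 0 & array(nb, dims) == 0)
    n_flip <- floor(length(eligible) * salt_noise_rate)
    if (n_flip > 0) {
      flip <- with_seed(seed, sample(eligible, n_flip))
      data[flip] <- 1L
      events$n_salt <- as.integer(n_flip)
    }
  }

  list(volume = voxel_volume(data, volume$spacing_nm, volume$origin_vx),
       events = events)
}

#' Write a phantom with its ground-truth sidecar
#'
#' Saves the binary volume (format chosen by extension, see
#' [write_stack()]) and a plain-JSON ground-truth file
#' `<path>.truth.json` holding the true node/edge/cycle counts and any
#' degradation events, for recovery tests.
#'
#' @param phantom result of [voxelize_network()].
#' @param path volume output path (`.tif`/`.mha`/`.mhd`).
#' @param events optional event log from [degrade_segmentation()].
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path, events = NULL) {
  write_stack(phantom$volume, path)
  truth <- phantom$truth
  sidecar <- c(unclass(truth), list(events = events))
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
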