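# Independent oracles and fixture builders, kept deliberately separate from
# the package's own algorithms: graph quantities go through igraph,
# pixel/voxel quantities through explicit brute-force loops.

# cycle rank E - V + C with the component count taken from igraph
oracle_cycle_rank <- function(n_nodes, edges) {
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::ecount(g) - igraph::vcount(g) + igraph::components(g)$no
}

oracle_components <- function(n_nodes, edges) {
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# cycle rank of a voxel set under 26-adjacency (for clean curve skeletons)
oracle_voxel_rank <- function(coords) {
  n <- nrow(coords)
  edges <- matrix(integer(), ncol = 2)
  if (n > 1) {
    pairs <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (max(abs(coords[i, ] - coords[j, ])) <= 1)
        pairs[[length(pairs) + 1]] <- c(i, j)
    }
    if (length(pairs)) edges <- do.call(rbind, pairs)
  }
  oracle_cycle_rank(n, edges)
}

# brute-force per-pixel confusion counts
oracle_confusion <- function(gt, seg) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    if (gt[i, j] == 1 && seg[i, j] == 1) tp <- tp + 1L
    else if (gt[i, j] == 0 && seg[i, j] == 0) tn <- tn + 1L
    else if (gt[i, j] == 0 && seg[i, j] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(n_tp = tp, n_tn = tn, n_fp = fp, n_fn = fn)
}

# brute-force 2D flood fill from the border over background (4-connected);
# anything unreached is an enclosed hole
oracle_fill_2d <- function(slice) {
  ny <- nrow(slice); nx <- ncol(slice)
  reach <- matrix(FALSE, ny, nx)
  queue <- list()
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if ((y == 1 || y == ny || x == 1 || x == nx) && slice[y, x] == 0)
      queue[[length(queue) + 1]] <- c(y, x)
  }
  for (q in queue) reach[q[1], q[2]] <- TRUE
  while (length(queue)) {
    c0 <- queue[[1]]; queue <- queue[-1]
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      y <- c0[1] + o[1]; x <- c0[2] + o[2]
      if (y >= 1 && y <= ny && x >= 1 && x <= nx &&
          slice[y, x] == 0 && !reach[y, x]) {
        reach[y, x] <- TRUE
        queue[[length(queue) + 1]] <- c(y, x)
      }
    }
  }
  out <- slice
  out[slice == 0 & !reach] <- 1L
  out
}

# exact membership test against the capsule definition, written
# independently of the package rasterizer
oracle_capsule_count <- function(a, b, r, dims) {
  count <- 0L
  ab <- b - a
  len2 <- sum(ab^2)
  for (z in 0:(dims[1] - 1)) for (y in 0:(dims[2] - 1))
    for (x in 0:(dims[3] - 1)) {
      p <- c(z, y, x)
      t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
      if (sum((p - a - t * ab)^2) <= r^2) count <- count + 1L
    }
  count
}

# random connected multigraph with chi <= 0 as a spatial_graph
random_connected_multigraph <- function(n_nodes, n_extra, allow_loops = TRUE) {
  nodes <- data.frame(id = seq_len(n_nodes),
                      z = runif(n_nodes) * 1000,
                      y = runif(n_nodes) * 1000,
                      x = runif(n_nodes) * 1000)
  from <- to <- integer()
  for (i in seq_len(n_nodes)[-1]) {  # random spanning tree
    from <- c(from, sample.int(i - 1L, 1L))
    to <- c(to, i)
  }
  for (k in seq_len(n_extra)) {
    a <- sample.int(n_nodes, 1L)
    b <- sample.int(n_nodes, 1L)
    if (!allow_loops && a == b) b <- if (a == n_nodes) 1L else a + 1L
    from <- c(from, a); to <- c(to, b)
  }
  edges <- data.frame(id = seq_along(from), from = from, to = to,
                      length_nm = runif(length(from), 1, 100))
  spatial_graph(nodes, edges)
}

# hand-built network_spec for non-lattice geometries
make_spec <- function(positions_nm, edges) {
  structure(list(node_positions_nm = positions_nm,
                 edges = matrix(as.integer(edges), ncol = 2),
                 lattice_dims = NULL, orientation_deg = 0,
                 spacing_nm = NA_real_),
            class = "network_spec")
}

# count skeleton endpoint voxels (foreground with exactly one 26-neighbour)
endpoint_count <- function(skeleton) {
  nb <- acntopo:::.neighbor_count_26(as.integer(skeleton$data != 0),
                                     dim(skeleton$data))
  sum(skeleton$data == 1 & array(nb, dim(skeleton$data)) == 1)
}

# full phantom -> loop-count pipeline used across tests
recover_graph <- function(volume, dissolve = TRUE) {
  g <- prune_degree_one(build_graph(skeletonize(largest_component(
    fill_holes(volume)))))
  if (dissolve) g <- dissolve_degree_two(g)
  g
}
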