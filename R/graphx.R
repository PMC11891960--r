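# Spatial-graph extraction from binary volumes: topology-preserving
# thinning, branch-point clustering and edge tracing, then pruning of
# dead-end (degree-1) nodes. Nodes represent branching points of the
# network, edges represent capillary segments.

#' Construct a spatial graph
#'
#' An undirected multigraph (parallel edges and self-loops allowed) whose
#' nodes carry 3D physical coordinates in nm and whose edges optionally
#' carry their ordered voxel path and physical length.
#'
#' @param nodes data.frame with columns `id` (integer), `z`, `y`, `x`
#'   (nm).
#' @param edges data.frame with columns `id`, `from`, `to`, `length_nm`;
#'   endpoints must exist in `nodes` and lengths must be positive.
#' @param paths optional list (one entry per edge row) of 0-based voxel
#'   coordinate matrices (columns z, y, x).
#' @param spacing_nm voxel spacing the paths refer to, if any.
#' @return An object of class `spatial_graph`.
#' @export
spatial_graph <- function(nodes, edges, paths = NULL, spacing_nm = NULL) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!all(c("id", "z", "y", "x") %in% names(nodes)))
    stop_ctx("nodes need columns id, z, y, x")
  if (!all(c("id", "from", "to", "length_nm") %in% names(edges)))
    stop_ctx("edges need columns id, from, to, length_nm")
  if (anyDuplicated(nodes$id)) stop_ctx("duplicate node ids")
  if (nrow(edges)) {
    if (!all(edges$from %in% nodes$id) || !all(edges$to %in% nodes$id))
      stop_ctx("edge endpoint references a missing node")
    if (any(edges$length_nm <= 0))
      stop_ctx("edge lengths must be > 0 (coincident-node artifact?)")
  }
  if (!is.null(paths) && length(paths) != nrow(edges))
    stop_ctx("paths must have one entry per edge")
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 spacing_nm = spacing_nm),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges (chi = %d)\n",
              nrow(x$nodes), nrow(x$edges),
              nrow(x$nodes) - nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a spatial graph
#'
#' A self-loop contributes 2 to its node's degree.
#'
#' @param graph a [spatial_graph()].
#' @return Named integer vector, one entry per node id.
#' @export
sg_degree <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  ends <- c(graph$edges$from, graph$edges$to)
  deg <- table(factor(ends, levels = graph$nodes$id))
  out <- as.integer(deg)
  names(out) <- graph$nodes$id
  out
}

#' Number of connected components of a spatial graph
#'
#' @param graph a [spatial_graph()].
#' @return Integer component count (isolated nodes count).
#' @export
sg_components <- function(graph) {
  n <- nrow(graph$nodes)
  if (n == 0L) return(0L)
  idx <- seq_len(n)
  names(idx) <- graph$nodes$id
  parent <- uf_new(n)
  e <- graph$edges
  for (k in seq_len(nrow(e)))
    parent <- uf_union(parent, idx[as.character(e$from[k])],
                       idx[as.character(e$to[k])])
  length(unique(vapply(idx, function(i) uf_find(parent, i), integer(1))))
}

#' Thin a binary volume to a one-voxel-wide curve skeleton
#'
#' Distance-ordered homotopic thinning: simple points (whose removal
#' provably preserves local topology under the 26/6 foreground/background
#' connectivity pairing) are deleted in increasing chamfer-distance order;
#' curve endpoints are retained. The skeleton therefore has the same number
#' of connected components and the same cycle rank as the input object.
#'
#' @param volume a binary [voxel_volume()] with at least one foreground
#'   voxel; a warning is issued if the foreground has more than one
#'   26-connected component (run [largest_component()] first).
#' @param spur_length_vx short endpoint spurs (thinning artifacts at
#'   junctions and ring corners) up to this length are eroded after
#'   thinning. Deleting a leaf voxel is always homotopic, so this never
#'   changes component count or cycle rank; it does shorten genuine
#'   dead-end branches by up to this many voxels. Default 3, comparable
#'   to the tube radii the method targets.
#' @return A binary [voxel_volume()] containing the skeleton.
#' @export
skeletonize <- function(volume, spur_length_vx = 3L) {
  assert_binary(volume)
  data <- volume$data
  dims <- dim(data)
  if (!any(data != 0)) stop_ctx("cannot skeletonize an empty volume")
  lab <- .cc_label_3d(as.integer(data != 0), dims, 26L)
  if (max(lab) > 1L)
    warning("foreground has ", max(lab), " 26-connected components; ",
            "skeletonizing all of them", call. = FALSE)
  sk <- array(as.integer(data != 0), dims)
  # thinning and spur erosion alternate to a fixpoint: eroding a spur can
  # expose junction voxels that are now simple (removing them dissolves
  # zero-area triangle artifacts), so re-thinning after erosion keeps the
  # skeleton minimal
  passes_used <- 0L
  repeat {
    sk <- array(.thin_3d(sk, dims), dims)
    if (passes_used >= spur_length_vx) break
    passes_used <- passes_used + 1L
    nb <- array(.neighbor_count_26(sk, dims), dims)
    tips <- which(sk == 1L & nb == 1L)
    if (!length(tips)) break
    # sequential removal, re-checking the neighbour count so the last
    # two voxels of a tiny component are never both deleted
    removed <- 0L
    co <- arrayInd(tips, dims)
    for (t in seq_along(tips)) {
      z <- co[t, 1]; y <- co[t, 2]; x <- co[t, 3]
      zz <- max(1, z - 1):min(dims[1], z + 1)
      yy <- max(1, y - 1):min(dims[2], y + 1)
      xx <- max(1, x - 1):min(dims[3], x + 1)
      if (sum(sk[zz, yy, xx]) == 2L) {  # itself + exactly one neighbour
        sk[z, y, x] <- 0L
        removed <- removed + 1L
      }
    }
    if (removed == 0L) break
  }
  voxel_volume(sk, volume$spacing_nm, volume$origin_vx)
}

#' Build a spatial graph from a curve skeleton
#'
#' Skeleton voxels are classified by their number of foreground
#' 26-neighbours: 1 = endpoint, 2 = path, >= 3 = branch. 26-connected
#' clusters of branch voxels merge into a single node at the cluster
#' centroid; endpoints become nodes; edges are traced along path voxels
#' between nodes. An isolated closed curve (no branch or endpoint voxels)
#' becomes one node carrying one self-loop, so its cycle survives in the
#' graph (chi = 0).
#'
#' Node positions are physical: `(origin_vx + voxel index) * spacing_nm`.
#'
#' @param skeleton a binary [voxel_volume()] holding a 1-voxel-wide
#'   skeleton (see [skeletonize()]).
#' @param spacing_nm override for the skeleton's spacing.
#' @return A [spatial_graph()] with voxel paths attached to every edge.
#' @export
build_graph <- function(skeleton, spacing_nm = NULL) {
  assert_binary(skeleton)
  if (is.null(spacing_nm)) spacing_nm <- skeleton$spacing_nm
  dims <- dim(skeleton$data)
  origin <- skeleton$origin_vx
  vox <- which(skeleton$data != 0)
  n_fg <- length(vox)
  if (n_fg == 0L)
    return(spatial_graph(
      data.frame(id = integer(), z = numeric(), y = numeric(),
                 x = numeric()),
      data.frame(id = integer(), from = integer(), to = integer(),
                 length_nm = numeric()),
      paths = list(), spacing_nm = spacing_nm))
  co <- arrayInd(vox, dims)  # 1-based (z, y, x)

  # adjacency lists over foreground voxels (indices into `vox`)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  all_src <- vector("list", nrow(offs))
  all_dst <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nz <- co[, 1] + offs$dz[k]; ny <- co[, 2] + offs$dy[k]
    nx <- co[, 3] + offs$dx[k]
    ok <- nz >= 1 & nz <= dims[1] & ny >= 1 & ny <= dims[2] &
      nx >= 1 & nx <= dims[3]
    lin <- nz[ok] + dims[1] * (ny[ok] - 1 + dims[2] * (nx[ok] - 1))
    m <- match(lin, vox)
    hit <- !is.na(m)
    all_src[[k]] <- which(ok)[hit]
    all_dst[[k]] <- m[hit]
  }
  src <- unlist(all_src); dst <- unlist(all_dst)
  ord <- order(src, dst)
  adj <- unname(split(dst[ord], factor(src[ord], levels = seq_len(n_fg))))
  cnt <- lengths(adj)

  is_branch <- cnt >= 3L
  is_path <- cnt == 2L
  node_of <- integer(n_fg)
  node_pos <- list()  # node id -> (z,y,x) 0-based voxel coords (possibly
                      # fractional centroid)
  next_id <- 0L

  # branch clusters: BFS over branch voxels, seeds in ascending voxel order
  seen <- logical(n_fg)
  for (i in seq_len(n_fg)) {
    if (!is_branch[i] || seen[i]) next
    next_id <- next_id + 1L
    comp <- integer()
    queue <- i
    seen[i] <- TRUE
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, c0)
      nbs <- adj[[c0]]
      nbs <- nbs[is_branch[nbs] & !seen[nbs]]
      seen[nbs] <- TRUE
      queue <- c(queue, nbs)
    }
    node_of[comp] <- next_id
    node_pos[[next_id]] <- colMeans(co[comp, , drop = FALSE]) - 1
  }
  for (i in seq_len(n_fg)) {
    if (cnt[i] > 1L) next  # endpoints (1) and isolated voxels (0)
    next_id <- next_id + 1L
    node_of[i] <- next_id
    node_pos[[next_id]] <- co[i, ] - 1
  }

  visited <- logical(n_fg)
  edge_from <- integer(); edge_to <- integer(); paths <- list()
  direct_seen <- character()

  trace_path <- function(v, w) {
    # returns indices of the voxel path v..node, or NULL on malformed input
    path <- c(v, w)
    visited[w] <<- TRUE
    prev <- v; cur <- w
    repeat {
      nbs <- adj[[cur]]
      nxt <- nbs[nbs != prev]
      if (length(nxt) != 1L) {
        bad <- co[cur, ] - 1
        stop_ctx("skeleton is not one voxel wide at (z,y,x) = (",
                 paste(bad, collapse = ","), ")")
      }
      path <- c(path, nxt)
      if (node_of[nxt] > 0L) return(path)
      visited[nxt] <<- TRUE
      prev <- cur; cur <- nxt
    }
  }

  add_edge <- function(path_idx) {
    edge_from <<- c(edge_from, node_of[path_idx[1]])
    edge_to <<- c(edge_to, node_of[path_idx[length(path_idx)]])
    paths[[length(paths) + 1L]] <<- co[path_idx, , drop = FALSE] - 1
  }

  node_voxels <- which(node_of > 0L)
  for (v in node_voxels) {
    for (w in adj[[v]]) {
      if (node_of[w] > 0L) {
        if (node_of[w] == node_of[v]) next  # intra-cluster adjacency
        key <- paste(sort(c(node_of[v], node_of[w])), collapse = "-")
        if (key %in% direct_seen) next  # one junction contact = one edge
        direct_seen <- c(direct_seen, key)
        add_edge(c(v, w))
      } else if (is_path[w] && !visited[w]) {
        add_edge(trace_path(v, w))
      }
    }
  }

  # isolated closed curves: pure path components never visited
  for (i in seq_len(n_fg)) {
    if (!is_path[i] || visited[i] || node_of[i] > 0L) next
    next_id <- next_id + 1L
    node_of[i] <- next_id
    node_pos[[next_id]] <- co[i, ] - 1
    visited[i] <- TRUE
    add_edge(trace_path(i, adj[[i]][1]))
  }

  pos <- do.call(rbind, node_pos)
  nodes <- data.frame(
    id = seq_len(next_id),
    z = (pos[, 1] + origin[1]) * spacing_nm[1],
    y = (pos[, 2] + origin[2]) * spacing_nm[2],
    x = (pos[, 3] + origin[3]) * spacing_nm[3])
  lengths_nm <- vapply(paths, function(p) {
    steps <- diff(p)
    sum(sqrt((steps[, 1] * spacing_nm[1])^2 +
             (steps[, 2] * spacing_nm[2])^2 +
             (steps[, 3] * spacing_nm[3])^2))
  }, numeric(1))
  edges <- data.frame(id = seq_along(edge_from), from = edge_from,
                      to = edge_to, length_nm = lengths_nm)
  spatial_graph(nodes, edges, paths, spacing_nm)
}

#' Delete dead-end (degree-1) nodes and their edges
#'
#' Dead-end branches of a capillary graph are not biologically meaningful
#' (they stem from boundary truncation or shrinking artifacts) and would
#' corrupt the Euler number. By default the deletion is iterated to a
#' fixpoint — a single pass exposes new dead-ends — and isolated
#' (degree-0) nodes are removed afterwards. A self-loop counts 2 towards
#' its node's degree, so pure cycles are never pruned.
#'
#' @param graph a [spatial_graph()].
#' @param to_fixpoint iterate until no degree-1 node remains (default);
#'   `FALSE` performs exactly one deletion pass.
#' @return The pruned [spatial_graph()], with the number of passes in
#'   `attr(, "iterations")`.
#' @export
prune_degree_one <- function(graph, to_fixpoint = TRUE) {
  stopifnot(inherits(graph, "spatial_graph"))
  iterations <- 0L
  repeat {
    deg <- sg_degree(graph)
    dead <- as.integer(names(deg)[deg == 1L])
    if (!length(dead)) break
    iterations <- iterations + 1L
    keep_e <- !(graph$edges$from %in% dead | graph$edges$to %in% dead)
    graph$edges <- graph$edges[keep_e, , drop = FALSE]
    if (!is.null(graph$paths)) graph$paths <- graph$paths[keep_e]
    graph$nodes <- graph$nodes[!(graph$nodes$id %in% dead), , drop = FALSE]
    if (!to_fixpoint) break
  }
  if (to_fixpoint) {
    deg <- sg_degree(graph)
    iso <- as.integer(names(deg)[deg == 0L])
    graph$nodes <- graph$nodes[!(graph$nodes$id %in% iso), , drop = FALSE]
  }
  attr(graph, "iterations") <- iterations
  graph
}

#' Dissolve degree-2 chain nodes
#'
#' Merges the two edges incident to each degree-2 node so that remaining
#' nodes are true branch points. Both node and edge count drop by one per
#' dissolution, leaving the Euler number unchanged. Nodes whose degree-2
#' status comes from a self-loop are kept, so a pure cycle component
#' reduces to one node with one self-loop rather than vanishing.
#'
#' @param graph a [spatial_graph()].
#' @return The dissolved [spatial_graph()].
#' @export
dissolve_degree_two <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  repeat {
    deg <- sg_degree(graph)
    e <- graph$edges
    selfloop_nodes <- unique(e$from[e$from == e$to])
    cand <- as.integer(names(deg)[deg == 2L])
    cand <- setdiff(cand, selfloop_nodes)
    if (!length(cand)) break
    n <- cand[1]
    inc <- which(e$from == n | e$to == n)
    stopifnot(length(inc) == 2L)
    e1 <- inc[1]; e2 <- inc[2]
    a <- if (e$from[e1] == n) e$to[e1] else e$from[e1]
    b <- if (e$from[e2] == n) e$to[e2] else e$from[e2]
    p1 <- if (!is.null(graph$paths)) graph$paths[[e1]] else NULL
    p2 <- if (!is.null(graph$paths)) graph$paths[[e2]] else NULL
    if (!is.null(p1)) {
      if (e$from[e1] == n) p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]
      if (e$from[e2] != n) p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
      merged <- rbind(p1, p2[-1, , drop = FALSE])
    } else merged <- NULL
    graph$edges$from[e1] <- a
    graph$edges$to[e1] <- b
    graph$edges$length_nm[e1] <- e$length_nm[e1] + e$length_nm[e2]
    if (!is.null(graph$paths)) {
      graph$paths[[e1]] <- merged
      graph$paths <- graph$paths[-e2]
    }
    graph$edges <- graph$edges[-e2, , drop = FALSE]
    graph$nodes <- graph$nodes[graph$nodes$id != n, , drop = FALSE]
  }
  graph
}
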