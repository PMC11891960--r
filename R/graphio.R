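# Graph serialization: DOT (graph description language) with positional
# node attributes, and VTK legacy ASCII polydata for viewers such as
# ParaView.

#' Write a spatial graph as a DOT file
#'
#' Nodes carry `pos="z,y,x"` in nm; edges carry their id and length. Edge
#' voxel paths are not serialized (DOT round-trips preserve node/edge
#' multisets, ids, positions and lengths).
#'
#' @param graph a [spatial_graph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path) {
  stopifnot(inherits(graph, "spatial_graph"))
  lines <- c("graph acn {")
  n <- graph$nodes
  for (i in seq_len(nrow(n))) {
    lines <- c(lines, sprintf("  %d [pos=\"%.10g,%.10g,%.10g\"];",
                              n$id[i], n$z[i], n$y[i], n$x[i]))
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, sprintf("  %d -- %d [id=%d, len=%.10g];",
                              e$from[i], e$to[i], e$id[i], e$length_nm[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a spatial graph from a DOT file
#'
#' Accepts the dialect written by [write_dot()]: node statements with a
#' `pos` attribute and `a -- b` edge statements with `id` and `len`
#' attributes.
#'
#' @param path DOT file.
#' @return A [spatial_graph()] (without voxel paths).
#' @export
read_dot <- function(path) {
  if (!file.exists(path)) stop_ctx("no such file: ", path)
  lines <- readLines(path)
  if (!length(grep("^\\s*graph\\b", lines)))
    stop_ctx("malformed DOT file (no `graph` header): ", path)
  node_re <- "^\\s*(\\d+)\\s*\\[pos=\"([^\"]+)\"\\];?\\s*$"
  edge_re <- paste0("^\\s*(\\d+)\\s*--\\s*(\\d+)\\s*",
                    "\\[id=(\\d+),\\s*len=([0-9.eE+-]+)\\];?\\s*$")
  nm <- regmatches(lines, regexec(node_re, lines))
  em <- regmatches(lines, regexec(edge_re, lines))
  nm <- nm[lengths(nm) == 3L]
  em <- em[lengths(em) == 5L]
  nodes <- if (length(nm)) {
    pos <- t(vapply(nm, function(m)
      as.numeric(strsplit(m[3], ",")[[1]]), numeric(3)))
    data.frame(id = as.integer(vapply(nm, `[`, "", 2)),
               z = pos[, 1], y = pos[, 2], x = pos[, 3])
  } else data.frame(id = integer(), z = numeric(), y = numeric(),
                    x = numeric())
  edges <- if (length(em)) {
    data.frame(id = as.integer(vapply(em, `[`, "", 4)),
               from = as.integer(vapply(em, `[`, "", 2)),
               to = as.integer(vapply(em, `[`, "", 3)),
               length_nm = as.numeric(vapply(em, `[`, "", 5)))
  } else data.frame(id = integer(), from = integer(), to = integer(),
                    length_nm = numeric())
  body <- grep("^\\s*(graph\\b.*\\{|\\})\\s*$", lines, invert = TRUE,
               value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) != nrow(nodes) + nrow(edges))
    stop_ctx("malformed DOT statement(s) in ", path)
  spatial_graph(nodes, edges)
}

#' Export a spatial graph as VTK legacy polylines
#'
#' Writes ASCII VTK polydata with one polyline per edge (the edge's voxel
#' path when available, otherwise the straight endpoint segment), with
#' point coordinates in nm ordered (x, y, z) as VTK expects.
#'
#' @param graph a [spatial_graph()].
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk_polylines <- function(graph, path) {
  stopifnot(inherits(graph, "spatial_graph"))
  pts <- list()
  lines_idx <- list()
  n_pts <- 0L
  node_pos <- graph$nodes
  sp <- graph$spacing_nm %||% c(1, 1, 1)
  for (i in seq_len(nrow(graph$edges))) {
    p <- if (!is.null(graph$paths) && !is.null(graph$paths[[i]])) {
      sweep(graph$paths[[i]], 2, sp, "*")  # voxel -> nm
    } else {
      a <- node_pos[node_pos$id == graph$edges$from[i], c("z", "y", "x")]
      b <- node_pos[node_pos$id == graph$edges$to[i], c("z", "y", "x")]
      rbind(as.numeric(a), as.numeric(b))
    }
    k <- nrow(p)
    pts[[length(pts) + 1L]] <- p
    lines_idx[[length(lines_idx) + 1L]] <- seq.int(n_pts, n_pts + k - 1L)
    n_pts <- n_pts + k
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "capillary network skeleton polylines",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n_pts)), con)
  all_pts <- if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(), ncol = 3)
  if (n_pts)
    writeLines(sprintf("%.10g %.10g %.10g",
                       all_pts[, 3], all_pts[, 2], all_pts[, 1]), con)
  total <- sum(lengths(lines_idx)) + length(lines_idx)
  writeLines(sprintf("LINES %d %d", length(lines_idx), total), con)
  for (li in lines_idx)
    writeLines(paste(c(length(li), li), collapse = " "), con)
  invisible(path)
}
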