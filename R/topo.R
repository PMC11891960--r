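# Core quantitative analysis: Euler number of the network graph, septal
# capillary loop (SCL) counts by two routes (Euler relation and cycle
# basis), numerical density, and group percentage comparisons.

#' Euler number of a graph
#'
#' `chi = N_nodes - N_edges`. For a connected capillary network the Euler
#' number is non-positive and `1 - chi` counts the independent capillary
#' loops.
#'
#' @param n_nodes,n_edges nonnegative counts.
#' @return Integer `n_nodes - n_edges` (may be positive, zero or negative).
#' @examples
#' euler_number(1884, 2373)  # -489
#' @export
euler_number <- function(n_nodes, n_edges) {
  if (!is_count(n_nodes) || !is_count(n_edges))
    stop_ctx("n_nodes and n_edges must be nonnegative counts")
  as.integer(n_nodes) - as.integer(n_edges)
}

#' Septal capillary loop count from the Euler number
#'
#' `N_SCL = |chi| + 1`, valid for a single connected network with
#' `chi <= 0`: the cycle rank of a connected graph is `1 - chi`, which
#' equals `|chi| + 1` only in that regime (a tree has `chi = +1` and zero
#' loops, not two, so positive `chi` is rejected).
#'
#' @param chi integer Euler number, must be `<= 0`.
#' @param n_components number of connected components, must be 1.
#' @return Integer loop count `|chi| + 1`.
#' @examples
#' scl_from_euler(-489)  # 490
#' @export
scl_from_euler <- function(chi, n_components = 1L) {
  if (!is.numeric(chi) || length(chi) != 1L || chi != round(chi))
    stop_ctx("chi must be a single integer")
  if (n_components != 1L)
    stop_ctx("the Euler relation N_SCL = |chi| + 1 assumes one connected ",
             "network (got ", n_components, " components); use ",
             "scl_from_cycle_basis() instead")
  if (chi > 0)
    stop_ctx("chi = ", chi, " > 0: the network is a tree/forest fragment ",
             "and has no capillary loops; |chi| + 1 would be wrong")
  as.integer(abs(chi) + 1L)
}

#' Septal capillary loop count as the cycle-basis size
#'
#' The minimal number of polygons required to form the network: the cycle
#' rank `E - V + C`, computed by growing a spanning forest with a
#' union-find structure — every non-forest edge (including self-loops and
#' parallel edges) contributes one independent basis cycle. Works for any
#' number of components and agrees with [scl_from_euler()] on connected
#' graphs with `chi <= 0`.
#'
#' @param graph a [spatial_graph()].
#' @return Integer cycle rank.
#' @export
scl_from_cycle_basis <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  n <- nrow(graph$nodes)
  if (n == 0L) return(0L)
  idx <- seq_len(n)
  names(idx) <- graph$nodes$id
  parent <- uf_new(n)
  rank <- 0L
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    a <- idx[as.character(e$from[k])]
    b <- idx[as.character(e$to[k])]
    if (uf_find(parent, a) == uf_find(parent, b)) {
      rank <- rank + 1L  # closes a cycle (self-loops land here too)
    } else {
      parent <- uf_union(parent, a, b)
    }
  }
  rank
}

#' Numerical density of capillary loops
#'
#' `N_V = N_SCL / V` in loops per cubic millimetre. Tables conventionally
#' display it in units of 10^3/mm^3 (divide by 1000).
#'
#' @param n_scl loop count.
#' @param volume_mm3 analysed tissue volume in mm^3 (> 0); see
#'   [volume_mm3()].
#' @return Density per mm^3.
#' @examples
#' numerical_density(490, 3.375e-3) / 1e3  # 145.19 (x10^3/mm^3)
#' @export
numerical_density <- function(n_scl, volume_mm3) {
  if (!is.numeric(volume_mm3) || length(volume_mm3) != 1L ||
      volume_mm3 <= 0)
    stop_ctx("volume_mm3 must be a single positive volume")
  n_scl / volume_mm3
}

#' Percentage deviation between two values
#'
#' `(comparison - reference) / reference * 100`; invariant under common
#' rescaling of both arguments. Reports round to 2 decimals; the returned
#' value is full precision.
#'
#' @param reference baseline value (nonzero).
#' @param comparison value compared against the baseline.
#' @return Percentage deviation.
#' @examples
#' percent_change(3344, 1884)  # -43.66...
#' @export
percent_change <- function(reference, comparison) {
  if (!is.numeric(reference) || any(reference == 0))
    stop_ctx("reference must be nonzero")
  (comparison - reference) / reference * 100
}

#' Topology report over subregions of a dataset
#'
#' Computes per-subregion node/edge counts, Euler number, loop counts by
#' both routes and numerical density, then aggregates with the arithmetic
#' mean and sample standard deviation (n - 1 denominator) per quantity.
#' `n_scl_graph` is `NA` for subregions violating the Euler-relation
#' preconditions (disconnected or positive chi); `n_scl_polygon` is always
#' defined.
#'
#' @param graphs list of [spatial_graph()], one per subregion.
#' @param volumes_mm3 numeric vector of subregion volumes in mm^3.
#' @param dataset optional dataset label stored in the report.
#' @return A `topology_report`: list with `per_subregion` and `summary`
#'   data frames.
#' @export
analyze_subregions <- function(graphs, volumes_mm3, dataset = NULL) {
  if (!is.list(graphs) || !length(graphs))
    stop_ctx("graphs must be a nonempty list of spatial graphs")
  if (length(graphs) != length(volumes_mm3))
    stop_ctx("graphs and volumes_mm3 must have equal length")
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    v <- nrow(g$nodes); e <- nrow(g$edges)
    chi <- euler_number(v, e)
    comps <- sg_components(g)
    scl_poly <- scl_from_cycle_basis(g)
    scl_graph <- if (comps == 1L && chi <= 0L) scl_from_euler(chi, comps)
                 else NA_integer_
    data.frame(subregion = i, n_nodes = v, n_edges = e, chi_graph = chi,
               n_components = comps, n_scl_graph = scl_graph,
               n_scl_polygon = scl_poly, volume_mm3 = volumes_mm3[i],
               nv_polygon_per_mm3 = numerical_density(scl_poly,
                                                      volumes_mm3[i]))
  })
  per <- do.call(rbind, rows)
  if (nrow(per) == 1L)
    warning("single subregion: SD reported as 0", call. = FALSE)
  agg <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0)
  }
  qty <- c("n_nodes", "n_edges", "chi_graph", "n_scl_graph",
           "n_scl_polygon", "nv_polygon_per_mm3")
  sm <- t(vapply(qty, function(q) agg(per[[q]]), numeric(2)))
  summary <- data.frame(quantity = qty, mean = sm[, 1], sd = sm[, 2],
                        row.names = NULL)
  structure(list(dataset = dataset, per_subregion = per, summary = summary),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  if (!is.null(x$dataset)) cat("dataset:", x$dataset, "\n")
  cat(sprintf("%d subregion(s)\n", nrow(x$per_subregion)))
  print(x$summary, ...)
  invisible(x)
}

#' Write a topology report as CSV
#'
#' One row per subregion plus summary rows (mean and SD per quantity).
#' Densities are written both per mm^3 and in the display unit 10^3/mm^3
#' rounded to 2 decimals.
#'
#' @param report a `topology_report` from [analyze_subregions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_topology_csv <- function(report, path) {
  stopifnot(inherits(report, "topology_report"))
  per <- report$per_subregion
  per$nv_polygon_1e3_mm3 <- round(per$nv_polygon_per_mm3 / 1e3, 2)
  per$row_type <- "subregion"
  sm <- report$summary
  mk <- function(stat) {
    r <- per[1, , drop = FALSE]
    r[] <- NA
    r$row_type <- stat
    for (q in sm$quantity) r[[q]] <- sm[[stat]][sm$quantity == q]
    r$nv_polygon_1e3_mm3 <- round(r$nv_polygon_per_mm3 / 1e3, 2)
    r
  }
  out <- rbind(per, mk("mean"), mk("sd"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
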