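test_that("skeletonization preserves topology and thins to curves", {
  # solid straight tube -> single 26-connected curve with 2 endpoints
  spec <- make_spec(rbind(c(750, 750, 600), c(750, 750, 3600)), c(1, 2))
  ph <- voxelize_network(spec, radius_vx = 2,
                         volume_shape = c(13, 13, 30), spacing_nm = 150)
  sk <- skeletonize(ph$volume)
  lab <- acntopo:::.cc_label_3d(as.integer(sk$data), dim(sk$data), 26L)
  expect_equal(max(lab), 1L)
  expect_equal(endpoint_count(sk), 2L)

  # voxelized 2x2 lattice (1 loop): skeleton cycle rank 1, no endpoints
  net <- make_lattice_network(2, 2)
  ph2 <- voxelize_network(net$spec, radius_vx = 2)
  sk2 <- skeletonize(largest_component(fill_holes(ph2$volume)))
  co <- which(sk2$data == 1, arr.ind = TRUE)
  expect_equal(oracle_voxel_rank(co), 1L)
  expect_equal(endpoint_count(sk2), 0L)

  expect_error(skeletonize(voxel_volume(array(0L, c(4, 4, 4)), 150)),
               "empty")
  two <- array(0L, c(9, 9, 9)); two[2, 2, 2] <- 1L; two[7, 7, 7] <- 1L
  expect_warning(skeletonize(voxel_volume(two, 150)), "components")
})

test_that("build_graph classifies junctions, endpoints and loops", {
  # straight curve skeleton -> 2 nodes, 1 edge
  line <- array(0L, c(3, 3, 12))
  line[2, 2, 2:11] <- 1L
  g <- build_graph(voxel_volume(line, 150))
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length_nm, 9 * 150)

  # H-shaped skeleton -> 6 nodes (4 endpoints + 2 junction clusters), 5 edges
  h <- array(0L, c(3, 11, 11))
  h[2, 1:9, 2] <- 1L
  h[2, 1:9, 8] <- 1L
  h[2, 5, 3:7] <- 1L
  gh <- build_graph(voxel_volume(h, 150))
  expect_equal(nrow(gh$nodes), 6L)
  expect_equal(nrow(gh$edges), 5L)
  deg <- sg_degree(gh)
  expect_equal(sort(unname(deg)), c(1L, 1L, 1L, 1L, 3L, 3L))
  # cycle rank invariant vs the voxel graph (tree here: 0)
  expect_equal(scl_from_cycle_basis(gh), 0L)

  # single closed ring -> 1 node with 1 self-loop, chi = 0
  # octagon-like ring: corners joined diagonally so that every voxel has
  # exactly two 26-neighbours (a rectangle would form corner triangles)
  ring <- array(0L, c(3, 9, 9))
  ring[2, 3:7, 2] <- 1L; ring[2, 3:7, 8] <- 1L
  ring[2, 2, 3:7] <- 1L; ring[2, 8, 3:7] <- 1L
  gr <- build_graph(voxel_volume(ring, 150))
  expect_equal(nrow(gr$nodes), 1L)
  expect_equal(nrow(gr$edges), 1L)
  expect_equal(gr$edges$from, gr$edges$to)
  expect_equal(euler_number(nrow(gr$nodes), nrow(gr$edges)), 0L)
  expect_equal(scl_from_cycle_basis(gr), 1L)
  expect_equal(oracle_voxel_rank(which(ring == 1, arr.ind = TRUE)), 1L)
})

test_that("node positions lie within the originating foreground", {
  net <- make_lattice_network(4, 4)
  ph <- voxelize_network(net$spec, radius_vx = 2)
  v <- largest_component(fill_holes(ph$volume))
  g <- build_graph(skeletonize(v))
  vx <- cbind(round(g$nodes$z / 150), round(g$nodes$y / 150),
              round(g$nodes$x / 150)) + 1
  inside <- v$data[vx]
  expect_true(all(inside == 1))
})

test_that("pruning removes dead ends to a fixpoint", {
  # triangle with a 2-node tail
  nodes <- data.frame(id = 1:5, z = 1:5 * 100, y = 0, x = 0)
  edges <- data.frame(id = 1:5, from = c(1, 2, 3, 3, 4),
                      to = c(2, 3, 1, 4, 5), length_nm = 1)
  g <- spatial_graph(nodes, edges)
  p <- prune_degree_one(g)
  expect_equal(nrow(p$nodes), 3L)
  expect_equal(nrow(p$edges), 3L)
  expect_gte(attr(p, "iterations"), 2L)

  # one pass only leaves the newly exposed dead end
  p1 <- prune_degree_one(g, to_fixpoint = FALSE)
  expect_equal(nrow(p1$nodes), 4L)
  expect_equal(nrow(p1$edges), 4L)

  # a pure tree vanishes at fixpoint
  tree <- spatial_graph(nodes,
                        data.frame(id = 1:4, from = c(1, 1, 2, 2),
                                   to = c(2, 3, 4, 5), length_nm = 1))
  pt <- prune_degree_one(tree)
  expect_equal(nrow(pt$nodes), 0L)
  expect_equal(nrow(pt$edges), 0L)

  # a pure cycle is untouched (self-loops count degree 2)
  cyc <- spatial_graph(nodes[1:3, ],
                       data.frame(id = 1:3, from = c(1, 2, 3),
                                  to = c(2, 3, 1), length_nm = 1))
  expect_equal(nrow(prune_degree_one(cyc)$edges), 3L)
  loop <- spatial_graph(nodes[1, , drop = FALSE],
                        data.frame(id = 1, from = 1, to = 1,
                                   length_nm = 1))
  expect_equal(nrow(prune_degree_one(loop)$edges), 1L)
})

test_that("pruning and dissolution preserve the cycle rank", {
  set.seed(42)
  for (k in 1:25) {
    g <- random_connected_multigraph(sample(3:12, 1), sample(1:6, 1))
    rank0 <- scl_from_cycle_basis(g)
    gp <- prune_degree_one(g)
    expect_equal(scl_from_cycle_basis(gp), rank0)
    gd <- dissolve_degree_two(gp)
    expect_equal(scl_from_cycle_basis(gd), rank0)
    expect_equal(euler_number(nrow(gd$nodes), nrow(gd$edges)),
                 euler_number(nrow(gp$nodes), nrow(gp$edges)))
    # after dissolution every surviving node is a true branch point or a
    # self-loop anchor
    if (nrow(gd$nodes)) {
      deg <- sg_degree(gd)
      self_anchor <- gd$nodes$id %in% gd$edges$from[gd$edges$from ==
                                                    gd$edges$to]
      expect_true(all(deg != 2 | self_anchor))
    }
  }
})

test_that("lattice phantoms recover the branch-point graph exactly", {
  # lattice corners are degree-2 and cannot appear in a skeleton-derived
  # graph; the dissolved ground truth is rows*cols - 4 nodes, E - 4 edges
  net <- make_lattice_network(5, 5)
  ph <- voxelize_network(net$spec, radius_vx = 2)
  g <- recover_graph(ph$volume)
  expect_equal(nrow(g$nodes), 25L - 4L)
  expect_equal(nrow(g$edges), 40L - 4L)
  expect_equal(euler_number(nrow(g$nodes), nrow(g$edges)), -15L)
  expect_equal(scl_from_cycle_basis(g), net$truth$n_cycles_true)
})

test_that("DOT and VTK serialization round-trip", {
  set.seed(9)
  g <- random_connected_multigraph(6, 3)
  path <- tempfile(fileext = ".dot")
  write_dot(g, path)
  g2 <- read_dot(path)
  expect_equal(nrow(g2$nodes), nrow(g$nodes))
  expect_equal(nrow(g2$edges), nrow(g$edges))
  expect_equal(sort(g2$nodes$id), sort(g$nodes$id))
  expect_equal(g2$nodes$z[order(g2$nodes$id)],
               g$nodes$z[order(g$nodes$id)], tolerance = 1e-9)
  em <- function(gr) sort(paste(pmin(gr$edges$from, gr$edges$to),
                                pmax(gr$edges$from, gr$edges$to)))
  expect_equal(em(g2), em(g))

  # 1-node self-loop and the empty graph
  loop <- spatial_graph(data.frame(id = 1, z = 0, y = 0, x = 0),
                        data.frame(id = 1, from = 1, to = 1,
                                   length_nm = 5))
  pl <- tempfile(fileext = ".dot")
  write_dot(loop, pl)
  expect_true(any(grepl("1 -- 1", readLines(pl))))
  l2 <- read_dot(pl)
  expect_equal(l2$edges$from, l2$edges$to)

  empty <- spatial_graph(data.frame(id = integer(), z = numeric(),
                                    y = numeric(), x = numeric()),
                         data.frame(id = integer(), from = integer(),
                                    to = integer(),
                                    length_nm = numeric()))
  pe <- tempfile(fileext = ".dot")
  write_dot(empty, pe)
  e2 <- read_dot(pe)
  expect_equal(nrow(e2$nodes), 0L)
  expect_equal(nrow(e2$edges), 0L)

  expect_error(read_dot(tempfile()), "no such file")
  bad <- tempfile(); writeLines(c("graph g {", "%%%", "}"), bad)
  expect_error(read_dot(bad), "malformed")

  # VTK polylines: one line per edge, points in nm
  vtk <- tempfile(fileext = ".vtk")
  net <- make_lattice_network(2, 2)
  ph <- voxelize_network(net$spec, radius_vx = 2)
  gg <- recover_graph(ph$volume, dissolve = FALSE)
  write_vtk_polylines(gg, vtk)
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET POLYDATA")
  expect_true(any(grepl(sprintf("^LINES %d ", nrow(gg$edges)), lines)))
})
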