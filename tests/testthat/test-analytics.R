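test_that("branch counts on a path and a tree are the hop distances", {
  nodes <- data.frame(id = 1:3, x = c(0, 10, 20), y = 0, z = 0)
  seg <- function(id, a, b) list(id = id, nodes = c(a, b),
                                 points = rbind(nodes[a, 2:4], nodes[b, 2:4]) |>
                                   as.matrix() |> unname(),
                                 radii = c(1, 1))
  net <- network_topology(nodes, list(seg(1L, 1, 2), seg(2L, 2, 3)))
  bc <- branch_counts(net, 1)
  expect_identical(unname(bc$counts[c("1", "2", "3")]), c(0L, 1L, 2L))

  gt <- generate_tree(phantom_spec(seed = 2, levels = 3L,
                                   root_position = c(150, 150, 30),
                                   root_radius = 10, radius_ratio = 0.85,
                                   segment_length = c(40, 60),
                                   domain_size = c(300, 300, 300)))
  bc <- branch_counts(gt$topology, 1)
  # in a full binary tree the count equals the node's depth: the segment
  # generations give the expected depth of each child endpoint
  for (s in gt$topology$segments)
    expect_identical(unname(bc$counts[as.character(s$nodes[2])]),
                     s$generation + 1L)
})

test_that("branch counts equal exhaustive shortest-path enumeration", {
  for (sd in 1:10) {
    net <- random_graph_net(sd, n_nodes = 5 + (sd %% 8), extra_edges = 2L)
    bc <- branch_counts(net, net$nodes$id[1])
    oracle <- bf_branch_counts(net, net$nodes$id[1])
    expect_identical(bc$counts[names(oracle)], oracle)
  }
})

test_that("adjacent nodes never differ by more than one branch count", {
  gt <- sample_phantoms(1, seed = 8, levels = 4L)[[1]]
  solid <- rasterize(gt, 2, "solid")
  sk <- skeletonize(solid)
  net <- prune_network(trace_skeleton(sk, estimate_radii(sk, solid)),
                       min_length = 20)
  src <- suggest_feeder_nodes(net, 1)$node[1]
  bc <- branch_counts(net, src)
  for (s in net$segments) {
    a <- bc$counts[as.character(s$nodes[1])]
    b <- bc$counts[as.character(s$nodes[2])]
    expect_lte(abs(a - b), 1L)
  }
})

test_that("unreachable nodes are flagged, and unknown sources error", {
  nodes <- data.frame(id = 1:4, x = c(0, 10, 50, 60), y = 0, z = 0)
  seg <- function(id, a, b) list(id = id, nodes = c(a, b),
                                 points = unname(as.matrix(
                                   rbind(nodes[a, 2:4], nodes[b, 2:4]))),
                                 radii = c(1, 1))
  net <- network_topology(nodes, list(seg(1L, 1, 2), seg(2L, 3, 4)))
  bc <- branch_counts(net, 1)
  expect_equal(sort(bc$unreachable), c(3, 4))
  expect_true(is.na(bc$counts["3"]))
  expect_error(branch_counts(net, 99), "unknown source")
})

test_that("diameter selection follows the window and length rules", {
  mknet <- function(dias) {
    n <- length(dias)
    nodes <- data.frame(id = seq_len(2 * n),
                        x = rep(seq(0, by = 200, length.out = n), each = 2) +
                          rep(c(0, 100), n),
                        y = 0, z = 0)
    segs <- lapply(seq_len(n), function(i) {
      a <- 2 * i - 1; b <- 2 * i
      list(id = i, nodes = c(a, b),
           points = rbind(c(nodes$x[a], 0, 0), c(nodes$x[b], 0, 0)),
           radii = rep(dias[i] / 2, 2))
    })
    network_topology(nodes, segs)
  }
  net <- mknet(c(10, 20, 40))
  sel <- select_by_diameter(net, 16, 32)
  expect_length(sel$segments, 1L)
  expect_equal(segment_table(sel)$diameter, 20)
  # identity when the window spans everything
  expect_length(select_by_diameter(net, 0, Inf)$segments, 3L)
  # widening windows keep supersets
  ids <- function(n2) vapply(n2$segments, `[[`, numeric(1), "id")
  expect_true(all(ids(select_by_diameter(net, 16, 32)) %in%
                    ids(select_by_diameter(net, 10, 40))))
})

test_that("the pHEV preset recovers exactly the qualifying phantom segments", {
  gt <- sample_phantoms(1, seed = 17, levels = 5L)[[1]]
  tt <- segment_table(gt$topology)
  want <- tt$id[tt$diameter >= 16 & tt$diameter <= 32 & tt$length >= 40]
  sel <- select_by_diameter(gt$topology, 16, 32, min_length = 40)
  got <- vapply(sel$segments, `[[`, numeric(1), "id")
  expect_identical(sort(got), sort(as.numeric(want)))
})

test_that("diameter-thresholded trees split into the two main components", {
  gt <- sample_phantoms(1, seed = 23, levels = 4L)[[1]]
  trees <- split_trees(gt$topology, dmin = 2 * 12 * 0.85^2)
  expect_gte(length(trees), 1L)
  total <- sum(segment_table(gt$topology)$diameter >= 2 * 12 * 0.85^2)
  expect_identical(sum(vapply(trees, function(t) length(t$segments),
                              integer(1))), as.integer(total))
})

test_that("ln_region closes and hole-fills around the vessels", {
  # hollow shell with a sealed interior: hole filling must recover the core
  gt <- tube_truth(c(30, 30, 10), c(30, 30, 90), r = 8,
                   domain = c(60, 60, 100), wall = 4)
  hollow <- rasterize(gt, 2, "hollow")
  filled <- ln_region(hollow, closing_radius = 0)
  solid <- rasterize(gt, 2, "solid")
  expect_true(all(filled$values[solid$values]))

  # closing is extensive
  reg <- ln_region(hollow, closing_radius = 20)
  expect_true(all(reg$values[hollow$values]))
  expect_gte(sum(reg$values), sum(filled$values))
})

test_that("a tube lattice under closing covers nearly all of its region", {
  net <- tube_lattice_net(xs = seq(20, 140, by = 40),
                          ys = seq(20, 140, by = 40), z0 = 10, z1 = 150, 4)
  segm <- t(vapply(net$segments, function(s)
    c(s$points[1, ], s$points[2, ], s$radii[1]), numeric(7)))
  dm <- c(81, 81, 81)
  code <- vasculonet:::cpp_rasterize_capsules(dm, 2, c(0, 0, 0), segm, 0)
  vessels <- binary_mask(array(code > 0, dm), 2)
  reg <- ln_region(vessels, closing_radius = 60)
  # the convex hull of the lattice spans [20,140]^2 x [10,150]
  hull <- array(FALSE, dm)
  hull[11:71, 11:71, 6:76] <- TRUE
  expect_gt(sum(reg$values & hull) / sum(hull), 0.99)
})

test_that("distance fields match the brute-force oracle exactly", {
  for (sd in 1:5) {
    dmv <- c(20, 16, 12)
    vess <- with_seed_t(sd, array(runif(prod(dmv)) < 0.02, dmv))
    if (!any(vess)) vess[1, 1, 1] <- TRUE
    vessels <- binary_mask(vess, 2)
    region <- binary_mask(array(TRUE, dmv), 2)
    df <- distance_field(region, vessels, spacing = 4)
    bf <- bf_distance_field(region, vessels, spacing = 4)
    expect_equal(sort(df$distances), sort(bf$distances))
    expect_identical(length(df$distances), length(bf$distances))
    # mean invariant to point order
    expect_equal(df$summary$mean, mean(bf$distances))
  }
})

test_that("distance-field conventions: exclusion, units, errors", {
  dmv <- c(16, 16, 16)
  vess <- array(FALSE, dmv); vess[2, 3, 3] <- TRUE   # world (2, 4, 4)
  vessels <- binary_mask(vess, 2)
  region <- binary_mask(array(TRUE, dmv), 2)
  df <- distance_field(region, vessels, spacing = 4)
  # a grid point 10 um away on-axis is at distance 10
  hit <- which(df$coords[, 1] == 12 & df$coords[, 2] == 4 &
                 df$coords[, 3] == 4)
  expect_equal(df$distances[hit], 10)
  # a grid point inside a vessel is excluded from the field
  vess2 <- array(FALSE, dmv); vess2[3, 3, 3] <- TRUE  # world (4, 4, 4), on-grid
  df2 <- distance_field(region, binary_mask(vess2, 2), spacing = 4)
  expect_false(any(df2$coords[, 1] == 4 & df2$coords[, 2] == 4 &
                     df2$coords[, 3] == 4))
  expect_error(distance_field(region, binary_mask(array(FALSE, dmv), 2), 4),
               "empty vessel")
  expect_error(distance_field(region, vessels, spacing = 3), "multiple")
})

test_that("void detection matches brute force and its limit cases", {
  dmv <- c(26, 26, 26)
  vess <- array(FALSE, dmv); vess[13, 13, 13] <- TRUE
  vessels <- binary_mask(vess, 2)
  region <- binary_mask(array(TRUE, dmv), 2)
  df <- distance_field(region, vessels, spacing = 2, void_threshold = 60)
  voids <- find_voids(df, 24)
  bf <- bf_distance_field(region, vessels, spacing = 2)
  expect_identical(sum(voids$values), sum(bf$distances > 24))
  # threshold above the maximum distance: no voids
  expect_identical(sum(find_voids(df, 1000)$values), 0L)
  # vanishing threshold: every interior point is a void
  expect_identical(sum(find_voids(df, 1e-9)$values), length(df$distances))
})

test_that("histology counts one crossing per centerline transit", {
  region <- binary_mask(array(TRUE, c(51, 51, 51)), 2)
  net <- tube_lattice_net(xs = 50, ys = 50, z0 = 10, z1 = 90, radius = 5)
  h <- histology_2d(net, region, "z", 50)
  expect_identical(nrow(h$intersections), 1L)
  expect_equal(h$intersections$diameter, 10)

  # U-shaped vessel crosses the plane twice
  nodes <- data.frame(id = 1:2, x = c(20, 60), y = 50, z = c(20, 20))
  pts <- rbind(c(20, 50, 20), c(20, 50, 70), c(40, 50, 70),
               c(60, 50, 70), c(60, 50, 20))
  u <- network_topology(nodes, list(list(id = 1L, nodes = c(1, 2),
                                         points = pts, radii = rep(4, 5))))
  h2 <- histology_2d(u, region, "z", 50)
  expect_identical(nrow(h2$intersections), 2L)

  # a tangential run lying exactly on the plane counts once
  pts3 <- rbind(c(20, 50, 20), c(20, 50, 50), c(40, 50, 50), c(60, 50, 50),
                c(60, 50, 20))
  nodes3 <- data.frame(id = 1:2, x = c(20, 60), y = 50, z = c(20, 20))
  tang <- network_topology(nodes3, list(list(id = 1L, nodes = c(1, 2),
                                             points = pts3,
                                             radii = rep(4, 5))))
  h3 <- histology_2d(tang, region, "z", 50)
  expect_identical(nrow(h3$intersections), 1L)

  expect_error(histology_2d(net, region, "z", 500), "outside")
})

test_that("lattice histology density equals the analytic tubes-per-area", {
  xs <- seq(20, 140, by = 40); ys <- seq(20, 140, by = 40)
  net <- tube_lattice_net(xs, ys, z0 = 10, z1 = 150, radius = 5)
  region <- binary_mask(array(TRUE, c(81, 81, 81)), 2)
  h <- histology_2d(net, region, "z", 80)
  expect_identical(nrow(h$intersections), length(xs) * length(ys))
  expect_equal(h$density, nrow(h$intersections) / h$area_mm2)
  expect_true(all(h$intersections$diameter == 10))
})

test_that("region stats are additive and consistent globally", {
  gt <- sample_phantoms(1, seed = 14, levels = 4L)[[1]]
  net <- gt$topology
  solid <- rasterize(gt, 2, "solid")
  region <- phantom_region(gt, 2)
  df <- distance_field(region, solid, spacing = 4)
  dom <- gt$region$domain

  whole <- region_stats(net, df, c(0, 0, 0), dom + 2)
  expect_identical(whole$n_segments, length(net$segments))
  expect_equal(whole$density_3d,
               length(net$segments) / (prod(dom + 2) / 1e9))

  # a partition of the volume splits the segment count exactly
  half1 <- region_stats(net, df, c(0, 0, 0),
                        c((dom[1] + 2) / 2, dom[2] + 2, dom[3] + 2))
  half2 <- region_stats(net, df, c((dom[1] + 2) / 2, 0, 0),
                        c((dom[1] + 2) / 2, dom[2] + 2, dom[3] + 2))
  expect_identical(half1$n_segments + half2$n_segments, whole$n_segments)
  expect_error(region_stats(net, df, c(0, 0, 0), c(0, 10, 10)), "empty")
})
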