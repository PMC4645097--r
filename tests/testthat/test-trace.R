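# hand-built skeleton masks exercise the tracer's node/segment rules

test_that("a Y-shaped skeleton traces to 4 nodes and 3 segments", {
  vals <- array(FALSE, c(21, 21, 21))
  vals[11, 11, 3:11] <- TRUE                 # stem
  for (t in 1:8) {
    vals[11 + t, 11, 11 + t] <- TRUE         # arm 1 (diagonal)
    vals[11 - t, 11, 11 + t] <- TRUE         # arm 2 (diagonal)
  }
  sk <- binary_mask(vals, 2)
  r <- array(2, dim(vals))
  net <- trace_skeleton(sk, r, trim_tips = FALSE)
  expect_identical(nrow(net$nodes), 4L)
  expect_length(net$segments, 3L)
  expect_identical(sort(unname(node_degrees(net))), c(1L, 1L, 1L, 3L))
})

test_that("a ring skeleton traces to one node with a self-loop", {
  vals <- array(FALSE, c(25, 25, 5))
  th <- seq(0, 2 * pi, length.out = 100)
  ij <- unique(cbind(round(12 + 8 * cos(th)), round(12 + 8 * sin(th)))) + 1
  vals[cbind(ij, 3)] <- TRUE
  sk <- skeletonize(binary_mask(vals, 2))  # clean up double-thick corners
  r <- array(2, dim(vals))
  net <- trace_skeleton(sk, r, trim_tips = FALSE)
  expect_identical(nrow(net$nodes), 1L)
  expect_length(net$segments, 1L)
  expect_identical(net$segments[[1]]$nodes[1], net$segments[[1]]$nodes[2])
  # the loop survives in the graph sense
  g <- vasculonet:::as_network_igraph(net)
  expect_equal(igraph::ecount(g) - igraph::vcount(g) +
                 igraph::components(g)$no, 1)
})

test_that("tracing a clean phantom recovers the exact ground-truth topology", {
  gt <- sample_phantoms(1, seed = 12, levels = 4L)[[1]]
  solid <- rasterize(gt, 2, "solid")
  sk <- skeletonize(solid)
  r <- estimate_radii(sk, solid)
  net <- prune_network(trace_skeleton(sk, r), min_length = 20)
  expect_identical(length(net$segments), length(gt$topology$segments))
  expect_identical(sort(unname(node_degrees(net))),
                   sort(unname(node_degrees(gt$topology))))
})

test_that("pruning removes short terminal twigs and merges the pass-through", {
  nodes <- data.frame(id = 1:4,
                      x = c(0, 50, 100, 53), y = c(0, 0, 0, 4), z = 0)
  seg <- function(id, a, b, pts, r = 5) list(id = id, nodes = c(a, b),
                                             points = pts,
                                             radii = rep(r, nrow(pts)))
  net <- network_topology(nodes, list(
    seg(1L, 1, 2, rbind(c(0, 0, 0), c(50, 0, 0))),
    seg(2L, 2, 3, rbind(c(50, 0, 0), c(100, 0, 0))),
    seg(3L, 2, 4, rbind(c(50, 0, 0), c(53, 4, 0)))   # 5 um twig
  ))
  pruned <- prune_network(net, min_length = 10)
  expect_length(pruned$segments, 1L)
  expect_identical(nrow(pruned$nodes), 2L)
  expect_equal(polyline_len <- sum(segment_table(pruned)$length), 100)

  # nothing below threshold: identity (up to renumbering)
  keep <- prune_network(net, min_length = 1)
  expect_length(keep$segments, 3L)
})

test_that("pruning never disconnects the network", {
  for (sd in c(3, 6)) {
    gt <- sample_phantoms(1, seed = sd, levels = 4L)[[1]]
    solid <- rasterize(gt, 2, "solid")
    sk <- skeletonize(solid)
    r <- estimate_radii(sk, solid)
    net <- trace_skeleton(sk, r)
    g0 <- igraph::components(vasculonet:::as_network_igraph(net))$no
    pruned <- prune_network(net, min_length = 30)
    g1 <- igraph::components(vasculonet:::as_network_igraph(pruned))$no
    expect_lte(g1, g0)
  }
})

test_that("summary reports closed-form values for simple networks", {
  nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0)
  net <- network_topology(nodes, list(
    list(id = 1L, nodes = c(1, 2), points = rbind(c(0, 0, 0), c(100, 0, 0)),
         radii = c(5, 5))))
  s <- summary(net)
  expect_identical(s$n_segments, 1L)
  expect_equal(s$mean_diameter, 10)
  expect_equal(s$mean_length, 100)
  expect_equal(s$total_length, 0.01)              # cm
  expect_equal(s$total_volume, pi * 25 * 100 / 1e9)  # mm^3
  expect_identical(sum(s$diameter_histogram), 1L)

  nodes3 <- data.frame(id = 1:3, x = c(0, 40, 120), y = 0, z = 0)
  net2 <- network_topology(nodes3, list(
    list(id = 1L, nodes = c(1, 2), points = rbind(c(0, 0, 0), c(40, 0, 0)),
         radii = c(5, 5)),
    list(id = 2L, nodes = c(2, 3), points = rbind(c(40, 0, 0), c(120, 0, 0)),
         radii = c(5, 5))))
  expect_equal(summary(net2)$mean_length, 60)
})

test_that("summaries are additive over an edge partition", {
  gt <- sample_phantoms(1, seed = 21, levels = 4L)[[1]]
  net <- gt$topology
  half <- length(net$segments) %/% 2
  a <- net; a$segments <- net$segments[seq_len(half)]
  b <- net; b$segments <- net$segments[(half + 1):length(net$segments)]
  a <- vasculonet:::drop_orphan_nodes(a)
  b <- vasculonet:::drop_orphan_nodes(b)
  s <- summary(net); sa <- summary(a); sb <- summary(b)
  expect_equal(sa$total_length + sb$total_length, s$total_length)
  expect_equal(sa$total_volume + sb$total_volume, s$total_volume)
  expect_identical(sa$n_segments + sb$n_segments, s$n_segments)
})

test_that("traced phantom volume approximates the voxel-count volume", {
  gt <- sample_phantoms(1, seed = 33, levels = 4L)[[1]]
  solid <- rasterize(gt, 2, "solid")
  sk <- skeletonize(solid)
  r <- estimate_radii(sk, solid)
  net <- prune_network(trace_skeleton(sk, r), min_length = 20)
  vol_vox <- sum(solid$values) * 8 / 1e9
  s <- summary(net)
  expect_lt(abs(s$total_volume - vol_vox) / vol_vox, 0.15)
})

test_that("network invariants are enforced by the validator", {
  nodes <- data.frame(id = 1:2, x = c(0, 10), y = 0, z = 0)
  expect_error(network_topology(nodes, list(
    list(id = 1L, nodes = c(1, 3), points = rbind(c(0, 0, 0), c(10, 0, 0)),
         radii = c(1, 1)))), "unknown node")
  expect_error(network_topology(nodes, list(
    list(id = 1L, nodes = c(1, 2), points = rbind(c(0, 0, 0), c(10, 0, 0)),
         radii = c(1, -1)))), "radii")
  expect_error(network_topology(nodes, list(
    list(id = 1L, nodes = c(1, 2), points = rbind(c(5, 0, 0), c(10, 0, 0)),
         radii = c(1, 1)))), "coincide")
})
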