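# Shared fixture builders. Everything is generated in code; the brute-force
# oracles here deliberately re-derive quantities through independent paths
# (plain R loops / closed forms) rather than calling the package internals.

# A hand-built single-tube "truth" object compatible with rasterize().
tube_truth <- function(p1, p2, r, domain, wall = 2, gapf = 0, seed = 1,
                       patch = 2) {
  nodes <- data.frame(id = 1:2, x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                      z = c(p1[3], p2[3]))
  len <- sqrt(sum((p2 - p1)^2))
  nstep <- max(2L, ceiling(len / 4) + 1L)
  ts <- seq(0, 1, length.out = nstep)
  pts <- cbind(p1[1] + ts * (p2[1] - p1[1]),
               p1[2] + ts * (p2[2] - p1[2]),
               p1[3] + ts * (p2[3] - p1[3]))
  topo <- network_topology(nodes,
                           list(list(id = 1L, nodes = c(1, 2), points = pts,
                                     radii = rep(r, nstep))))
  spec <- phantom_spec(seed = seed, levels = 0L, root_position = p1,
                       root_direction = (p2 - p1) / len, root_radius = r,
                       segment_length = c(len, len), wall_thickness = wall,
                       gap_fraction = gapf, gap_patch_radius = patch,
                       domain_size = domain)
  structure(list(topology = topo, spec = spec,
                 region = list(shape = "box", domain = domain)),
            class = "PhantomTruth")
}

# Brute-force capsule rasterisation: plain-R voxel-center-in-capsule test.
bf_capsule_mask <- function(dimv, vs, p1, p2, r) {
  out <- array(FALSE, dim = dimv)
  v <- p2 - p1
  vv <- sum(v^2)
  for (k in seq_len(dimv[3])) for (j in seq_len(dimv[2]))
    for (i in seq_len(dimv[1])) {
      p <- c(i - 1, j - 1, k - 1) * vs - p1
      t <- if (vv > 0) max(0, min(1, sum(p * v) / vv)) else 0
      out[i, j, k] <- sum((p - t * v)^2) <= r^2
    }
  out
}

# Solid axis-aligned cylinder (infinite-ends tube clipped to the volume).
cylinder_mask <- function(dimv, vs, center_xy, r_um, axis = 3L) {
  stopifnot(axis == 3L)
  i <- ((seq_len(dimv[1]) - 1) * vs - center_xy[1])^2
  j <- ((seq_len(dimv[2]) - 1) * vs - center_xy[2])^2
  disc <- outer(i, j, "+") <= r_um^2
  array(rep(disc, dimv[3]), dim = dimv)
}

# Solid torus centered in the volume, axis along z.
torus_mask <- function(dimv, vs, R_um, r_um) {
  ctr <- (dimv - 1) / 2 * vs
  out <- array(FALSE, dim = dimv)
  for (k in seq_len(dimv[3])) {
    z <- (k - 1) * vs - ctr[3]
    for (j in seq_len(dimv[2])) {
      y <- (j - 1) * vs - ctr[2]
      for (i in seq_len(dimv[1])) {
        x <- (i - 1) * vs - ctr[1]
        out[i, j, k] <- (sqrt(x^2 + y^2) - R_um)^2 + z^2 <= r_um^2
      }
    }
  }
  out
}

n_components <- function(mask, connectivity = 26L) {
  lab <- vasculonet:::cpp_label_components(as.logical(mask$values),
                                           dim(mask$values),
                                           as.integer(connectivity))
  max(0L, max(lab))
}

# Exhaustive minimum-edge-count path search (depth-first over simple paths).
bf_branch_counts <- function(net, source) {
  ids <- net$nodes$id
  adj <- lapply(ids, function(nid) {
    unlist(lapply(net$segments, function(s) {
      if (s$nodes[1] == nid) s$nodes[2]
      else if (s$nodes[2] == nid) s$nodes[1]
    }))
  })
  names(adj) <- as.character(ids)
  best <- setNames(rep(Inf, length(ids)), as.character(ids))
  walk <- function(node, depth, seen) {
    key <- as.character(node)
    if (depth < best[key]) best[key] <<- depth
    for (nb in adj[[key]]) {
      if (nb %in% seen) next
      if (depth + 1 >= best[as.character(nb)]) next
      walk(nb, depth + 1, c(seen, nb))
    }
  }
  walk(source, 0, source)
  out <- suppressWarnings(as.integer(best))
  out[is.infinite(best)] <- NA_integer_
  setNames(out, names(best))
}

# Random connected multigraph network with straight unit-radius segments.
random_graph_net <- function(seed, n_nodes, extra_edges = 2L) {
  with_seed_t(seed, {
    pos <- matrix(runif(n_nodes * 3, 0, 100), ncol = 3)
    nodes <- data.frame(id = seq_len(n_nodes), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3])
    el <- cbind(2:n_nodes, vapply(2:n_nodes,
                                  function(i) sample.int(i - 1L, 1L),
                                  integer(1)))
    if (extra_edges > 0)
      el <- rbind(el, matrix(sample.int(n_nodes, 2 * extra_edges,
                                        replace = TRUE), ncol = 2))
    segs <- lapply(seq_len(nrow(el)), function(e) {
      a <- el[e, 1]; b <- el[e, 2]
      list(id = e, nodes = c(a, b),
           points = rbind(pos[a, ], pos[b, ]), radii = c(1, 1))
    })
    # drop degenerate self-loops with zero length (same node twice)
    keep <- vapply(segs, function(s)
      s$nodes[1] != s$nodes[2] || sum((s$points[1, ] - s$points[2, ])^2) > 0,
      logical(1))
    network_topology(nodes, segs[keep])
  })
}

# local seeded-RNG helper for tests (keeps the global stream untouched)
with_seed_t <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# O(N*M) brute-force nearest-vessel distances on a coarse grid.
bf_distance_field <- function(region, vessels, spacing) {
  vs <- region$voxel_size
  stride <- as.integer(round(spacing / vs))
  d <- dim(region$values)
  von <- which(vessels$values)
  vco <- (arrayInd(von, d) - 1) * vs
  gi <- seq(1L, d[1], by = stride)
  gj <- seq(1L, d[2], by = stride)
  gk <- seq(1L, d[3], by = stride)
  pts <- list(); dist <- numeric(0)
  for (k in gk) for (j in gj) for (i in gi) {
    if (!region$values[i, j, k] || vessels$values[i, j, k]) next
    p <- (c(i, j, k) - 1) * vs
    dmin <- sqrt(min(colSums((t(vco) - p)^2)))
    pts[[length(pts) + 1L]] <- p
    dist <- c(dist, dmin)
  }
  list(coords = do.call(rbind, pts), distances = dist)
}

# straight tube network along z for histology tests
tube_lattice_net <- function(xs, ys, z0, z1, radius) {
  nodes <- list(); segs <- list()
  nid <- 0L
  for (x in xs) for (y in ys) {
    a <- nid + 1L; b <- nid + 2L; nid <- nid + 2L
    nodes[[a]] <- data.frame(id = a, x = x, y = y, z = z0)
    nodes[[b]] <- data.frame(id = b, x = x, y = y, z = z1)
    segs[[length(segs) + 1L]] <-
      list(id = length(segs) + 1L, nodes = c(a, b),
           points = rbind(c(x, y, z0), c(x, y, z1)),
           radii = rep(radius, 2))
  }
  network_topology(do.call(rbind, nodes), segs)
}
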