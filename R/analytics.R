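#' Branch counts from a feeder vessel
#'
#' For every node, the number of edges on a minimum-edge path from the
#' source node (breadth-first distance on the segment multigraph). This is
#' the "branch separation" used to colour networks by distance from the
#' feeding artery or draining vein. Nodes in other components are flagged
#' as unreachable rather than silently set to 0.
#'
#' @param net a [network_topology()].
#' @param source node id of the feeder (e.g. where the artery enters).
#' @return An object of class `BranchCountMap`: list with `source_node`,
#'   `counts` (named integer vector over node ids; `NA` for unreachable
#'   nodes) and `unreachable` (node ids).
#' @export
branch_counts <- function(net, source) {
  if (!source %in% net$nodes$id) stop("unknown source node id: ", source)
  g <- as_network_igraph(net)
  dvec <- igraph::distances(g, v = as.character(source), weights = NA)[1, ]
  counts <- suppressWarnings(as.integer(dvec))
  counts[is.infinite(dvec)] <- NA_integer_
  names(counts) <- names(dvec)
  counts <- counts[as.character(net$nodes$id)]
  structure(list(
    source_node = source,
    counts = counts,
    unreachable = net$nodes$id[is.na(counts)]
  ), class = "BranchCountMap")
}

#' Suggest feeder-node candidates
#'
#' The feed artery and exit vein are the widest vessels entering the
#' network; candidate source nodes are degree-1 nodes ranked by the
#' diameter of their incident segment.
#'
#' @param net a [network_topology()].
#' @param n number of candidates to return.
#' @return data.frame with `node`, `diameter` (um), sorted widest first.
#' @export
suggest_feeder_nodes <- function(net, n = 5L) {
  deg <- node_degrees(net)
  st <- segment_table(net)
  ends <- names(deg)[deg == 1L]
  if (length(ends) == 0L)
    return(data.frame(node = numeric(0), diameter = numeric(0)))
  dia <- vapply(ends, function(nid) {
    max(st$diameter[st$node_a == as.numeric(nid) |
                      st$node_b == as.numeric(nid)])
  }, numeric(1))
  o <- order(dia, decreasing = TRUE)
  data.frame(node = as.numeric(ends[o]), diameter = unname(dia[o]))[
    seq_len(min(n, length(ends))), ]
}

#' Select a subnetwork by segment diameter and length
#'
#' Keeps segments whose mean diameter lies in `[dmin, dmax]` and whose
#' length is at least `min_length`; nodes without any kept segment are
#' dropped. The result may be disconnected. The putative-HEV preset is
#' diameter 16-32 um with length >= 40 um; vessels above 15 um diameter
#' separate the arterial and venous trees.
#'
#' @param net a [network_topology()].
#' @param dmin,dmax diameter window in um (`dmax` may be `Inf`).
#' @param min_length minimum segment length in um.
#' @param exclude_segments segment ids to drop regardless (e.g. manually
#'   identified arterial branches).
#' @return A [network_topology()] with original ids preserved.
#' @export
select_by_diameter <- function(net, dmin, dmax = Inf, min_length = 0,
                               exclude_segments = integer(0)) {
  stopifnot(dmin <= dmax)
  st <- segment_table(net)
  keep <- st$diameter >= dmin & st$diameter <= dmax &
    st$length >= min_length & !(st$id %in% exclude_segments)
  net$segments <- net$segments[keep]
  drop_orphan_nodes(net)
}

#' Split a thresholded network into candidate arterial/venous trees
#'
#' Applies [select_by_diameter()] with `dmin` (no upper bound), splits the
#' result into connected components, and returns the two largest as the
#' candidate arterial and venous trees (no flow direction is inferred).
#'
#' @param net a [network_topology()].
#' @param dmin diameter threshold in um (15 um excludes the capillary bed).
#' @return list of up to two [network_topology()] objects, largest first
#'   (by total segment length).
#' @export
split_trees <- function(net, dmin = 15) {
  sub <- select_by_diameter(net, dmin)
  if (length(sub$segments) == 0L) return(list())
  g <- as_network_igraph(sub)
  comp <- igraph::components(g)
  memb <- comp$membership
  nets <- lapply(seq_len(comp$no), function(ci) {
    nids <- as.numeric(names(memb)[memb == ci])
    s <- sub
    s$segments <- s$segments[vapply(s$segments,
                                    function(x) all(x$nodes %in% nids),
                                    logical(1))]
    s$nodes <- s$nodes[s$nodes$id %in% nids, , drop = FALSE]
    s
  })
  len <- vapply(nets, function(s) sum(segment_table(s)$length), numeric(1))
  nets <- nets[order(len, decreasing = TRUE)]
  nets[seq_len(min(2L, length(nets)))]
}

#' Delineate the organ region from the vessel mask
#'
#' Morphological closing of the vessel mask with a ball of
#' `closing_radius` followed by hole filling (background components not
#' 6-connected to the volume border become foreground). The result is an
#' estimate of the tissue region the network supplies and is always a
#' superset of the vessel mask.
#'
#' @param mask the final vessel [binary_mask()].
#' @param closing_radius ball radius in um (0 = hole filling only).
#' @return A [binary_mask()].
#' @export
ln_region <- function(mask, closing_radius = 60) {
  stopifnot(inherits(mask, "BinaryMask"), closing_radius >= 0)
  d <- dim(mask$values)
  vals <- mask$values
  if (closing_radius > 0 && any(vals)) {
    rvox <- closing_radius / mask$voxel_size
    dil <- array(cpp_edt_sq(as.logical(vals), d) <= rvox^2, dim = d)
    vals <- array(cpp_edt_sq(as.logical(!dil), d) > rvox^2, dim = d)
    vals <- vals | mask$values  # guard discretisation: closing is extensive
  }
  # hole filling: background 6-components touching the border stay background
  bg <- !vals
  lab <- array(cpp_label_components(as.logical(bg), d, 6L), dim = d)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels != 0L]
  holes <- bg & !(lab %in% border_labels)
  vals <- vals | array(holes, dim = d)
  binary_mask(vals, mask$voxel_size, mask$origin)
}

#' Nearest-vessel distance field
#'
#' Overlays the region with a regular grid of the given spacing and, for
#' every grid point inside the region but outside the vessels, computes
#' the Euclidean distance (um) to the nearest vessel voxel center.
#'
#' @param region organ-region [binary_mask()].
#' @param vessels vessel [binary_mask()], same geometry.
#' @param spacing grid spacing in um; must be a positive integer multiple
#'   of the voxel size so grid points coincide with voxel centers.
#' @param void_threshold distance (um) used for the `fraction_within`
#'   summary (fraction of interior points within this distance).
#' @return An object of class `DistanceField`: list with `spacing`,
#'   `voxel_size`, `origin`, `grid_dim`, `points` (n x 3 matrix of
#'   0-based grid indices), `coords` (n x 3 um), `distances` (um) and
#'   `summary` (mean, 1-um-bin histogram, `fraction_within`,
#'   `void_threshold`).
#' @export
distance_field <- function(region, vessels, spacing = 4,
                           void_threshold = 60) {
  stopifnot(inherits(region, "BinaryMask"), inherits(vessels, "BinaryMask"))
  if (!same_geometry(region, vessels))
    stop("region and vessel geometries differ")
  if (!any(vessels$values))
    stop("empty vessel mask: distances are undefined")
  vs <- region$voxel_size
  stride <- spacing / vs
  if (abs(stride - round(stride)) > 1e-9 || stride < 1)
    stop("spacing must be a positive integer multiple of the voxel size")
  stride <- as.integer(round(stride))
  d <- dim(region$values)
  dist_um <- sqrt(cpp_edt_sq(as.logical(vessels$values), d)) * vs
  dist_um <- array(dist_um, dim = d)

  gi <- seq(1L, d[1], by = stride)
  gj <- seq(1L, d[2], by = stride)
  gk <- seq(1L, d[3], by = stride)
  sub_region <- region$values[gi, gj, gk, drop = FALSE]
  sub_vessel <- vessels$values[gi, gj, gk, drop = FALSE]
  sub_dist <- dist_um[gi, gj, gk, drop = FALSE]
  keep <- sub_region & !sub_vessel
  w <- which(keep)
  gco <- arrayInd(w, dim(sub_region))          # 1-based grid indices
  dists <- sub_dist[w]
  coords <- sweep((gco - 1) * spacing, 2L, region$origin, "+")

  h <- if (length(dists)) {
    b <- floor(dists)
    table(factor(b, levels = seq(0, max(b))))
  } else integer(0)
  structure(list(
    spacing = spacing, voxel_size = vs, origin = region$origin,
    grid_dim = dim(sub_region),
    points = gco - 1L, coords = coords, distances = dists,
    summary = list(
      mean = if (length(dists)) mean(dists) else NA_real_,
      histogram = h,
      fraction_within = if (length(dists)) mean(dists <= void_threshold)
        else NA_real_,
      void_threshold = void_threshold
    )
  ), class = "DistanceField")
}

#' @export
print.DistanceField <- function(x, ...) {
  cat(sprintf(
    "DistanceField: %d interior points at %g um spacing, mean %.2f um\n",
    length(x$distances), x$spacing, x$summary$mean))
  cat(sprintf("  %.2f%% of points within %g um of a vessel\n",
              100 * x$summary$fraction_within, x$summary$void_threshold))
  invisible(x)
}

#' Detect vascular voids
#'
#' Returns, at the distance-grid resolution, the mask of interior points
#' lying farther than `threshold` from any vessel — candidate
#' under-supplied tissue locations. Write it with [write_stack()] to get
#' the white-voxel void TIFF used for 3D visualisation.
#'
#' @param df a [distance_field()].
#' @param threshold distance in um (> 0); the conventional void threshold
#'   is 60 um.
#' @return A [binary_mask()] on the distance grid (voxel size = spacing).
#' @export
find_voids <- function(df, threshold = 60) {
  stopifnot(inherits(df, "DistanceField"), threshold > 0)
  vals <- array(FALSE, dim = df$grid_dim)
  far <- df$distances > threshold
  if (any(far)) vals[df$points[far, , drop = FALSE] + 1L] <- TRUE
  binary_mask(vals, df$spacing, df$origin)
}

#' Virtual 2D histology: vessels crossing a plane
#'
#' Records one intersection wherever a segment's centerline polyline
#' crosses an axis-aligned plane (a tangential touch where consecutive
#' points lie exactly on the plane counts once). The local diameter is
#' linearly interpolated between the bracketing centerline points, and
#' the density is crossings per mm^2 of region cross-section.
#'
#' @param net a [network_topology()].
#' @param region organ-region [binary_mask()] (used for the cross-section
#'   area and bounds).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param coordinate plane position in um.
#' @return An object of class `HistologyResult`: list with `axis`,
#'   `coordinate`, `intersections` (data.frame: `segment`, `x`, `y`, `z`,
#'   `diameter`), `area_mm2` and `density` (per mm^2).
#' @export
histology_2d <- function(net, region, axis = c("z", "x", "y"), coordinate) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  d <- dim(region$values)
  lo <- region$origin[ax]
  hi <- region$origin[ax] + (d[ax] - 1) * region$voxel_size
  if (coordinate < lo || coordinate > hi)
    stop(sprintf("plane %s = %g um lies outside the volume [%g, %g]",
                 axis, coordinate, lo, hi))
  hits <- list()
  for (seg in net$segments) {
    p <- seg$points
    s <- p[, ax] - coordinate
    dia <- 2 * seg$radii
    i <- 1L
    n <- nrow(p)
    while (i < n) {
      if (s[i] == 0) {
        # touch (or start of a tangential run): count once, then skip the run
        j <- i
        while (j < n && s[j + 1] == 0) j <- j + 1L
        hits[[length(hits) + 1L]] <-
          c(seg$id, p[i, ], dia[i])
        # only a crossing if the signs on both sides differ; either way the
        # run itself was counted once
        i <- j + 1L
      } else if (s[i] * s[i + 1] < 0) {
        t <- s[i] / (s[i] - s[i + 1])
        pos <- p[i, ] + t * (p[i + 1, ] - p[i, ])
        hits[[length(hits) + 1L]] <-
          c(seg$id, pos, (1 - t) * dia[i] + t * dia[i + 1])
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
    if (n >= 1L && s[n] == 0 && (n == 1L || s[n - 1] != 0)) {
      hits[[length(hits) + 1L]] <- c(seg$id, p[n, ], dia[n])
    }
  }
  inter <- if (length(hits)) {
    m <- do.call(rbind, hits)
    data.frame(segment = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4],
               diameter = m[, 5])
  } else {
    data.frame(segment = numeric(0), x = numeric(0), y = numeric(0),
               z = numeric(0), diameter = numeric(0))
  }
  k <- round((coordinate - region$origin[ax]) / region$voxel_size) + 1L
  k <- min(max(k, 1L), d[ax])
  slice_n <- switch(axis,
                    x = sum(region$values[k, , ]),
                    y = sum(region$values[, k, ]),
                    z = sum(region$values[, , k]))
  area_mm2 <- slice_n * region$voxel_size^2 / 1e6
  structure(list(
    axis = axis, coordinate = coordinate, intersections = inter,
    area_mm2 = area_mm2,
    density = if (area_mm2 > 0) nrow(inter) / area_mm2 else NA_real_
  ), class = "HistologyResult")
}

# arc-length midpoint of a polyline
.polyline_midpoint <- function(p) {
  if (nrow(p) == 1L) return(p[1, ])
  seglen <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  total <- sum(seglen)
  if (total == 0) return(p[1, ])
  target <- total / 2
  cum <- c(0, cumsum(seglen))
  i <- max(which(cum <= target))
  i <- min(i, nrow(p) - 1L)
  t <- if (seglen[i] > 0) (target - cum[i]) / seglen[i] else 0
  p[i, ] + t * (p[i + 1, ] - p[i, ])
}

#' Subregion statistics for a rectangular block
#'
#' Computes, over an axis-aligned block (typically 100^3 voxels, about
#' 200 um per side at 2 um resolution): the mean nearest-vessel distance
#' over distance-field points in the block, the 3D vessel density as the
#' count of segments whose arc-length midpoint falls in the block divided
#' by the block volume, the 2D density from a virtual histology plane
#' through the block center, and the mean diameter of the midpoint
#' segments. The midpoint rule makes 3D counts additive over a partition
#' into blocks.
#'
#' @param net a [network_topology()].
#' @param df a [distance_field()] for the same volume.
#' @param block_origin um triple: block corner.
#' @param block_size um triple: block extents (> 0).
#' @param label free-text label for the region.
#' @return An object of class `RegionStats`: list with `label`,
#'   `mean_distance` (um), `density_3d` (segments/mm^3), `density_2d`
#'   (intersections/mm^2), `mean_diameter` (um), `n_segments`.
#' @export
region_stats <- function(net, df, block_origin, block_size,
                         label = "") {
  stopifnot(length(block_origin) == 3L, length(block_size) == 3L)
  if (any(block_size <= 0)) stop("empty block")
  lo <- as.numeric(block_origin)
  hi <- lo + as.numeric(block_size)

  inb <- df$coords[, 1] >= lo[1] & df$coords[, 1] < hi[1] &
    df$coords[, 2] >= lo[2] & df$coords[, 2] < hi[2] &
    df$coords[, 3] >= lo[3] & df$coords[, 3] < hi[3]
  mean_dist <- if (any(inb)) mean(df$distances[inb]) else NA_real_

  mids <- t(vapply(net$segments, function(s) .polyline_midpoint(s$points),
                   numeric(3)))
  if (length(net$segments) == 0L) mids <- matrix(numeric(0), ncol = 3)
  inm <- mids[, 1] >= lo[1] & mids[, 1] < hi[1] &
    mids[, 2] >= lo[2] & mids[, 2] < hi[2] &
    mids[, 3] >= lo[3] & mids[, 3] < hi[3]
  vol_mm3 <- prod(block_size) / 1e9
  st <- segment_table(net)

  # central z-plane histology restricted to the block footprint
  zc <- lo[3] + block_size[3] / 2
  crossings <- 0L
  for (seg in net$segments) {
    p <- seg$points
    s <- p[, 3] - zc
    for (i in seq_len(nrow(p) - 1L)) {
      if (s[i] * s[i + 1] < 0 || (s[i] == 0 && s[i + 1] != 0 &&
                                  (i == 1L || s[i - 1] != 0))) {
        t <- s[i] / (s[i] - s[i + 1])
        pos <- p[i, ] + t * (p[i + 1, ] - p[i, ])
        if (pos[1] >= lo[1] && pos[1] < hi[1] &&
            pos[2] >= lo[2] && pos[2] < hi[2])
          crossings <- crossings + 1L
      }
    }
  }
  area_mm2 <- block_size[1] * block_size[2] / 1e6

  structure(list(
    label = label,
    mean_distance = mean_dist,
    density_3d = sum(inm) / vol_mm3,
    density_2d = crossings / area_mm2,
    mean_diameter = if (any(inm)) mean(st$diameter[inm]) else NA_real_,
    n_segments = sum(inm)
  ), class = "RegionStats")
}
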