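#' Geometric network description ("topology map")
#'
#' A `NetworkTopology` holds the geometric description of a vascular
#' network: nodes (junctions and endpoints) and segments (vessel runs
#' between nodes), each segment carrying an ordered centerline polyline and
#' a radius at every polyline point. Positions and radii are in
#' micrometres. Self-loops and multi-edges are supported (capillary beds
#' contain reconnecting arcades).
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (um).
#' @param segments list; each element a list with `id`, `nodes` (length-2
#'   vector of node ids, order matching the polyline direction), `points`
#'   (n x 3 matrix of um coordinates from the first node to the second) and
#'   `radii` (length-n positive numeric, um).
#' @param voxel_size voxel size (um) of the source image, kept as provenance.
#' @return An object of class `NetworkTopology`.
#' @export
network_topology <- function(nodes, segments, voxel_size = NA_real_) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  net <- structure(
    list(nodes = nodes, segments = segments,
         voxel_size = as.numeric(voxel_size)),
    class = "NetworkTopology"
  )
  validate_network(net)
  net
}

#' Check NetworkTopology invariants
#'
#' Verifies that segment endpoints refer to existing nodes and coincide
#' with the node positions, that every segment has at least two polyline
#' points with one radius per point, and that all radii are positive.
#'
#' @param net a [network_topology()].
#' @param tol positional tolerance in um for endpoint/node agreement.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net, tol = 1e-6) {
  ids <- net$nodes$id
  pos <- as.matrix(net$nodes[, c("x", "y", "z")])
  rownames(pos) <- as.character(ids)
  for (seg in net$segments) {
    if (length(seg$nodes) != 2L) stop("segment ", seg$id, ": needs 2 node ids")
    if (!all(seg$nodes %in% ids))
      stop("segment ", seg$id, ": unknown node id")
    p <- seg$points
    if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L)
      stop("segment ", seg$id, ": points must be an n x 3 matrix, n >= 2")
    if (length(seg$radii) != nrow(p))
      stop("segment ", seg$id, ": one radius per point required")
    if (any(seg$radii <= 0)) stop("segment ", seg$id, ": radii must be > 0")
    a <- pos[as.character(seg$nodes[1]), ]
    b <- pos[as.character(seg$nodes[2]), ]
    if (max(abs(p[1, ] - a)) > tol || max(abs(p[nrow(p), ] - b)) > tol)
      stop("segment ", seg$id, ": endpoints do not coincide with its nodes")
  }
  invisible(net)
}

#' @export
print.NetworkTopology <- function(x, ...) {
  cat(sprintf("NetworkTopology: %d nodes, %d segments\n",
              nrow(x$nodes), length(x$segments)))
  if (length(x$segments)) {
    st <- segment_table(x)
    cat(sprintf("  diameters %.2f-%.2f um, total length %.3g cm\n",
                min(st$diameter), max(st$diameter), sum(st$length) / 1e4))
  }
  invisible(x)
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Length-weighted mean diameter of one segment. Junction blobs inflate the
# distance-based radius estimate, so when a segment has >= 4 points its
# first and last point are excluded from the average.
segment_diameter <- function(seg) {
  p <- seg$points
  r <- seg$radii
  n <- nrow(p)
  keep <- if (n >= 4L) 2:(n - 1L) else seq_len(n)
  p <- p[keep, , drop = FALSE]
  r <- r[keep]
  if (nrow(p) < 2L) return(2 * mean(r))
  h <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  dmid <- (r[-1] + r[-length(r)])  # mean diameter of each interval (2*(r1+r2)/2)
  if (sum(h) == 0) return(2 * mean(r))
  sum(dmid * h) / sum(h)
}

# Sum of conical-frustum volumes between consecutive polyline points (um^3).
segment_volume <- function(seg) {
  p <- seg$points
  r <- seg$radii
  if (nrow(p) < 2L) return(0)
  h <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  r1 <- r[-length(r)]
  r2 <- r[-1]
  sum(pi / 3 * h * (r1^2 + r1 * r2 + r2^2))
}

#' Per-segment geometry table
#'
#' @param net a [network_topology()].
#' @return data.frame with one row per segment: `id`, `node_a`, `node_b`,
#'   `n_points`, `length` (um), `diameter` (um, length-weighted mean of
#'   point diameters), `volume` (um^3, conical frusta).
#' @export
segment_table <- function(net) {
  if (length(net$segments) == 0L)
    return(data.frame(id = integer(), node_a = integer(), node_b = integer(),
                      n_points = integer(), length = numeric(),
                      diameter = numeric(), volume = numeric()))
  data.frame(
    id = vapply(net$segments, function(s) as.integer(s$id), integer(1)),
    node_a = vapply(net$segments, function(s) as.integer(s$nodes[1]), integer(1)),
    node_b = vapply(net$segments, function(s) as.integer(s$nodes[2]), integer(1)),
    n_points = vapply(net$segments, function(s) nrow(s$points), integer(1)),
    length = vapply(net$segments, function(s) polyline_length(s$points),
                    numeric(1)),
    diameter = vapply(net$segments, segment_diameter, numeric(1)),
    volume = vapply(net$segments, segment_volume, numeric(1))
  )
}

#' Node degrees (incident segment ends; a self-loop contributes two)
#'
#' @param net a [network_topology()].
#' @return named integer vector, names are node ids.
#' @export
node_degrees <- function(net) {
  deg <- setNames(integer(nrow(net$nodes)), as.character(net$nodes$id))
  for (seg in net$segments) {
    deg[as.character(seg$nodes[1])] <- deg[as.character(seg$nodes[1])] + 1L
    deg[as.character(seg$nodes[2])] <- deg[as.character(seg$nodes[2])] + 1L
  }
  deg
}

# igraph view of the network (multigraph; self-loops kept).
as_network_igraph <- function(net) {
  ids <- as.character(net$nodes$id)
  if (length(net$segments)) {
    el <- t(vapply(net$segments, function(s) as.character(s$nodes),
                   character(2)))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  }
  g
}

#' Summarise a network
#'
#' Computes the standard morphometric summary of a topology map: segment
#' and node counts, mean segment diameter and length, total network length
#' and volume, and 1-um-bin histograms of diameters and lengths.
#'
#' @param object a [network_topology()].
#' @param ... unused.
#' @return An object of class `NetworkSummary`: list with `n_segments`,
#'   `n_nodes`, `mean_diameter` (um), `mean_length` (um), `total_length`
#'   (cm), `total_volume` (mm^3), `diameter_histogram` and
#'   `length_histogram` (named counts, 1 um bins labelled by lower edge).
#' @export
summary.NetworkTopology <- function(object, ...) {
  st <- segment_table(object)
  hist1 <- function(x) {
    if (length(x) == 0L) return(integer(0))
    b <- floor(x)
    table(factor(b, levels = seq(min(b), max(b))))
  }
  structure(list(
    n_segments = nrow(st),
    n_nodes = nrow(object$nodes),
    mean_diameter = if (nrow(st)) mean(st$diameter) else 0,
    mean_length = if (nrow(st)) mean(st$length) else 0,
    total_length = sum(st$length) / 1e4,   # um -> cm
    total_volume = sum(st$volume) / 1e9,   # um^3 -> mm^3
    diameter_histogram = hist1(st$diameter),
    length_histogram = hist1(st$length)
  ), class = "NetworkSummary")
}

#' @export
print.NetworkSummary <- function(x, ...) {
  cat("Network summary\n")
  cat(sprintf("  segments:       %d\n", x$n_segments))
  cat(sprintf("  nodes:          %d\n", x$n_nodes))
  cat(sprintf("  mean diameter:  %.2f um\n", x$mean_diameter))
  cat(sprintf("  mean length:    %.2f um\n", x$mean_length))
  cat(sprintf("  total length:   %.4g cm\n", x$total_length))
  cat(sprintf("  total volume:   %.4g mm^3\n", x$total_volume))
  invisible(x)
}
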