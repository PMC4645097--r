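#' Write a network as an Amira SpatialGraph (AmiraMesh 3D ASCII)
#'
#' Emits the standard HxSpatialGraph layout: VERTEX/VertexCoordinates,
#' EDGE/EdgeConnectivity, EDGE/NumEdgePoints, POINT/EdgePointCoordinates
#' and POINT/thickness. Coordinates are in micrometres; per-point
#' thickness stores the radius (the common SpatialGraph convention).
#' Numbers are written with fixed 6-decimal formatting so output is
#' byte-identical for identical input. Vertex indices are 0-based;
#' self-loop edges (both endpoints equal) are legal.
#'
#' @param net a [network_topology()].
#' @param path output file path.
#' @param point_field optional list `list(name =, values =)` adding one
#'   extra float per edge point (used by [attribute_export()]).
#' @return `path`, invisibly.
#' @export
write_spatialgraph <- function(net, path, point_field = NULL) {
  net <- renumber_network(net)
  nv <- nrow(net$nodes)
  ne <- length(net$segments)
  npts <- sum(vapply(net$segments, function(s) nrow(s$points), integer(1)))
  num <- function(x) sprintf("%.6f", x)
  con <- file(path, open = "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con, sep = "\n")
  w("# AmiraMesh 3D ASCII 2.0", "",
    sprintf("define VERTEX %d", nv),
    sprintf("define EDGE %d", ne),
    sprintf("define POINT %d", npts), "",
    "Parameters {",
    "    ContentType \"HxSpatialGraph\"",
    "}", "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "POINT { float thickness } @5")
  if (!is.null(point_field))
    w(sprintf("POINT { float %s } @6", point_field$name))
  w("", "@1")
  w(paste(num(net$nodes$x), num(net$nodes$y), num(net$nodes$z)))
  w("", "@2")
  idmap <- setNames(seq_len(nv) - 1L, as.character(net$nodes$id))
  w(vapply(net$segments, function(s)
    paste(idmap[as.character(s$nodes[1])], idmap[as.character(s$nodes[2])]),
    character(1)))
  w("", "@3")
  w(vapply(net$segments, function(s) sprintf("%d", nrow(s$points)),
           character(1)))
  w("", "@4")
  for (s in net$segments)
    w(paste(num(s$points[, 1]), num(s$points[, 2]), num(s$points[, 3])))
  w("", "@5")
  for (s in net$segments) w(num(s$radii))
  if (!is.null(point_field)) {
    w("", "@6")
    w(num(point_field$values))
  }
  invisible(path)
}

#' Read a SpatialGraph written by [write_spatialgraph()]
#'
#' Parses the ASCII AmiraMesh sections back into a network; positions are
#' preserved to the writer's 1e-6 um formatting.
#'
#' @param path SpatialGraph file path.
#' @return A [network_topology()].
#' @export
read_spatialgraph <- function(path) {
  lines <- readLines(path)
  getdef <- function(what) {
    ln <- grep(sprintf("^define %s ", what), lines, value = TRUE)
    as.integer(sub(sprintf("define %s ", what), "", ln[1]))
  }
  nv <- getdef("VERTEX"); ne <- getdef("EDGE"); npts <- getdef("POINT")
  section <- function(tag, n) {
    start <- grep(sprintf("^@%d$", tag), lines)[1]
    block <- lines[(start + 1):(start + n)]
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
  }
  vc <- section(1, nv)
  ec <- if (ne > 0) matrix(section(2, ne), ncol = 2) else
    matrix(numeric(0), ncol = 2)
  nep <- if (ne > 0) as.integer(section(3, ne)) else integer(0)
  pc <- if (npts > 0) section(4, npts) else matrix(numeric(0), ncol = 3)
  th <- if (npts > 0) as.numeric(section(5, npts)) else numeric(0)

  nodes <- data.frame(id = seq_len(nv), x = vc[, 1], y = vc[, 2], z = vc[, 3])
  segments <- list()
  off <- 0L
  for (e in seq_len(ne)) {
    n <- nep[e]
    pts <- pc[off + seq_len(n), , drop = FALSE]
    a <- as.integer(ec[e, 1]) + 1L
    b <- as.integer(ec[e, 2]) + 1L
    # snap endpoints onto the vertex coordinates (formatting round-trip)
    pts[1, ] <- as.numeric(nodes[a, c("x", "y", "z")])
    pts[n, ] <- as.numeric(nodes[b, c("x", "y", "z")])
    segments[[e]] <- list(id = e, nodes = c(a, b), points = pts,
                          radii = th[off + seq_len(n)])
    off <- off + n
  }
  network_topology(nodes, segments, NA_real_)
}

#' Write a network in CMGUI exnode/exelem format
#'
#' Minimal self-consistent dialect: `basename.exnode` holds node
#' coordinates (um) plus a radius field (mean radius of the incident
#' segment ends); `basename.exelem` holds 1D linear elements joining the
#' segment endpoint nodes. Node numbers are contiguous from 1 regardless
#' of internal ids.
#'
#' @param net a [network_topology()].
#' @param basename output path without extension.
#' @param group group name written into both files.
#' @return character vector of the two paths, invisibly.
#' @export
write_cmgui <- function(net, basename, group = "vessels") {
  net <- renumber_network(net)
  exnode <- paste0(basename, ".exnode")
  exelem <- paste0(basename, ".exelem")

  # node radius: mean of the incident segment-end radii
  radsum <- setNames(numeric(nrow(net$nodes)), as.character(net$nodes$id))
  radn <- radsum
  for (s in net$segments) {
    a <- as.character(s$nodes[1]); b <- as.character(s$nodes[2])
    radsum[a] <- radsum[a] + s$radii[1]; radn[a] <- radn[a] + 1
    radsum[b] <- radsum[b] + s$radii[length(s$radii)]; radn[b] <- radn[b] + 1
  }
  nr <- ifelse(radn > 0, radsum / pmax(radn, 1), 0)

  con <- file(exnode, open = "wb")
  writeLines(c(
    sprintf(" Group name: %s", group),
    " #Fields=2",
    " 1) coordinates, coordinate, rectangular cartesian, #Components=3",
    "   x.  Value index= 1, #Derivatives= 0",
    "   y.  Value index= 2, #Derivatives= 0",
    "   z.  Value index= 3, #Derivatives= 0",
    " 2) radius, field, rectangular cartesian, #Components=1",
    "   r.  Value index= 4, #Derivatives= 0"), con)
  for (i in seq_len(nrow(net$nodes))) {
    writeLines(c(sprintf(" Node: %d", net$nodes$id[i]),
                 sprintf("  %.6f %.6f %.6f %.6f", net$nodes$x[i],
                         net$nodes$y[i], net$nodes$z[i],
                         nr[as.character(net$nodes$id[i])])), con)
  }
  close(con)

  con <- file(exelem, open = "wb")
  writeLines(c(
    sprintf(" Group name: %s", group),
    " Shape.  Dimension=1",
    " #Scale factor sets= 0",
    " #Nodes= 2",
    " #Fields=1",
    " 1) coordinates, coordinate, rectangular cartesian, #Components=3",
    "   x.  l.Lagrange, no modify, standard node based.",
    "     #Nodes= 2",
    "      1.  #Values=1",
    "       Value indices:     1",
    "      2.  #Values=1",
    "       Value indices:     1",
    "   y.  l.Lagrange, no modify, standard node based.",
    "     #Nodes= 2",
    "      1.  #Values=1",
    "       Value indices:     2",
    "      2.  #Values=1",
    "       Value indices:     2",
    "   z.  l.Lagrange, no modify, standard node based.",
    "     #Nodes= 2",
    "      1.  #Values=1",
    "       Value indices:     3",
    "      2.  #Values=1",
    "       Value indices:     3"), con)
  for (s in net$segments) {
    writeLines(c(sprintf(" Element: %d 0 0", s$id),
                 "   Nodes:",
                 sprintf("     %d %d", s$nodes[1], s$nodes[2])), con)
  }
  close(con)
  invisible(c(exnode, exelem))
}

#' Serialise / load a network as JSON
#'
#' Schema: `{voxel_size, nodes: [{id, pos, segs}], segments:
#' [{id, nodes, points, radii}]}` with positions in um. Round-trips the
#' graph exactly and positions at full double precision.
#'
#' @param net a [network_topology()].
#' @param path output file path.
#' @return `path` (write) / a [network_topology()] (read).
#' @export
write_network_json <- function(net, path) {
  seg_ids_by_node <- lapply(net$nodes$id, function(nid) {
    ids <- vapply(net$segments, function(s)
      if (any(s$nodes == nid)) s$id else NA_integer_, numeric(1))
    as.integer(ids[!is.na(ids)])
  })
  doc <- list(
    voxel_size = if (is.na(net$voxel_size)) NULL else net$voxel_size,
    nodes = lapply(seq_len(nrow(net$nodes)), function(i) list(
      id = net$nodes$id[i],
      pos = as.numeric(net$nodes[i, c("x", "y", "z")]),
      segs = seg_ids_by_node[[i]]
    )),
    segments = lapply(net$segments, function(s) list(
      id = s$id, nodes = s$nodes,
      points = unname(as.matrix(s$points)), radii = s$radii
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  nodes <- do.call(rbind, lapply(doc$nodes, function(n)
    data.frame(id = n$id, x = n$pos[1], y = n$pos[2], z = n$pos[3])))
  segments <- lapply(doc$segments, function(s) list(
    id = as.integer(s$id), nodes = as.numeric(s$nodes),
    points = matrix(as.numeric(s$points), ncol = 3),
    radii = as.numeric(s$radii)
  ))
  vs <- if (is.null(doc$voxel_size)) NA_real_ else as.numeric(doc$voxel_size)
  network_topology(nodes, segments, vs)
}

#' Export a node or segment attribute for colour mapping
#'
#' Writes a CSV of `(id, value)` pairs plus a SpatialGraph carrying the
#' attribute as an extra per-point float field, ready for rainbow colour
#' mapping in a 3D viewer (no rendering is done here). Segment attributes
#' are constant along each segment's points; node attributes are linearly
#' interpolated along the polyline between the two endpoint values.
#'
#' @param net a [network_topology()].
#' @param values numeric vector named by node ids (`kind = "node"`) or
#'   segment ids (`kind = "segment"`); every element must be covered.
#' @param kind `"segment"` or `"node"`.
#' @param csv_path CSV output path.
#' @param spatialgraph_path optional SpatialGraph output path.
#' @param field_name name of the per-point field.
#' @return invisible list of written paths.
#' @export
attribute_export <- function(net, values, kind = c("segment", "node"),
                             csv_path, spatialgraph_path = NULL,
                             field_name = "attribute") {
  kind <- match.arg(kind)
  ids <- if (kind == "segment")
    vapply(net$segments, function(s) s$id, numeric(1)) else net$nodes$id
  missing_ids <- setdiff(as.character(ids), names(values))
  if (length(missing_ids))
    stop("missing ", kind, " values for ids: ",
         paste(missing_ids, collapse = ", "))
  df <- data.frame(id = ids, value = as.numeric(values[as.character(ids)]))
  utils::write.csv(df, csv_path, row.names = FALSE)
  paths <- csv_path
  if (!is.null(spatialgraph_path)) {
    per_point <- unlist(lapply(net$segments, function(s) {
      n <- nrow(s$points)
      if (kind == "segment") {
        rep(values[as.character(s$id)], n)
      } else {
        va <- values[as.character(s$nodes[1])]
        vb <- values[as.character(s$nodes[2])]
        seq(va, vb, length.out = n)
      }
    }))
    write_spatialgraph(net, spatialgraph_path,
                       point_field = list(name = field_name,
                                          values = unname(per_point)))
    paths <- c(paths, spatialgraph_path)
  }
  invisible(paths)
}
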