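#' Skeletonise a binary network to one-voxel-wide centerlines
#'
#' Iterative topology-preserving 3D thinning: voxels are removed only when
#' they are simple points for (26, 6) connectivity (foreground stays
#' 26-connected, background 6-connected), never when they are curve
#' endpoints, in six directional subiterations per cycle until no voxel
#' can be removed. Connected components and independent loops of the input
#' are preserved.
#'
#' @param mask a [binary_mask()] (normally the filled, single-component
#'   vessel network).
#' @return A [binary_mask()] holding the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "BinaryMask"))
  d <- dim(mask$values)
  out <- cpp_thin(as.logical(mask$values), d)
  binary_mask(array(out, dim = d), mask$voxel_size, mask$origin)
}

#' Estimate vessel radii along the skeleton
#'
#' The radius at a skeleton voxel is its Euclidean distance to the nearest
#' off voxel of the vessel mask, in micrometres (distance-transform
#' estimate; voxel-center convention).
#'
#' @param skeleton a [binary_mask()] with the skeleton; must be a subset
#'   of `mask`.
#' @param mask the filled vessel [binary_mask()].
#' @return A 3D numeric array of radii (um) at skeleton voxels, `NA`
#'   elsewhere, with attribute `voxel_size`.
#' @export
estimate_radii <- function(skeleton, mask) {
  stopifnot(inherits(skeleton, "BinaryMask"), inherits(mask, "BinaryMask"))
  if (!same_geometry(skeleton, mask))
    stop("skeleton and mask geometries differ")
  if (any(skeleton$values & !mask$values))
    stop("skeleton voxels outside the vessel mask")
  d <- dim(mask$values)
  edt <- cpp_edt_sq(as.logical(!mask$values), d)  # distance to nearest off
  r <- array(NA_real_, dim = d)
  idx <- which(skeleton$values)
  r[idx] <- sqrt(edt[idx]) * mask$voxel_size
  attr(r, "voxel_size") <- mask$voxel_size
  r
}

# 26-neighbour adjacency of a set of voxels.
# Returns a 2-column matrix of 1-based positions into `idx` (a < b).
.skeleton_edges <- function(idx, d) {
  if (length(idx) == 0L) return(matrix(integer(0), ncol = 2))
  lab <- array(0L, dim = d)
  lab[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep each unordered pair once: only "positive" offsets
  offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 1] > 0))), ,
               drop = FALSE]
  ea <- integer(0); eb <- integer(0)
  for (t in seq_len(nrow(offs))) {
    ni <- co[, 1] + offs[t, 1]
    nj <- co[, 2] + offs[t, 2]
    nk <- co[, 3] + offs[t, 3]
    ok <- ni >= 1 & nj >= 1 & nk >= 1 & ni <= d[1] & nj <= d[2] & nk <= d[3]
    if (!any(ok)) next
    nb <- integer(length(idx))
    nb[ok] <- lab[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- which(nb > 0L)
    ea <- c(ea, hit)
    eb <- c(eb, nb[hit])
  }
  cbind(ea, eb)
}

#' Euler characteristic of a voxel set
#'
#' Computes the Euler characteristic of the cubical complex spanned by the
#' on-voxels (vertices - edges + faces - cubes). For a solid object without
#' internal cavities the number of independent loops is
#' `components - euler_characteristic`, which is how topology preservation
#' of the thinning step is verified.
#'
#' @param mask a [binary_mask()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  stopifnot(inherits(mask, "BinaryMask"))
  d <- dim(mask$values)
  p <- array(FALSE, dim = d + 2L)
  p[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask$values
  pd <- dim(p)
  sh <- function(di, dj, dk) {
    p[(1 + di):(pd[1] - 1 + di), (1 + dj):(pd[2] - 1 + dj),
      (1 + dk):(pd[3] - 1 + dk)]
  }
  # corners: OR over the 8 voxels sharing each corner
  V <- sum(sh(0,0,0) | sh(1,0,0) | sh(0,1,0) | sh(0,0,1) |
             sh(1,1,0) | sh(1,0,1) | sh(0,1,1) | sh(1,1,1))
  # edges along x: OR over the 4 voxels sharing each x-edge, etc.
  Ex <- sum(sh(0,0,0) | sh(0,1,0) | sh(0,0,1) | sh(0,1,1))
  Ey <- sum(sh(0,0,0) | sh(1,0,0) | sh(0,0,1) | sh(1,0,1))
  Ez <- sum(sh(0,0,0) | sh(1,0,0) | sh(0,1,0) | sh(1,1,0))
  # faces: OR over the 2 voxels sharing each face
  Fx <- sum(sh(0,0,0) | sh(1,0,0))
  Fy <- sum(sh(0,0,0) | sh(0,1,0))
  Fz <- sum(sh(0,0,0) | sh(0,0,1))
  C <- sum(mask$values)
  as.integer(V - (Ex + Ey + Ez) + (Fx + Fy + Fz) - C)
}

#' Independent loop count of a skeleton
#'
#' First Betti number of the skeleton seen as a curve network: the
#' skeleton is traced into nodes and segments (collapsing cliques of
#' mutually adjacent junction voxels, which would otherwise masquerade as
#' tiny cycles) and `segments - nodes + components` of the resulting
#' multigraph is returned.
#'
#' @param skeleton a one-voxel-wide [binary_mask()].
#' @return Integer loop count.
#' @export
skeleton_loop_count <- function(skeleton) {
  if (!any(skeleton$values)) return(0L)
  dummy <- array(1, dim(skeleton$values))
  net <- trace_skeleton(skeleton, dummy, trim_tips = FALSE)
  if (length(net$segments) == 0L) return(0L)
  g <- as_network_igraph(net)
  as.integer(igraph::ecount(g) - igraph::vcount(g) +
               igraph::components(g)$no)
}
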