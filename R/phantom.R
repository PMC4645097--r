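#' Parametric specification of a vascular-tree phantom
#'
#' Describes a random binary branching tube tree used as a synthetic
#' stand-in for a stained microvascular volume: the tree is generated with
#' exact ground-truth topology and can be rasterised either as solid tubes
#' or as hollow tubes (luminal staining) with controllable wall gaps.
#'
#' Defaults emulate a lymph-node-like network: six bifurcation levels from
#' a 30 um radius feeder with a 0.75 child/parent radius ratio span vessel
#' diameters from roughly 8 to 60 um when rasterised at 2 um voxels.
#'
#' @param seed integer RNG seed; the generator is deterministic given the spec.
#' @param levels bifurcation depth (>= 0; 0 = a single unbranched segment).
#' @param root_position um triple, start of the root segment.
#' @param root_direction initial growth direction (normalised internally).
#' @param root_radius root vessel radius in um.
#' @param radius_ratio child/parent radius factor, in (0, 1].
#' @param segment_length um range `c(min, max)` for segment lengths.
#' @param branch_angle degree range `c(min, max)` between parent and child.
#' @param wall_thickness wall shell thickness in um (0 = solid-only phantom).
#' @param gap_fraction fraction of wall voxels deleted as contiguous
#'   patches in hollow mode, in `[0, 1)`.
#' @param gap_patch_radius radius (voxels) of the spherical wall patches
#'   carved out to emulate staining gaps.
#' @param domain_size um triple; all geometry must fit inside.
#' @param min_clearance um; when > 0, every new segment is placed so its
#'   surface stays at least this far from all non-adjacent segments
#'   (angles are resampled on conflict). 0 (the default) permits
#'   near-touching branches, which real capillary beds contain and an
#'   extractor must tolerate.
#' @param region_shape `"box"` or `"ellipsoid"` tissue region containing
#'   the tree (see [phantom_region()]).
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(seed = 1L, levels = 6L,
                         root_position = c(400, 400, 60),
                         root_direction = c(0, 0, 1),
                         root_radius = 30, radius_ratio = 0.75,
                         segment_length = c(60, 100),
                         branch_angle = c(25, 55),
                         wall_thickness = 4, gap_fraction = 0,
                         gap_patch_radius = 2,
                         domain_size = c(800, 800, 800),
                         min_clearance = 0,
                         region_shape = c("box", "ellipsoid")) {
  region_shape <- match.arg(region_shape)
  stopifnot(root_radius > 0, radius_ratio > 0, radius_ratio <= 1,
            gap_fraction >= 0, gap_fraction < 1, levels >= 0,
            length(segment_length) == 2L, segment_length[1] <= segment_length[2],
            length(branch_angle) == 2L, branch_angle[1] <= branch_angle[2],
            wall_thickness >= 0, all(domain_size > 0), min_clearance >= 0)
  structure(list(
    seed = as.integer(seed), levels = as.integer(levels),
    root_position = as.numeric(root_position),
    root_direction = as.numeric(root_direction) /
      sqrt(sum(root_direction^2)),
    root_radius = root_radius, radius_ratio = radius_ratio,
    segment_length = as.numeric(segment_length),
    branch_angle = as.numeric(branch_angle),
    wall_thickness = wall_thickness, gap_fraction = gap_fraction,
    gap_patch_radius = gap_patch_radius,
    domain_size = as.numeric(domain_size),
    min_clearance = min_clearance,
    region_shape = region_shape
  ), class = "PhantomSpec")
}

# unit vectors spanning the plane orthogonal to d
.ortho_basis <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

.fits_domain <- function(p, r, domain) {
  all(p - r >= 0) && all(p + r <= domain)
}

#' Generate a ground-truth vascular tree phantom
#'
#' Grows a full binary tree of straight tube segments: `2^(levels+1) - 1`
#' segments and `2^(levels+1)` nodes, with radii shrinking by
#' `radius_ratio` per generation and branch directions drawn uniformly
#' from the angle range, rotated uniformly about the parent axis. The two
#' children of a bifurcation leave at opposite azimuths. Geometry that
#' would leave the domain is resampled; generation fails with an error if
#' no fit is found after repeated retries.
#'
#' @param spec a [phantom_spec()].
#' @param max_retries resampling attempts per segment before giving up.
#' @return An object of class `PhantomTruth`: list with `topology` (the
#'   exact [network_topology()]), `spec`, and `region` (shape + domain,
#'   rasterised on demand by [phantom_region()]).
#' @export
generate_tree <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  with_seed(spec$seed, {
    nodes <- list()
    segments <- list()
    add_node <- function(p) {
      id <- length(nodes) + 1L
      nodes[[id]] <<- c(id = id, x = p[1], y = p[2], z = p[3])
      id
    }
    root_id <- add_node(spec$root_position)
    if (!.fits_domain(spec$root_position, spec$root_radius, spec$domain_size))
      stop("root position does not fit inside the domain")

    # chord cache for clearance checks: x1,y1,z1,x2,y2,z2,r,node_a,node_b
    chords <- matrix(numeric(0), ncol = 9)

    clear_ok <- function(p1, p2, r, node_a) {
      if (spec$min_clearance <= 0 || nrow(chords) == 0L) return(TRUE)
      for (s in seq_len(nrow(chords))) {
        if (chords[s, 8] == node_a || chords[s, 9] == node_a) next
        gap <- .segseg_dist(p1, p2, chords[s, 1:3], chords[s, 4:6]) -
          r - chords[s, 7]
        if (gap < spec$min_clearance) return(FALSE)
      }
      TRUE
    }

    place_segment <- function(node_id, pos, dir, depth) {
      radius <- spec$root_radius * spec$radius_ratio^depth
      for (try in seq_len(max_retries)) {
        len <- stats::runif(1, spec$segment_length[1], spec$segment_length[2])
        end <- pos + len * dir
        if (.fits_domain(end, radius, spec$domain_size) &&
            clear_ok(pos, end, radius, node_id)) {
          end_id <- add_node(end)
          sid <- length(segments) + 1L
          # polyline sampled every <= 4 um so plane-crossing tests see it
          nstep <- max(2L, ceiling(len / 4) + 1L)
          ts <- seq(0, 1, length.out = nstep)
          pts <- cbind(pos[1] + ts * (end[1] - pos[1]),
                       pos[2] + ts * (end[2] - pos[2]),
                       pos[3] + ts * (end[3] - pos[3]))
          segments[[sid]] <<- list(id = sid, nodes = c(node_id, end_id),
                                   points = pts,
                                   radii = rep(radius, nstep),
                                   generation = depth)
          chords <<- rbind(chords, c(pos, end, radius, node_id, end_id))
          return(list(end_id = end_id, end = end, dir = dir))
        }
        # re-aim toward the domain center — but only in free-growth mode:
        # under clearance enforcement the direction must stay the one the
        # caller screened against its sibling, so only lengths resample
        if (spec$min_clearance == 0) {
          ctr <- spec$domain_size / 2
          pull <- ctr - pos
          pull <- pull / sqrt(sum(pull^2))
          dir <- dir + 0.3 * try / max_retries * pull
          dir <- dir / sqrt(sum(dir^2))
        }
      }
      stop("phantom geometry cannot fit in the domain; enlarge domain_size, ",
           "shorten segments, or relax min_clearance")
    }

    grow <- function(node_id, pos, dir, depth) {
      placed <- place_segment(node_id, pos, dir, depth)
      if (depth < spec$levels) {
        b <- .ortho_basis(placed$dir)
        phi <- stats::runif(1, 0, 2 * pi)
        # with clearance enforcement, siblings (which share a node and are
        # exempt from the chord check) must also diverge enough that their
        # tubes separate within a segment length
        min_sib <- if (spec$min_clearance > 0)
          2 * spec$branch_angle[1] * pi / 180 else 0
        sib_dirs <- list()
        for (side in c(0, pi)) {
          done <- FALSE
          for (attempt in 1:12) {
            th <- stats::runif(1, spec$branch_angle[1],
                               spec$branch_angle[2]) * pi / 180
            ph <- if (attempt == 1L) phi + side else stats::runif(1, 0, 2 * pi)
            cd <- cos(th) * placed$dir +
              sin(th) * (cos(ph) * b$u + sin(ph) * b$v)
            cd <- cd / sqrt(sum(cd^2))
            if (length(sib_dirs) && min_sib > 0 &&
                any(vapply(sib_dirs, function(sd2)
                  acos(min(1, sum(cd * sd2))) < min_sib, logical(1))))
              next
            n_seg0 <- length(segments)
            n_node0 <- length(nodes)
            n_chord0 <- nrow(chords)
            res <- try(grow(placed$end_id, placed$end, cd, depth + 1L),
                       silent = TRUE)
            if (!inherits(res, "try-error")) {
              done <- TRUE
              sib_dirs[[length(sib_dirs) + 1L]] <- cd
              break
            }
            # roll back the partial subtree before retrying
            segments <<- segments[seq_len(n_seg0)]
            nodes <<- nodes[seq_len(n_node0)]
            chords <<- chords[seq_len(n_chord0), , drop = FALSE]
          }
          if (!done) stop("phantom geometry cannot fit in the domain; ",
                          "enlarge domain_size, shorten segments, or relax ",
                          "min_clearance")
        }
      }
      invisible(NULL)
    }
    grow(root_id, spec$root_position, spec$root_direction, 0L)

    nd <- as.data.frame(do.call(rbind, nodes))
    topo <- network_topology(nd, segments, voxel_size = NA_real_)
    structure(list(topology = topo, spec = spec,
                   region = list(shape = spec$region_shape,
                                 domain = spec$domain_size)),
              class = "PhantomTruth")
  })
}

#' Generate a suite of well-separated validation phantoms
#'
#' Draws `n` tracer-validation phantoms with bifurcation depths cycling
#' through `levels`, each built with a surface clearance of
#' `min_separation` between non-adjacent branches (seeds that still fail
#' the post-hoc [min_branch_separation()] check are skipped
#' deterministically). Tube dimensions follow the validation conditions:
#' 12 um root radius shrinking by 0.85 per generation (all radii at least
#' two 2-um voxels), segment lengths well above ten voxels, and a domain
#' sized to the depth.
#'
#' @param n number of phantoms.
#' @param seed base RNG seed; the i-th phantom derives its seed from it.
#' @param levels integer vector of depths, recycled over the `n` phantoms.
#' @param min_separation required surface gap (um) between non-adjacent
#'   branches.
#' @param gap_fraction,wall_thickness passed to [phantom_spec()] (used
#'   when the phantoms are rasterised hollow).
#' @return list of `PhantomTruth` objects.
#' @export
sample_phantoms <- function(n, seed = 1L, levels = c(4L, 5L, 6L),
                            min_separation = 20, gap_fraction = 0,
                            wall_thickness = 4) {
  levels <- rep_len(as.integer(levels), n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lv <- levels[i]
    dom <- c(`4` = 420, `5` = 560, `6` = 700)[as.character(lv)]
    sl <- switch(as.character(lv), `4` = c(45, 75), `5` = c(45, 70),
                 c(45, 70))
    k <- 0L
    repeat {
      k <- k + 1L
      if (k > 50L) stop("could not draw a separated phantom")
      spc <- phantom_spec(
        seed = (as.integer(seed) %% 10000L) * 100000L + i * 100L + k,
        levels = lv,
        root_position = c(dom / 2, dom / 2, 40),
        root_radius = 12, radius_ratio = 0.85,
        segment_length = sl, branch_angle = c(25, 55),
        wall_thickness = wall_thickness, gap_fraction = gap_fraction,
        domain_size = rep(dom, 3), min_clearance = min_separation)
      gt <- try(generate_tree(spc), silent = TRUE)
      if (!inherits(gt, "try-error") &&
          min_branch_separation(gt) >= min_separation) break
    }
    out[[i]] <- gt
  }
  out
}

#' Minimum surface separation between non-adjacent branches
#'
#' Computes, over all pairs of segments that do not share a node, the
#' minimum distance between the segment chords minus both tube radii —
#' the narrowest surface-to-surface gap in the phantom (negative when
#' branches collide). Useful to select well-separated phantoms for
#' tracer validation: the generator allows near-touching branches and an
#' extractor cannot distinguish touching tubes from a true junction.
#'
#' @param gt a `PhantomTruth` from [generate_tree()].
#' @return Minimum surface gap in um (`Inf` for a single-segment tree).
#' @export
min_branch_separation <- function(gt) {
  stopifnot(inherits(gt, "PhantomTruth"))
  segs <- gt$topology$segments
  n <- length(segs)
  if (n < 2L) return(Inf)
  sm <- .segment_matrix(gt$topology)
  ends <- lapply(segs, `[[`, "nodes")
  best <- Inf
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (length(intersect(ends[[a]], ends[[b]]))) next
      d <- .segseg_dist(sm[a, 1:3], sm[a, 4:6], sm[b, 1:3], sm[b, 4:6])
      best <- min(best, d - sm[a, 7] - sm[b, 7])
    }
  }
  best
}

# minimum distance between 3D line segments p1-p2 and q1-q2
.segseg_dist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c1 <- sum(d1 * r)
    if (e <= 1e-12) {
      t <- 0; s <- min(max(-c1 / a, 0), 1)
    } else {
      bb <- sum(d1 * d2)
      denom <- a * e - bb * bb
      s <- if (denom > 1e-12) min(max((bb * f - c1 * e) / denom, 0), 1) else 0
      t <- (bb * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((bb - c1) / a, 0), 1) }
    }
  }
  cp <- p1 + s * d1
  cq <- q1 + t * d2
  sqrt(sum((cp - cq)^2))
}

.phantom_dims <- function(domain, voxel_size) {
  pmax(1L, as.integer(round(domain / voxel_size)) + 1L)
}

#' Rasterise the phantom tissue region as a BinaryMask
#'
#' The region is the box (or inscribed ellipsoid) of the phantom domain;
#' it plays the role of the organ-region mask in downstream analyses.
#'
#' @param gt a `PhantomTruth` from [generate_tree()].
#' @param voxel_size voxel edge length in um.
#' @return A [binary_mask()].
#' @export
phantom_region <- function(gt, voxel_size) {
  stopifnot(inherits(gt, "PhantomTruth"))
  dm <- .phantom_dims(gt$region$domain, voxel_size)
  if (gt$region$shape == "box") {
    vals <- array(TRUE, dim = dm)
  } else {
    ctr <- gt$region$domain / 2
    ax <- gt$region$domain / 2
    i <- (seq_len(dm[1]) - 1) * voxel_size
    j <- (seq_len(dm[2]) - 1) * voxel_size
    k <- (seq_len(dm[3]) - 1) * voxel_size
    e1 <- ((i - ctr[1]) / ax[1])^2
    e2 <- ((j - ctr[2]) / ax[2])^2
    e3 <- ((k - ctr[3]) / ax[3])^2
    vals <- outer(outer(e1, e2, "+"), e3, "+") <= 1
  }
  binary_mask(vals, voxel_size)
}

# straight-chord segment matrix (x1,y1,z1,x2,y2,z2,r) for the rasteriser
.segment_matrix <- function(topo) {
  t(vapply(topo$segments, function(s) {
    n <- nrow(s$points)
    c(s$points[1, ], s$points[n, ], s$radii[1])
  }, numeric(7)))
}

#' Rasterise a phantom tree into a binary volume
#'
#' In solid mode a voxel is on iff its center lies within the segment
#' radius of the centerline (union of capsules). In hollow mode only the
#' wall shell `[radius - wall_thickness, radius]` is kept — interiors of
#' *all* capsules are subtracted, so junctions stay open — and then a
#' deterministic, seeded fraction `gap_fraction` of wall voxels is carved
#' out in contiguous spherical patches, emulating staining gaps in vessel
#' walls.
#'
#' @param gt a `PhantomTruth` from [generate_tree()].
#' @param voxel_size voxel edge length in um; a warning is issued when it
#'   exceeds the smallest tube radius.
#' @param mode `"solid"` or `"hollow"`.
#' @return A [binary_mask()] over the phantom domain (origin at 0).
#' @export
rasterize <- function(gt, voxel_size, mode = c("solid", "hollow")) {
  stopifnot(inherits(gt, "PhantomTruth"))
  mode <- match.arg(mode)
  spec <- gt$spec
  segm <- .segment_matrix(gt$topology)
  if (voxel_size > min(segm[, 7]))
    warning("voxel_size exceeds the smallest tube radius; ",
            "thin branches may rasterise disconnected")
  dm <- .phantom_dims(spec$domain_size, voxel_size)
  wall <- if (mode == "hollow") spec$wall_thickness else 0
  if (mode == "hollow" && wall <= 0)
    stop("hollow mode requires wall_thickness > 0 in the spec")
  code <- cpp_rasterize_capsules(dm, voxel_size, c(0, 0, 0), segm, wall)
  code <- array(code, dim = dm)
  if (mode == "solid") return(binary_mask(code > 0L, voxel_size))

  wallmask <- code == 1L
  if (spec$gap_fraction > 0) {
    widx <- which(wallmask)
    target <- floor(spec$gap_fraction * length(widx))
    pr <- spec$gap_patch_radius
    offs <- as.matrix(expand.grid(di = -pr:pr, dj = -pr:pr, dk = -pr:pr))
    offs <- offs[rowSums(offs^2) <= pr^2, , drop = FALSE]
    with_seed(spec$seed + 7919L, {
      removed <- 0L
      guard <- 0L
      while (removed < target && guard < 10L * length(widx)) {
        guard <- guard + 1L
        cand <- widx[sample.int(length(widx), 1L)]
        if (!wallmask[cand]) next
        ci <- arrayInd(cand, dm)
        pts <- sweep(offs, 2L, as.integer(ci), "+")
        keep <- pts[, 1] >= 1 & pts[, 2] >= 1 & pts[, 3] >= 1 &
          pts[, 1] <= dm[1] & pts[, 2] <= dm[2] & pts[, 3] <= dm[3]
        pts <- pts[keep, , drop = FALSE]
        hit <- wallmask[pts]
        if (any(hit)) {
          wallmask[pts[hit, , drop = FALSE]] <- FALSE
          removed <- removed + sum(hit)
        }
      }
    })
  }
  binary_mask(wallmask, voxel_size)
}
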