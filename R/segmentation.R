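#' Local mean thresholding
#'
#' Binarises a grayscale volume: a voxel is on iff its intensity exceeds
#' the mean over a cubic window of half-width `window_radius` (truncated at
#' the borders) plus `offset`. The window should be wider than the widest
#' vessel so the local mean estimates background; the default 25 voxels
#' corresponds to 50 um at 2 um resolution.
#'
#' @param vol a [volume_image()].
#' @param window_radius window half-width in voxels (>= 1).
#' @param offset intensity added to the local mean before comparison.
#' @return A [binary_mask()] with the geometry of `vol`.
#' @export
local_threshold <- function(vol, window_radius = 25L, offset = 10) {
  stopifnot(inherits(vol, "VolumeImage"), window_radius >= 1)
  d <- dim(vol$values)
  on <- cpp_local_threshold(as.numeric(vol$values), d,
                            as.integer(window_radius), offset)
  binary_mask(array(on, dim = d), vol$voxel_size, vol$origin)
}

# deterministic quasi-uniform direction set on the sphere
ray_directions <- function(n_rays) {
  stopifnot(n_rays >= 6)
  if (n_rays == 26L) {
    g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    return(g / sqrt(rowSums(g^2)))
  }
  # Fibonacci sphere
  i <- seq_len(n_rays) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n_rays
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Close staining gaps and fill vessel lumina by "insideness"
#'
#' Luminal staining labels vessel walls and can leave both unstained lumina
#' and gaps in the walls. This operator converts background voxels that are
#' inside a vessel: the insideness of a voxel is the fraction of a fixed,
#' deterministic set of ray directions along which an on-voxel is met
#' within `max_radius`. Voxels with insideness at or above
#' `inside_fraction` are added to the mask. The operator is extensive
#' (output is a superset of the input) and monotone, and is applied
#' repeatedly until a fixpoint (converted voxels can support further
#' conversions), capped at `max_iter` sweeps.
#'
#' The default search radius of 45 um sits just above the largest vessel
#' radius expected in a lymph node.
#'
#' @param mask a [binary_mask()].
#' @param max_radius ray length in um (>= voxel size).
#' @param n_rays number of ray directions (>= 6); 26 uses the voxel
#'   neighbour directions, other values a Fibonacci sphere.
#' @param inside_fraction required hit fraction, in (0, 1].
#' @param max_iter maximum fixpoint sweeps.
#' @param candidate_radius only background voxels within this distance
#'   (um) of the current mask are evaluated per sweep (default: the ray
#'   length). A small value targets the operator at surface dents without
#'   changing the insideness measure itself.
#' @return A [binary_mask()] superset of `mask`.
#' @export
fill_lumina <- function(mask, max_radius = 45, n_rays = 26L,
                        inside_fraction = 0.85, max_iter = 10L,
                        candidate_radius = max_radius) {
  stopifnot(inherits(mask, "BinaryMask"),
            max_radius >= mask$voxel_size, n_rays >= 6,
            inside_fraction > 0, inside_fraction <= 1)
  d <- dim(mask$values)
  rvox <- max_radius / mask$voxel_size
  cvox <- candidate_radius / mask$voxel_size
  vals <- mask$values
  lattice <- n_rays == 26L && candidate_radius >= max_radius
  dirs <- if (lattice) NULL else ray_directions(n_rays)
  for (it in seq_len(max_iter)) {
    if (!any(vals)) break
    if (lattice) {
      # exact per-direction visibility along the 26 lattice directions
      cnt <- cpp_inside_counts26(as.logical(vals), d, rvox)
      conv <- which(!vals & cnt / 26 >= inside_fraction)
    } else {
      # only background voxels near the structure can qualify
      edt <- cpp_edt_sq(as.logical(vals), d)
      cand <- which(!vals & edt <= cvox^2)
      if (length(cand) == 0L) break
      conv <- cpp_inside_candidates(as.logical(vals), d, as.integer(cand),
                                    dirs, rvox, inside_fraction, 0.4)
    }
    if (length(conv) == 0L) break
    vals[conv] <- TRUE
  }
  binary_mask(vals, mask$voxel_size, mask$origin)
}

#' Keep only the largest connected component
#'
#' Ties are broken deterministically: among equally large components the
#' one containing the lexicographically smallest voxel index `(i, j, k)`
#' is kept.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26.
#' @return A [binary_mask()] containing a single component (or empty, with
#'   a warning, when the input is empty).
#' @export
largest_component <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "BinaryMask"), connectivity %in% c(6L, 18L, 26L))
  d <- dim(mask$values)
  if (!any(mask$values)) {
    warning("empty mask: no components")
    return(mask)
  }
  lab <- cpp_label_components(as.logical(mask$values), d,
                              as.integer(connectivity))
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # lexicographic (i, j, k) tie-break
    lex_min <- function(lb) {
      w <- arrayInd(which(lab == lb), d)
      w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
      w[1, ]
    }
    mins <- t(vapply(best, lex_min, integer(3)))
    o <- order(mins[, 1], mins[, 2], mins[, 3])
    best <- best[o[1]]
  }
  binary_mask(array(lab == best, dim = d), mask$voxel_size, mask$origin)
}

#' Full segmentation pipeline
#'
#' [local_threshold()], then insideness filling, then
#' [largest_component()], returning the single connected, lumen-filled
#' vessel network mask.
#'
#' The filling runs in two stages with different geometric targets. Stage
#' one converts lumen voxels: deep inside a tube nearly every direction
#' meets wall within the search radius, so a high `inside_fraction`
#' (default 0.85) with a search radius above the largest vessel radius
#' fills lumina without touching the exterior. Stage two closes the
#' shallow surface dents left where staining gaps removed the outer wall
#' layer: a voxel in such a dent sees vessel over clearly more than a
#' hemisphere of directions at short range, whereas a voxel resting on a
#' flat or convex outer surface sees at most a hemisphere; the stage
#' therefore uses a finer ray set over a short reach — `gap_radius` must
#' stay below the closest approach of distinct vessels, so rays can never
#' register a neighbouring branch — evaluated only for voxels within a
#' few voxels of the current surface, with a threshold of 0.6, midway
#' between the hemisphere bound (0.5) and the visibility of a gap floor
#' (about 0.7). Set `gap_radius = 0` to skip stage two when the staining
#' has no wall gaps.
#'
#' @inheritParams local_threshold
#' @inheritParams fill_lumina
#' @param gap_radius stage-two ray reach in um (0 disables stage two);
#'   keep below the minimum separation between distinct vessels.
#' @param gap_candidate_radius stage-two candidate shell thickness in um.
#' @param gap_rays,gap_fraction_threshold stage-two ray count and
#'   insideness threshold.
#' @param connectivity component connectivity for the final isolation step.
#' @return A [binary_mask()].
#' @export
segment_vessels <- function(vol, window_radius = 25L, offset = 10,
                            max_radius = 45, n_rays = 26L,
                            inside_fraction = 0.85,
                            gap_radius = 10, gap_candidate_radius = 6,
                            gap_rays = 66L, gap_fraction_threshold = 0.6,
                            connectivity = 26L) {
  m <- local_threshold(vol, window_radius, offset)
  m <- fill_lumina(m, max_radius, n_rays, inside_fraction)
  if (gap_radius > 0)
    m <- fill_lumina(m, gap_radius, gap_rays, gap_fraction_threshold,
                     candidate_radius = gap_candidate_radius)
  largest_component(m, connectivity)
}
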