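#' Compare a subnetwork summary against the full network
#'
#' Builds the standard comparison table between a selected subnetwork
#' (e.g. the putative-HEV set) and the total network: for each parameter
#' the two absolute values and the subnetwork/total ratio as a percentage,
#' plus each network's volume as a fraction of the organ volume when that
#' is supplied. `printed` rounds each ratio the way such tables are
#' usually typeset (whole percent for counts, diameters and volumes; one
#' decimal for the length fraction; two decimals for organ-volume
#' fractions).
#'
#' @param total `NetworkSummary` (from [summary.NetworkTopology()]) of the
#'   full network, or a list with fields `n_segments`, `n_nodes`,
#'   `mean_diameter`, `mean_length`, `total_length`, `total_volume`.
#' @param sub the same for the subnetwork.
#' @param organ_volume_mm3 optional total organ volume in mm^3.
#' @return data.frame with columns `parameter`, `total`, `subnetwork`,
#'   `ratio_pct` (exact) and `printed` (rounded ratio).
#' @export
network_ratio_report <- function(total, sub, organ_volume_mm3 = NULL) {
  need <- c("n_segments", "n_nodes", "mean_diameter", "mean_length",
            "total_length", "total_volume")
  stopifnot(all(need %in% names(total)), all(need %in% names(sub)))
  rows <- list(
    list("segments", total$n_segments, sub$n_segments, 0),
    list("nodes", total$n_nodes, sub$n_nodes, 0),
    list("mean_diameter_um", total$mean_diameter, sub$mean_diameter, 0),
    list("mean_length_um", total$mean_length, sub$mean_length, 0),
    list("total_length_cm", total$total_length, sub$total_length, 1),
    list("total_volume_mm3", total$total_volume, sub$total_volume, 0)
  )
  if (!is.null(organ_volume_mm3)) {
    rows <- c(rows, list(
      list("organ_volume_fraction_total", organ_volume_mm3,
           total$total_volume, 2),
      list("organ_volume_fraction_sub", organ_volume_mm3,
           sub$total_volume, 2)
    ))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    ratio <- 100 * r[[3]] / r[[2]]
    data.frame(parameter = r[[1]], total = r[[2]], subnetwork = r[[3]],
               ratio_pct = ratio, printed = round(ratio, r[[4]]))
  }))
  rownames(out) <- NULL
  out
}
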