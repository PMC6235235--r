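# Instrument geometry and flow arithmetic.

#' Scan volume in cubic millimetres
#'
#' @param extent_um `(x, y, z)` scan extent in um; the default is the
#'   instrument's 666 x 431 x 1060 um field.
#' @return volume in mm^3 (~0.30 for the default).
#' @export
scan_volume_mm3 <- function(extent_um = c(666, 431, 1060)) {
  if (length(extent_um) != 3L || any(extent_um <= 0))
    stop("'extent_um' must be three positive extents in um")
  prod(extent_um) / 1e9
}

#' Mean flow speed in the specimen tubing
#'
#' Volumetric flow divided by the tube cross-section.
#'
#' @param flow_ml_per_min volumetric flow rate, ml/min (default 1).
#' @param tube_id_mm tubing inner diameter, mm (default 0.7).
#' @return mean speed in cm/s (~4.3 for the defaults).
#' @export
flow_speed_cm_s <- function(flow_ml_per_min = 1, tube_id_mm = 0.7) {
  stopifnot_scalar_pos(flow_ml_per_min, "flow_ml_per_min")
  stopifnot_scalar_pos(tube_id_mm, "tube_id_mm")
  q_mm3_s <- flow_ml_per_min * 1000 / 60
  area_mm2 <- pi * (tube_id_mm / 2)^2
  q_mm3_s / area_mm2 / 10
}
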