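## ATP-luminescence viability processing (3D organoid and 2D culture modes).

#' Average technical replicates of a luminescence measurement
#'
#' Arithmetic mean; identity for a single reading (2D mode, where
#' measurements are taken directly in the culture plate without technical
#' replicates).
#'
#' @param readings numeric vector of luminescence values (>= 1)
#' @return mean luminescence
#' @export
averageTechnicalReplicates <- function(readings) {
  if (length(readings) < 1) stop("no readings to average")
  mean(readings)
}

#' Relative viability per well (percent of control)
#'
#' Averages each well's technical replicates, then normalizes each well's
#' mean luminescence to the mean of the plate's solvent-control wells
#' (delegating to [plateNormalize()], so the control mean is exactly 100%).
#' Lost/absent wells carry no row — absence, never zero.
#'
#' @param luminescence data.frame(plate, well, replicate, value) for one
#'   plate
#' @param map the plate's [PlateMap-class]
#' @return data.frame(plate, well, compound_id, concentration_uM, role,
#'   mean_lum, rel_viability)
#' @export
relativeViability <- function(luminescence, map) {
  sp <- split(luminescence$value, luminescence$well)
  df <- data.frame(well = names(sp),
                   mean_lum = vapply(sp, averageTechnicalReplicates, 0))
  w <- map@wells[match(df$well, map@wells$well), ]
  if (any(is.na(w$well)))
    stop("luminescence rows for wells not on the plate map: ",
         paste(df$well[is.na(w$well)], collapse = ", "))
  df$plate <- map@plateId
  df$compound_id <- w$compound_id
  df$concentration_uM <- w$concentration_uM
  df$role <- w$role
  df$rel_viability <- plateNormalize(df$mean_lum,
                                     df$role == "solvent_control")
  rownames(df) <- NULL
  df[, c("plate", "well", "compound_id", "concentration_uM", "role",
         "mean_lum", "rel_viability")]
}
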