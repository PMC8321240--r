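## Per-organoid aggregation, area and plate-control normalization, QC
## inclusion, and homogeneity (CV) metrics.

#' Aggregate per-plane measurements for one well
#'
#' Component-wise sums of organoid area, TH intensity and Map2 intensity
#' across all planes of one well/organoid.
#'
#' @param planes data.frame with columns `area_um2`, `th_sum`, `map2_sum`
#'   (one row per plane; NA rows are planes without a gated organoid)
#' @return list(area_um2, th_sum, map2_sum)
#' @export
aggregatePlanes <- function(planes) {
  stopifnot(nrow(planes) >= 1)
  list(area_um2 = sum(planes$area_um2, na.rm = TRUE),
       th_sum = sum(planes$th_sum, na.rm = TRUE),
       map2_sum = sum(planes$map2_sum, na.rm = TRUE))
}

#' Normalize an intensity sum to organoid area
#'
#' @param sum summed intensity (abu)
#' @param area organoid area (um^2), > 0
#' @return intensity per unit area (abu/um^2)
#' @export
areaNormalize <- function(sum, area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("undefined well: organoid area must be > 0 (QC should have excluded it)")
  sum / area
}

#' Percent-of-control plate normalization
#'
#' Each value is expressed as `100 * value / mean(control values)`. Controls
#' are included in the output, so the mean of the controls' normalized values
#' is exactly 100. Normalization is per plate; plate-level gain factors
#' cancel.
#'
#' @param values numeric per-well values
#' @param isControl logical vector marking the solvent-control wells
#' @return percent-of-control values, same length/order as `values`
#' @export
plateNormalize <- function(values, isControl) {
  stopifnot(length(values) == length(isControl))
  ctrl <- values[isControl & is.finite(values)]
  if (length(ctrl) < 1) stop("no control wells with finite values")
  m <- mean(ctrl)
  if (m <= 0) stop("plate-level error: control mean <= 0")
  100 * values / m
}

#' QC inclusion filter
#'
#' A well is retained iff the pipeline found a bona fide organoid ROI and a
#' signal in both the Map2 and TH channels. Excluded wells are recorded with
#' a reason; nothing is dropped silently
#' (`nrow(retained) + nrow(excluded) == nrow(input)`).
#'
#' @param wells data.frame with logical columns `organoid_found`,
#'   `th_signal_present`, `map2_signal_present`
#' @return list(retained, excluded) of data.frames; `excluded` has a
#'   `reason` column
#' @export
qcFilter <- function(wells) {
  reason <- character(nrow(wells))
  reason[!wells$map2_signal_present] <- "no Map2 signal"
  reason[!wells$th_signal_present] <- "no TH signal"
  reason[!wells$organoid_found] <- "no organoid"
  keep <- wells$organoid_found & wells$th_signal_present &
    wells$map2_signal_present
  excluded <- wells[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  else excluded$reason <- character(0)
  list(retained = wells[keep, , drop = FALSE], excluded = excluded)
}

#' Coefficient of variation, percent
#'
#' `100 * sample SD / mean` (n-1 denominator, appropriate for the small
#' control groups of 4-12 wells). When a grouping factor is supplied,
#' per-group CVs are computed and averaged, the convention used for the
#' DMSO controls of multiple plates.
#'
#' @param values numeric vector
#' @param groups optional grouping factor (e.g. plate); per-group CVs are
#'   averaged
#' @return CV in percent
#' @examples
#' coefficientOfVariation(c(95, 100, 105))  # 5
#' @export
coefficientOfVariation <- function(values, groups = NULL) {
  cv1 <- function(v) {
    if (length(v) < 2) stop("CV needs n >= 2")
    m <- mean(v)
    if (m == 0) stop("CV undefined: mean is 0")
    100 * sd(v) / m
  }
  if (is.null(groups)) return(cv1(values))
  mean(vapply(split(values, groups), cv1, 0))
}

#' Normalize a measured plate: area normalization then percent-of-control
#'
#' Applies the fixed normalization order: TH and Map2 sums are first divided
#' by the organoid area of the same well, then each area-normalized signal is
#' expressed relative to the mean of the plate's solvent-control wells.
#' Operates on QC-retained wells only.
#'
#' @param measurements data.frame from [analyzeImages()] (one plate)
#' @param map the plate's [PlateMap-class]
#' @return list(normalized, excluded): `normalized` adds `th_per_area`,
#'   `map2_per_area`, `th_rel`, `map2_rel` plus condition columns; `excluded`
#'   is the QC exclusion log
#' @export
normalizePlate <- function(measurements, map) {
  qc <- qcFilter(measurements)
  ret <- qc$retained
  if (nrow(ret) == 0) stop("no wells passed QC on plate ", map@plateId)
  w <- map@wells[match(ret$well, map@wells$well), ]
  ret$compound_id <- w$compound_id
  ret$concentration_uM <- w$concentration_uM
  ret$role <- w$role
  ret$th_per_area <- areaNormalize(ret$th_sum, ret$area_um2)
  ret$map2_per_area <- areaNormalize(ret$map2_sum, ret$area_um2)
  isCtrl <- ret$role == "solvent_control"
  if (!any(isCtrl)) stop("no QC-passing control wells on plate ", map@plateId)
  ret$th_rel <- plateNormalize(ret$th_per_area, isCtrl)
  ret$map2_rel <- plateNormalize(ret$map2_per_area, isCtrl)
  list(normalized = ret, excluded = qc$excluded)
}
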