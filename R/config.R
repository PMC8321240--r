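## Constructors for configuration and parameter objects.

#' Construct 4PL parameters
#'
#' @param bottom,top response plateaus (fractions for generator effects,
#'   percent for fitted curves)
#' @param logIC50 log10 of the IC50 in uM
#' @param hill Hill slope; positive for responses that fall with dose
#' @return a [FourPLParams-class]
#' @examples
#' fourPL(bottom = 0, top = 1, logIC50 = 1, hill = 1)
#' @export
fourPL <- function(bottom, top, logIC50, hill) {
  new("FourPLParams", bottom = bottom, top = top, logIC50 = logIC50,
      hill = hill)
}

#' A no-effect 4PL (survival stays at 1 for all doses)
#' @return a [FourPLParams-class] whose survival is 1 everywhere
#' @export
noEffect <- function() fourPL(bottom = 1, top = 1, logIC50 = 0, hill = 1)

#' Construct per-compound generator effects
#'
#' @param compoundId compound identifier
#' @param th,map2,viability [FourPLParams-class] survival effects for the
#'   dopaminergic population, the pan-neuronal population, and overall
#'   viability. Defaults are no-effect.
#' @return a [CompoundEffect-class]
#' @export
compoundEffect <- function(compoundId, th = noEffect(), map2 = noEffect(),
                           viability = noEffect()) {
  new("CompoundEffect", compoundId = compoundId, effectTH = th,
      effectMap2 = map2, effectViability = viability)
}

#' Default analysis configuration
#'
#' Encodes the published pipeline constants. Organoid gate: area > 9000 um^2,
#' roundness > 0.4, mean nuclear (DAPI) intensity > 190 abu — strict
#' inequalities. Cell gates by mode: primary TH+ ROIs need area > 25 um^2 and
#' mean background-corrected brightness strictly between 200 and 2200 abu;
#' primary Map2+ ROIs need area > 10 um^2; dose-response TH+ ROIs need area >
#' 10 um^2 and maximum brightness < 5000 abu; dose-response Map2+ ROIs keep
#' the area > 10 um^2 rule. Filters: median radius 10 px on the channel sum;
#' Gaussian sigma 10 px for the TH (647 nm) channel; Map2 (488 nm) uses sigma
#' 5 px plus a sliding-parabola top-hat (curvature 10) in primary mode, and
#' sigma 10 px without the parabola in dose-response mode.
#'
#' Printed "px" filter sizes are interpreted as the median footprint radius
#' and the Gaussian standard deviation respectively; both are configurable.
#'
#' @param mode `"primary"` or `"dose_response"`
#' @param pixelSize um per px; the default 1 makes um^2 thresholds equal px^2
#'   and must be overridden for real acquisitions
#' @param alpha significance level applied to adjusted p-values
#' @param ... named overrides for `organoidGate`, `cellGate`, `filters`,
#'   `seeds` entries (partial lists are merged)
#' @return an [AnalysisConfig-class]
#' @examples
#' cfg <- analysisConfig("primary")
#' cfg@organoidGate$minArea
#' @export
analysisConfig <- function(mode = c("primary", "dose_response"),
                           pixelSize = 1.0, alpha = 0.05, ...) {
  mode <- match.arg(mode)
  defaults <- list(
    organoidGate = list(minArea = 9000, minRoundness = 0.4,
                        minNuclearMean = 190),
    cellGate = list(
      primary = list(
        dopaminergic = list(minArea = 25, meanBCRange = c(200, 2200)),
        pan_neuronal = list(minArea = 10)),
      dose_response = list(
        dopaminergic = list(minArea = 10, maxBrightnessBelow = 5000),
        pan_neuronal = list(minArea = 10))),
    filters = list(medianRadius = 10, thGaussianSigma = 10,
                   map2GaussianSigma = if (mode == "primary") 5 else 10,
                   parabolaCurvature = 10,
                   map2UseParabola = (mode == "primary")),
    seeds = list(k = 3, minSeparation = 4, floor = 20, regionK = 1,
                 regionFloor = 8))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(defaults)) stop("unknown config entry: ", nm)
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
  }
  new("AnalysisConfig", mode = mode, organoidGate = defaults$organoidGate,
      cellGate = defaults$cellGate, filters = defaults$filters,
      seeds = defaults$seeds, pixelSize = pixelSize, alpha = alpha)
}

#' Read an analysis configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`
#' @return an [AnalysisConfig-class]
#' @export
readAnalysisConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else stop("unsupported config format: ", ext)
  args <- list(mode = lst$mode %||% "primary")
  if (!is.null(lst$pixelSize)) args$pixelSize <- lst$pixelSize
  if (!is.null(lst$alpha)) args$alpha <- lst$alpha
  for (nm in intersect(names(lst), c("organoidGate", "cellGate", "filters", "seeds")))
    args[[nm]] <- lst[[nm]]
  do.call(analysisConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default simulation configuration
#'
#' The generator's defaults define the study conditions emulated throughout:
#' one spherical organoid per well rendered as a bright disc (radius ~64 px at
#' 1 um/px, so ~12,900 um^2, comfortably above the 9000 um^2 gate) with 2%
#' radius CV (4% area CV, the published size homogeneity of control
#' organoids); TH+ and Map2+ cells as 2D Gaussian blobs (sigma 2.5 px) with
#' lognormal per-cell brightness; smooth planar background gradients per
#' channel; dust specks (1-5 px, 2-3x background) only outside the organoid;
#' signal-proportional Gaussian noise plus an additive floor; luminescence
#' proportional to total surviving cells with a 3% technical-replicate CV, 2%
#' per-well biological CV and a lognormal plate gain; and a logistic
#' dose-dependent sample-loss model with >90% retention under control
#' conditions.
#'
#' @param frame frame side in px
#' @param planes number of confocal planes (3 for the primary screen, 5 for
#'   dose-response panels)
#' @param pixelSize um/px
#' @param ... named overrides merged into the default component lists
#'   (`organoid`, `populations`, `background`, `noise`, `luminescence`,
#'   `dust`, `loss`, `cvTargets`)
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(frame = 192, planes = 3, pixelSize = 1.0, ...) {
  defaults <- list(
    organoid = list(radiusMean = 64, radiusCV = 0.02, centerJitter = 6,
                    dapiBase = 260, nucleiPerPlane = 90, nucleusSigma = 2,
                    nucleusAmplitude = 300),
    populations = list(
      th = list(n = 45, sigma = 2, amplitudeMeanLog = log(1600),
                amplitudeSdLog = 0.12, minSeparation = 10),
      map2 = list(n = 110, sigma = 2, amplitudeMeanLog = log(1000),
                  amplitudeSdLog = 0.12, minSeparation = 6)),
    background = list(nuclear = list(base = 30, gradient = 20),
                      pan_neuronal = list(base = 15, gradient = 10),
                      dopaminergic = list(base = 8, gradient = 6)),
    noise = list(cvSignal = 0.02, floorSd = 3),
    luminescence = list(perCellSignal = 50, replicateCV = 0.03,
                        wellCV = 0.02, gainSdLog = 0.1,
                        technicalReplicates = 2),
    dust = list(lambdaPerPlane = 1.5, sizeRange = c(1, 5),
                brightnessFactor = c(2, 3), margin = 8),
    loss = list(pFloor = 0.05, pMax = 0.9, steepness = 8, midpoint = 0.3),
    cvTargets = list(size = 0.04, viability = 0.03))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(defaults)) stop("unknown config entry: ", nm)
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
  }
  new("SimulationConfig", frame = frame, planes = planes,
      pixelSize = pixelSize, planeSpacing = 36.6,
      organoid = defaults$organoid, populations = defaults$populations,
      background = defaults$background, noise = defaults$noise,
      luminescence = defaults$luminescence, dust = defaults$dust,
      loss = defaults$loss, cvTargets = defaults$cvTargets,
      minSeparation = 9)
}
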