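## S4 class definitions and validity rules.

VALID_ROLES <- c("treated", "solvent_control", "non_treated", "empty")
VALID_SOLVENTS <- c("DMSO", "ethanol", "none")
CHANNEL_NAMES <- c("nuclear", "pan_neuronal", "dopaminergic")

#' Check a 96-well coordinate ("A1".."H12")
#' @param well character vector of well labels
#' @return logical vector
#' @export
isValidWell <- function(well) {
  grepl("^[A-H](1[0-2]|[1-9])$", well)
}

#' PlateMap: the experimental layout of one 96-well plate
#'
#' Holds per-well conditions (compound, concentration in uM, solvent, role)
#' for a plate. Roles follow screening convention: `treated`,
#' `solvent_control` (DMSO/ethanol vehicle wells used for percent-of-control
#' normalization), `non_treated`, `empty`. Every plate must carry at least one
#' solvent-control well; screens here use four per plate.
#'
#' @slot plateId character plate identifier
#' @slot cellLineId character cell-line identifier
#' @slot exposureH numeric compound exposure in hours
#' @slot wells data.frame with columns `well`, `compound_id`,
#'   `concentration_uM`, `solvent`, `role`
#' @export
setClass("PlateMap",
  representation(plateId = "character", cellLineId = "character",
                 exposureH = "numeric", wells = "data.frame"))

setValidity("PlateMap", function(object) {
  w <- object@wells
  need <- c("well", "compound_id", "concentration_uM", "solvent", "role")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  bad <- !isValidWell(w$well)
  if (any(bad))
    return(paste0("malformed well coordinate: ", w$well[which(bad)[1]]))
  if (anyDuplicated(w$well))
    return(paste0("duplicate well: ", w$well[duplicated(w$well)][1]))
  if (!all(w$role %in% VALID_ROLES))
    return(paste0("unknown role: ", setdiff(w$role, VALID_ROLES)[1]))
  if (!all(w$solvent %in% VALID_SOLVENTS))
    return(paste0("unknown solvent: ", setdiff(w$solvent, VALID_SOLVENTS)[1]))
  if (any(!is.na(w$concentration_uM) & w$concentration_uM < 0)) {
    i <- which(!is.na(w$concentration_uM) & w$concentration_uM < 0)[1]
    return(paste0("negative concentration in well ", w$well[i]))
  }
  if (!any(w$role == "solvent_control"))
    return("no control wells: plate has no solvent_control wells")
  tr <- w$role == "treated"
  if (any(tr & (is.na(w$compound_id) | w$compound_id == "")))
    return(paste0("treated well without compound_id: ",
                  w$well[which(tr & (is.na(w$compound_id) | w$compound_id == ""))[1]]))
  if (any(tr & (is.na(w$concentration_uM) | w$concentration_uM <= 0)))
    return(paste0("treated well without positive concentration: ",
                  w$well[which(tr & (is.na(w$concentration_uM) | w$concentration_uM <= 0))[1]]))
  sc <- w$role == "solvent_control"
  if (any(sc & w$concentration_uM != 0))
    return(paste0("solvent_control well with nonzero concentration: ",
                  w$well[which(sc & w$concentration_uM != 0)[1]]))
  TRUE
})

#' ImageStack: a multi-channel, multi-plane fluorescence stack for one well
#'
#' Pixel data live in a 4D array indexed `[row, col, channel, plane]`
#' (0-based pixel semantics at the file level; R arrays are 1-based).
#' Channels are named `nuclear` (DAPI), `pan_neuronal` (Map2, 488 nm) and
#' `dopaminergic` (TH, 647 nm). Intensities are arbitrary brightness units
#' (abu), non-negative.
#'
#' @slot data 4D numeric array `[row, col, channel, plane]`
#' @slot channels character vector of channel names (3rd dim)
#' @slot pixelSize numeric, micrometres per pixel
#' @slot planeSpacing numeric, micrometres between planes
#' @export
setClass("ImageStack",
  representation(data = "array", channels = "character",
                 pixelSize = "numeric", planeSpacing = "numeric"))

setValidity("ImageStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 4) return("data must be a 4D array [row, col, channel, plane]")
  if (dim(d)[3] != length(object@channels))
    return("third dimension must match number of channels")
  if (dim(d)[4] < 1) return("plane count must be >= 1")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixel_size must be a positive finite scalar")
  if (any(d < 0)) return("intensities must be >= 0")
  TRUE
})

#' Four-parameter logistic (4PL) dose-response parameters
#'
#' `y = bottom + (top - bottom) / (1 + 10^((x - logIC50) * hill))` with
#' `x = log10(concentration in uM)`. With `hill > 0` and `top` the no-effect
#' level, the response decreases with dose.
#'
#' @slot bottom numeric lower plateau (response units)
#' @slot top numeric upper plateau
#' @slot logIC50 numeric log10 of IC50 in uM
#' @slot hill numeric Hill slope (nonzero)
#' @export
setClass("FourPLParams",
  representation(bottom = "numeric", top = "numeric",
                 logIC50 = "numeric", hill = "numeric"))

setValidity("FourPLParams", function(object) {
  p <- c(object@bottom, object@top, object@logIC50, object@hill)
  if (length(p) != 4 || !all(is.finite(p))) return("all four parameters must be finite scalars")
  if (object@top < object@bottom) return("top must be >= bottom")
  if (object@hill == 0) return("hill must be nonzero")
  TRUE
})

#' Per-compound ground-truth effects for the synthetic generator
#'
#' One 4PL effect per readout: dopaminergic (TH) survival, pan-neuronal
#' (Map2) survival, and overall viability. Selective dopaminergic toxicants
#' are encoded by `logIC50(TH) < logIC50(Map2)`.
#'
#' @slot compoundId character
#' @slot effectTH [FourPLParams-class]
#' @slot effectMap2 [FourPLParams-class]
#' @slot effectViability [FourPLParams-class]
#' @export
setClass("CompoundEffect",
  representation(compoundId = "character", effectTH = "FourPLParams",
                 effectMap2 = "FourPLParams", effectViability = "FourPLParams"))

#' Analysis configuration for the image pipeline and statistics
#'
#' Houses the printed pipeline constants: the organoid gate (area > 9000 um^2,
#' roundness > 0.4, mean nuclear intensity > 190 abu), the per-channel,
#' per-mode cell gates, filter sizes (median radius 10 px, Gaussian sigmas,
#' parabola curvature 10), seed-detection parameters, pixel calibration and
#' the significance level.
#'
#' @slot mode character, `"primary"` or `"dose_response"`
#' @slot organoidGate list(minArea, minRoundness, minNuclearMean)
#' @slot cellGate nested list: `cellGate[[mode]][[channel]]` with fields
#'   `minArea` and either `meanBCRange` (primary TH), `maxBrightnessBelow`
#'   (dose-response TH) or nothing beyond area (Map2)
#' @slot filters list(medianRadius, thGaussianSigma, map2GaussianSigma,
#'   parabolaCurvature, map2UseParabola)
#' @slot seeds list(k, minSeparation, floor, regionK, regionFloor):
#'   local-maxima seed threshold is `max(median + k * MAD, floor)` of the BC
#'   image inside the organoid mask; segments grow down to the lower
#'   hysteresis floor `max(median + regionK * MAD, regionFloor)`
#' @slot pixelSize numeric um/px
#' @slot alpha numeric significance level for adjusted p-values
#' @export
setClass("AnalysisConfig",
  representation(mode = "character", organoidGate = "list", cellGate = "list",
                 filters = "list", seeds = "list", pixelSize = "numeric",
                 alpha = "numeric"))

setValidity("AnalysisConfig", function(object) {
  if (!object@mode %in% c("primary", "dose_response"))
    return(paste0("unknown mode: ", object@mode))
  og <- object@organoidGate
  if (!all(c("minArea", "minRoundness", "minNuclearMean") %in% names(og)))
    return("organoidGate must have minArea, minRoundness, minNuclearMean")
  if (!all(vapply(og, function(x) is.finite(x) && length(x) == 1, TRUE)))
    return("organoid gate thresholds must be finite scalars")
  if (!object@mode %in% names(object@cellGate))
    return("cellGate has no parameter set for the active mode")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  TRUE
})

#' Simulation configuration for the synthetic plate generator
#'
#' All knobs of the generator: frame geometry, organoid size distribution,
#' per-population cell counts and blob appearance, per-channel backgrounds and
#' gradients, the noise model (signal-proportional Gaussian plus an additive
#' floor), the luminescence model (per-cell signal, technical-replicate CV,
#' plate gain), dust artifacts, the dose-dependent sample-loss model, and the
#' control CV targets the generated plates are calibrated to.
#'
#' @slot frame integer frame side in px
#' @slot planes integer number of confocal planes
#' @slot pixelSize numeric um/px
#' @slot planeSpacing numeric um between planes
#' @slot organoid list(radiusMean, radiusCV, centerJitter, dapiBase, nucleiPerPlane,
#'   nucleusSigma, nucleusAmplitude)
#' @slot populations list per population (`th`, `map2`): list(n, sigma,
#'   amplitudeMeanLog, amplitudeSdLog, minSeparation)
#' @slot background list per channel: list(base, gradient)
#' @slot noise list(cvSignal, floorSd)
#' @slot luminescence list(perCellSignal, replicateCV, wellCV, gainSdLog,
#'   technicalReplicates)
#' @slot dust list(lambdaPerPlane, sizeRange, brightnessFactor, margin)
#' @slot loss list(pFloor, pMax, steepness, midpoint)
#' @slot cvTargets list(size, viability)
#' @slot minSeparation numeric minimum cell-centre separation in px
#' @export
setClass("SimulationConfig",
  representation(frame = "numeric", planes = "numeric", pixelSize = "numeric",
                 planeSpacing = "numeric", organoid = "list",
                 populations = "list", background = "list", noise = "list",
                 luminescence = "list", dust = "list", loss = "list",
                 cvTargets = "list", minSeparation = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@frame < 32) return("frame must be >= 32 px")
  if (object@planes < 1) return("planes must be >= 1")
  if (object@noise$cvSignal < 0 || object@noise$floorSd < 0)
    return("noise SDs must be >= 0")
  if (object@cvTargets$size < 0 || object@cvTargets$viability < 0)
    return("CV targets must be >= 0")
  if (!all(c("th", "map2") %in% names(object@populations)))
    return("populations must include th and map2")
  TRUE
})

#' Ground truth for one simulated plate
#'
#' Generator-side truth used as the oracle in tests: per-well true population
#' counts, surviving fractions, organoid geometry, rendered foreground
#' integrals, dust placements, the plate gain, and the lost flag. Truth rows
#' exist for every well including lost ones.
#'
#' @slot wells data.frame, one row per well (see [simulatePlate()])
#' @slot cells named list (by well) of data.frames of rendered cell blobs
#'   (x, y, plane, population, amplitude, sigma)
#' @slot dust named list (by well) of data.frames of dust specks
#' @slot plateGain numeric plate-level luminescence gain factor
#' @export
setClass("PlateGroundTruth",
  representation(wells = "data.frame", cells = "list", dust = "list",
                 plateGain = "numeric"))

setValidity("PlateGroundTruth", function(object) {
  w <- object@wells
  if (any(w$n_th_true < 0) || any(w$n_map2_true < 0)) return("counts must be >= 0")
  sf <- c(w$sf_th, w$sf_map2, w$sf_viability)
  if (any(sf < 0 | sf > 1)) return("surviving fractions must be in [0,1]")
  TRUE
})

#' A fully simulated plate: layout, truth, images and luminescence
#'
#' @slot plateMap [PlateMap-class]
#' @slot truth [PlateGroundTruth-class]
#' @slot images named list (by well) of [ImageStack-class]; lost wells absent
#' @slot luminescence data.frame(plate, well, replicate, value); lost wells absent
#' @export
setClass("SimulatedPlate",
  representation(plateMap = "PlateMap", truth = "PlateGroundTruth",
                 images = "list", luminescence = "data.frame"))

#' A fitted four-parameter logistic dose-response curve
#'
#' @slot bottom,top,logIC50,hill numeric fitted parameters
#' @slot rss numeric residual sum of squares at the optimum
#' @slot converged logical honest convergence flag; `ic50()` refuses to report
#'   when `FALSE`
#' @slot n integer number of fitted points
#' @slot message character optimizer message
#' @export
setClass("DoseResponseFit",
  representation(bottom = "numeric", top = "numeric", logIC50 = "numeric",
                 hill = "numeric", rss = "numeric", converged = "logical",
                 n = "integer", message = "character"))

#' An emulated sample-attrition survival series
#'
#' Concentrations are mapped to integer x (solvent control at 0, each
#' concentration step +1). Every unit drop in the rounded remaining-sample
#' count is an event at that x; a censoring entry sits one step past the
#' highest tested concentration.
#'
#' @slot x integer indices 0..K
#' @slot counts integer rounded remaining-sample counts per x
#' @slot events data.frame(x, multiplicity)
#' @slot censoredAt integer index of the censoring entry (K + 1)
#' @slot nCensored integer samples remaining at the end (count at K)
#' @export
setClass("AttritionSeries",
  representation(x = "integer", counts = "integer", events = "data.frame",
                 censoredAt = "integer", nCensored = "integer"))

setValidity("AttritionSeries", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (object@censoredAt != max(object@x) + 1L)
    return("censoredAt must be max concentration index + 1")
  TRUE
})

#' A screening run report
#'
#' Collects the tables, test results, fits, CV metrics and attrition series of
#' one end-to-end run, together with metadata (seed, configuration, package
#' version) sufficient to reproduce the run byte-identically.
#'
#' @slot tables list of data.frames (measurements, normalized signals, viability)
#' @slot tests list of per-family test-result data.frames
#' @slot fits list of [DoseResponseFit-class] objects
#' @slot cvs list of CV summaries
#' @slot attrition `NULL` or an [AttritionSeries-class]
#' @slot metadata list(seed, config, package_version, mode)
#' @export
setClass("ScreenReport",
  representation(tables = "list", tests = "list", fits = "list",
                 cvs = "list", attrition = "ANY", metadata = "list"))
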