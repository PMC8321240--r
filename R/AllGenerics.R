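## Generics, accessors and show methods.

#' @rdname ImageStack-class
#' @param object an object
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname ImageStack-class
#' @export
setGeneric("planeCount", function(object) standardGeneric("planeCount"))
#' @rdname PlateMap-class
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))
#' @rdname PlateMap-class
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))
#' @rdname PlateMap-class
#' @export
setGeneric("controlWells", function(object) standardGeneric("controlWells"))
#' @rdname DoseResponseFit-class
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @rdname DoseResponseFit-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname PlateGroundTruth-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname ImageStack-class
setMethod("channelNames", "ImageStack", function(object) object@channels)
#' @rdname ImageStack-class
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
#' @rdname ImageStack-class
setMethod("planeCount", "ImageStack", function(object) dim(object@data)[4])
#' @rdname PlateMap-class
setMethod("wells", "PlateMap", function(object) object@wells)
#' @rdname PlateMap-class
setMethod("plateId", "PlateMap", function(object) object@plateId)
#' @rdname PlateMap-class
setMethod("controlWells", "PlateMap", function(object)
  object@wells$well[object@wells$role == "solvent_control"])
#' @rdname PlateGroundTruth-class
#' @param object an object
setMethod("groundTruth", "SimulatedPlate", function(object) object@truth)
#' @rdname DoseResponseFit-class
setMethod("isConverged", "DoseResponseFit", function(object) object@converged)

#' @rdname DoseResponseFit-class
#' @param object a [DoseResponseFit-class]
#' @return `ic50()`: the IC50 in uM (`10^logIC50`); errors if the fit did not
#'   converge.
setMethod("ic50", "DoseResponseFit", function(object) {
  if (!object@converged)
    stop("fit did not converge; no IC50 is reported")
  10^object@logIC50
})

setMethod("show", "PlateMap", function(object) {
  w <- object@wells
  cat("PlateMap", object@plateId, "(cell line ", object@cellLineId,
      ", ", object@exposureH, " h)\n", sep = "")
  cat(" ", nrow(w), "wells:", sum(w$role == "treated"), "treated,",
      sum(w$role == "solvent_control"), "solvent controls,",
      sum(w$role == "non_treated"), "non-treated,",
      sum(w$role == "empty"), "empty\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack: ", d[1], "x", d[2], " px, ", d[3], " channels (",
      paste(object@channels, collapse = ", "), "), ", d[4], " planes, ",
      object@pixelSize, " um/px, plane spacing ", object@planeSpacing,
      " um\n", sep = "")
})

setMethod("show", "DoseResponseFit", function(object) {
  cat("4PL dose-response fit (n = ", object@n, ")\n", sep = "")
  cat(sprintf("  bottom %.3f  top %.3f  logIC50 %.4f  hill %.3f  RSS %.4g\n",
              object@bottom, object@top, object@logIC50, object@hill,
              object@rss))
  if (object@converged)
    cat(sprintf("  converged; IC50 = %.4g uM\n", 10^object@logIC50))
  else cat("  NOT converged:", object@message, "\n")
})

setMethod("show", "AttritionSeries", function(object) {
  cat("AttritionSeries over x = 0..", max(object@x), " (counts ",
      paste(object@counts, collapse = ","), ")\n", sep = "")
  if (nrow(object@events) == 0) cat("  no events;")
  else cat("  events at x =",
           paste(rep(object@events$x, object@events$multiplicity),
                 collapse = ", "), ";")
  cat(" censored at x =", object@censoredAt, "with", object@nCensored,
      "samples remaining\n")
})

setMethod("show", "SimulatedPlate", function(object) {
  cat("SimulatedPlate", object@plateMap@plateId, "-",
      nrow(object@truth@wells), "truth wells,", length(object@images),
      "imaged wells,", nrow(object@luminescence), "luminescence rows\n")
})

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport (mode ", object@metadata$mode, ", seed ",
      object@metadata$seed, ")\n", sep = "")
  cat("  tables:", paste(names(object@tables), collapse = ", "), "\n")
  if (length(object@tests))
    cat("  test families:", paste(names(object@tests), collapse = ", "), "\n")
  if (length(object@fits))
    cat("  fits:", paste(names(object@fits), collapse = ", "), "\n")
})
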