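## End-to-end orchestration: primary screen, dose-response panels, 2D-vs-3D.

screenMetadata <- function(seed, mode, simCfg, anaCfg = NULL) {
  list(seed = seed, mode = mode,
       package_version = as.character(packageVersion("organoidScreen")),
       sim_config = simCfg, analysis_config = anaCfg)
}

#' Run a primary screen: viability plus cell-type-specific toxicity
#'
#' Simulates `nPlates` replicate plates (every compound at one screening
#' concentration plus solvent controls), analyses the image stacks in primary
#' mode, processes luminescence viability, applies QC and the two
#' normalizations, and runs the `viability_vs_control` and `th_vs_map2`
#' comparison families with Bonferroni-Dunn correction. Control CVs for
#' organoid size, viability and the TH/Map2 signals are reported.
#'
#' @param effects named list of [CompoundEffect-class]
#' @param seed master seed
#' @param simCfg a [SimulationConfig-class]
#' @param anaCfg an [AnalysisConfig-class] (primary mode)
#' @param nPlates replicate plates (default 3)
#' @param concentration screening concentration in uM
#' @param nControls solvent-control wells per plate (default 4)
#' @return a [ScreenReport-class]
#' @export
runPrimaryScreen <- function(effects, seed, simCfg = simulationConfig(),
                             anaCfg = analysisConfig("primary"),
                             nPlates = 3, concentration = 100,
                             nControls = 4) {
  normAll <- list(); viabAll <- list(); exclAll <- list()
  for (r in seq_len(nPlates)) {
    map <- primaryPlateMap(names(effects), concentration, nControls,
                           plateId = paste0("plate", r))
    sim <- simulatePlate(map, effects, simCfg, seed)
    meas <- analyzeImages(sim@images, anaCfg, plate = map@plateId)
    if (nrow(meas) > 0) {
      norm <- normalizePlate(meas, map)
      normAll[[r]] <- norm$normalized
      exclAll[[r]] <- norm$excluded
    }
    viabAll[[r]] <- relativeViability(sim@luminescence, map)
  }
  norm <- do.call(rbind, c(normAll, make.row.names = FALSE))
  viab <- do.call(rbind, c(viabAll, make.row.names = FALSE))
  excl <- do.call(rbind, c(exclAll, make.row.names = FALSE))
  ctrlN <- norm[norm$role == "solvent_control", ]
  ctrlV <- viab[viab$role == "solvent_control", ]
  cvs <- list(
    size = coefficientOfVariation(ctrlN$area_um2, ctrlN$plate),
    viability = coefficientOfVariation(ctrlV$rel_viability, ctrlV$plate),
    th = coefficientOfVariation(ctrlN$th_rel, ctrlN$plate),
    map2 = coefficientOfVariation(ctrlN$map2_rel, ctrlN$plate))
  tv <- viab[viab$role %in% c("treated", "solvent_control"), ]
  testsViab <- screenCompare(
    data.frame(id = tv$compound_id, role = tv$role, value = tv$rel_viability),
    family = "viability_vs_control", alpha = anaCfg@alpha)
  tn <- norm[norm$role == "treated", ]
  testsSub <- screenCompare(
    data.frame(id = tn$compound_id, th_rel = tn$th_rel,
               map2_rel = tn$map2_rel),
    family = "th_vs_map2", alpha = anaCfg@alpha)
  new("ScreenReport",
      tables = list(normalized = norm, viability = viab, excluded = excl),
      tests = list(viability_vs_control = testsViab, th_vs_map2 = testsSub),
      fits = list(), cvs = cvs, attrition = NULL,
      metadata = screenMetadata(seed, "primary", simCfg, anaCfg))
}

#' Run a dose-response panel for one compound
#'
#' One plate with the concentration series plus solvent controls. Produces
#' relative-viability and (optionally) TH/Map2 dose-response tables, 4PL fits
#' with IC50s, per-concentration TH-vs-Map2 tests, and the sample-attrition
#' series built from the plate's remaining-sample counts.
#'
#' @param effect a [CompoundEffect-class]
#' @param seed master seed
#' @param simCfg a [SimulationConfig-class] (use `planes = 5` for the
#'   acquisition depth of dose-response panels)
#' @param anaCfg an [AnalysisConfig-class] in `dose_response` mode
#' @param doses concentration series in uM
#' @param wellsPerDose organoids per concentration (default 8)
#' @param nControls solvent-control wells (default 8)
#' @param analyzeImagesToo set `FALSE` for a viability-only panel
#' @return a [ScreenReport-class]
#' @export
runDoseResponse <- function(effect, seed,
                            simCfg = simulationConfig(planes = 5),
                            anaCfg = analysisConfig("dose_response"),
                            doses = c(0.01, 0.1, 1, 10, 50, 100, 200, 500,
                                      1000),
                            wellsPerDose = 8, nControls = 8,
                            analyzeImagesToo = TRUE) {
  cid <- effect@compoundId
  map <- doseResponsePlateMap(cid, doses, wellsPerDose, nControls)
  effects <- setNames(list(effect), cid)
  sim <- simulatePlate(map, effects, simCfg, seed,
                       renderImages = analyzeImagesToo)
  viab <- relativeViability(sim@luminescence, map)
  fits <- list(viability = fitDoseResponse(viab$concentration_uM,
                                           viab$rel_viability))
  tables <- list(viability = viab)
  tests <- list()
  if (analyzeImagesToo) {
    meas <- analyzeImages(sim@images, anaCfg, plate = map@plateId)
    norm <- normalizePlate(meas, map)
    tables$normalized <- norm$normalized
    tables$excluded <- norm$excluded
    fits$th <- fitDoseResponse(norm$normalized$concentration_uM,
                               norm$normalized$th_rel)
    fits$map2 <- fitDoseResponse(norm$normalized$concentration_uM,
                                 norm$normalized$map2_rel)
    tr <- norm$normalized[norm$normalized$role == "treated", ]
    tests$th_vs_map2 <- screenCompare(
      data.frame(id = tr$concentration_uM, th_rel = tr$th_rel,
                 map2_rel = tr$map2_rel),
      family = "th_vs_map2", alpha = anaCfg@alpha)
  }
  rem <- remainingByConcentration(sim@truth)
  # stochastic loss on a single plate can produce non-monotone counts, which
  # the series builder rejects by contract; report no series in that case
  attr <- tryCatch(buildAttritionSeries(roundCounts(rem$remaining)),
                   error = function(e) NULL)
  new("ScreenReport", tables = tables, tests = tests, fits = fits,
      cvs = list(), attrition = attr,
      metadata = screenMetadata(seed, "dose_response", simCfg, anaCfg))
}

#' Compare compound toxicity between 2D culture and 3D organoids
#'
#' Viability dose-response in both modes from the same effect table: 3D wells
#' carry two technical luminescence replicates, 2D wells a single reading.
#' Produces per-mode 4PL fits and IC50s plus per-concentration 2D-vs-3D
#' pooled t-tests.
#'
#' @param effect3d,effect2d [CompoundEffect-class] viability effects for the
#'   two culture modes (same compound)
#' @param seed master seed
#' @param simCfg a [SimulationConfig-class]
#' @param doses concentration series in uM
#' @param wellsPerDose samples per concentration (default 6)
#' @param nControls solvent controls per plate (default 6)
#' @param alpha significance level
#' @return a [ScreenReport-class] with fits `viability_3d`, `viability_2d`
#' @export
run2D3DComparison <- function(effect3d, effect2d, seed,
                              simCfg = simulationConfig(),
                              doses = c(0.01, 0.1, 1, 10, 50, 100, 200, 500,
                                        1000),
                              wellsPerDose = 6, nControls = 6, alpha = 0.05) {
  cid <- effect3d@compoundId
  cfg3d <- simCfg
  cfg2d <- simCfg
  cfg2d@luminescence$technicalReplicates <- 1
  runs <- list(`3D` = list(cfg = cfg3d, eff = effect3d),
               `2D` = list(cfg = cfg2d, eff = effect2d))
  viabs <- list(); fits <- list()
  for (mode in names(runs)) {
    map <- doseResponsePlateMap(cid, doses, wellsPerDose, nControls,
                                plateId = paste0(mode, "_", cid))
    sim <- simulatePlate(map, setNames(list(runs[[mode]]$eff), cid),
                         runs[[mode]]$cfg, seed, renderImages = FALSE)
    v <- relativeViability(sim@luminescence, map)
    v$mode <- mode
    viabs[[mode]] <- v
    fits[[paste0("viability_", tolower(mode))]] <-
      fitDoseResponse(v$concentration_uM, v$rel_viability)
  }
  viab <- do.call(rbind, c(viabs, make.row.names = FALSE))
  tr <- viab[viab$role == "treated", ]
  tests <- list(mode_2d_vs_3d = screenCompare(
    data.frame(id = tr$concentration_uM, mode = tr$mode,
               value = tr$rel_viability),
    family = "mode_2d_vs_3d", alpha = alpha))
  new("ScreenReport", tables = list(viability = viab), tests = tests,
      fits = fits, cvs = list(), attrition = NULL,
      metadata = screenMetadata(seed, "2d_3d", simCfg))
}
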