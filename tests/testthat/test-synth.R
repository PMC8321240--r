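test_that("survival fraction matches the 4PL formula and its plateaus", {
  eff <- fourPL(bottom = 0, top = 1, logIC50 = 1, hill = 1)
  expect_equal(survivalFraction(0, eff), 1)       # solvent: no-effect plateau
  expect_equal(survivalFraction(10, eff), 0.5)    # midpoint at IC50
  # grid vs independent formula evaluation
  cs <- 10^seq(-2, 3, length.out = 40)
  eff2 <- fourPL(0.1, 0.95, 0.7, 1.8)
  expect_equal(survivalFraction(cs, eff2),
               brute4PL(0.1, 0.95, 0.7, 1.8, log10(cs)),
               tolerance = 1e-12)
  # monotone non-increasing for hill > 0
  expect_true(all(diff(survivalFraction(cs, eff2)) <= 0))
})

test_that("per-well substream seeds are stable and independent", {
  expect_identical(wellSeed(7, "p1", "A1"), wellSeed(7, "p1", "A1"))
  expect_false(wellSeed(7, "p1", "A1") == wellSeed(7, "p1", "A2"))
  expect_false(wellSeed(7, "p1", "A1") == wellSeed(8, "p1", "A1"))
  expect_true(wellSeed(.Machine$integer.max, "plateX", "H12") < 2^31)
})

test_that("simulated plates are pure functions of (cfg, effects, seed)", {
  cfg <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0))
  map <- primaryPlateMap("c1", 100, 1, plateId = "det")
  effs <- nullEffects("c1")
  s1 <- simulatePlate(map, effs, cfg, seed = 13)
  s2 <- simulatePlate(map, effs, cfg, seed = 13)
  expect_identical(s1@truth@wells, s2@truth@wells)
  expect_identical(s1@truth@cells, s2@truth@cells)
  expect_identical(s1@luminescence, s2@luminescence)
  expect_identical(s1@images[[1]]@data, s2@images[[1]]@data)
})

test_that("adding a well does not perturb other wells' draws", {
  cfg <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0))
  effs <- nullEffects("c1")
  m1 <- primaryPlateMap("c1", 100, 1, plateId = "grow")
  m2 <- new("PlateMap", plateId = "grow", cellLineId = "line1",
            exposureH = 48,
            wells = rbind(m1@wells,
                          data.frame(well = "H12", compound_id = "c1",
                                     concentration_uM = 100, solvent = "DMSO",
                                     role = "treated")))
  s1 <- simulatePlate(m1, effs, cfg, seed = 5, renderImages = FALSE)
  s2 <- simulatePlate(m2, effs, cfg, seed = 5, renderImages = FALSE)
  shared <- s1@truth@wells$well
  expect_identical(s1@truth@wells,
                   s2@truth@wells[s2@truth@wells$well %in% shared, ])
})

test_that("no-effect screens have surviving fraction 1 everywhere", {
  cfg <- simulationConfig()
  map <- primaryPlateMap(c("a", "b"), 100, 2, plateId = "ne")
  s <- simulatePlate(map, nullEffects(c("a", "b")), cfg, seed = 2,
                     renderImages = FALSE)
  expect_true(all(s@truth@wells$sf_th == 1))
  expect_true(all(s@truth@wells$sf_map2 == 1))
  expect_true(all(s@truth@wells$sf_viability == 1))
})

test_that("binomial thinning has the right mean and variance", {
  # 8 dose-response plates of one compound at a single dose give >500 draws
  cfg <- simulationConfig(loss = list(pFloor = 0, pMax = 0))
  eff <- compoundEffect("t", th = fourPL(0, 1, 1, 1),
                        map2 = fourPL(0, 1, 2, 1))
  draws <- integer(0); draws2 <- integer(0)
  for (k in 1:6) {
    map <- doseResponsePlateMap("t", doses = 10, wellsPerDose = 88,
                                nControls = 8,
                                plateId = paste0("bin", k))
    s <- simulatePlate(map, list(t = eff), cfg, seed = 100 + k,
                       renderImages = FALSE)
    tr <- s@truth@wells[s@truth@wells$role == "treated", ]
    draws <- c(draws, tr$n_th_true)
    draws2 <- c(draws2, tr$n_map2_true)
  }
  n <- simulationConfig()@populations$th$n
  fTH <- survivalFraction(10, eff@effectTH)      # 0.5
  fM <- survivalFraction(10, eff@effectMap2)     # ~0.909
  expect_gt(length(draws), 500)
  # mean within 5 sigma of binomial expectation
  expect_lt(abs(mean(draws) - n * fTH),
            5 * sqrt(n * fTH * (1 - fTH) / length(draws)))
  nM <- simulationConfig()@populations$map2$n
  expect_lt(abs(mean(draws2) - nM * fM),
            5 * sqrt(nM * fM * (1 - fM) / length(draws2)))
  # chi-square test of the variance at alpha = 0.01
  s2 <- var(draws); v0 <- n * fTH * (1 - fTH)
  stat <- (length(draws) - 1) * s2 / v0
  pval <- 2 * min(pchisq(stat, length(draws) - 1),
                  1 - pchisq(stat, length(draws) - 1))
  expect_gt(pval, 0.01)
})

test_that("luminescence model: proportionality, gain linearity, empirical CV", {
  cfg <- simulationConfig(luminescence = list(replicateCV = 0, wellCV = 0))
  set.seed(1)
  r <- simulateLuminescence(100, cfg, gain = 1)
  expect_length(r, 2)
  expect_equal(r[1], r[2])
  expect_equal(r[1], 100 * cfg@luminescence$perCellSignal)
  set.seed(42); r1 <- simulateLuminescence(80, cfg, gain = 1)
  set.seed(42); r2 <- simulateLuminescence(80, cfg, gain = 2)
  expect_equal(r2, 2 * r1)
  cfg2 <- simulationConfig(luminescence = list(replicateCV = 0.03,
                                               wellCV = 0))
  set.seed(7)
  draws <- replicate(5000, simulateLuminescence(100, cfg2, 1,
                                                replicates = 2))
  expect_equal(100 * sd(draws) / mean(draws), 3, tolerance = 0.1)
})

test_that("sample loss is Bernoulli with a monotone dose-dependent rate", {
  lossNone <- list(pFloor = 0, pMax = 0.9, steepness = 8, midpoint = 0.3)
  expect_equal(lossProbability(1, lossNone), 0)  # retention at full viability
  expect_equal(lossProbability(0, lossNone), 0.9)
  cfg <- simulationConfig(loss = lossNone)
  set.seed(3)
  expect_false(any(simulateSampleLoss(rep(1, 1000), cfg)))
  nLost <- sum(simulateSampleLoss(rep(0, 1000), cfg))
  expect_lt(abs(nLost - 900), 5 * sqrt(1000 * 0.9 * 0.1))
  lo <- sum(simulateSampleLoss(rep(0.2, 1000), cfg))
  hi <- sum(simulateSampleLoss(rep(0.8, 1000), cfg))
  expect_gte(lo, hi)
  # p(v) monotone non-increasing
  v <- seq(0, 1, by = 0.01)
  expect_true(all(diff(lossProbability(v, simulationConfig()@loss)) <= 0))
})

test_that("control-well size and viability CVs match the configured targets", {
  # near-full plates of solvent controls, no images (viability CV) plus the
  # truth-level area CV; both within +/-50% relative of the targets
  cfg <- simulationConfig()
  map <- doseResponsePlateMap("x", doses = 1, wellsPerDose = 1,
                              nControls = 95, plateId = "cv")
  s <- simulatePlate(map, nullEffects("x"), cfg, seed = 9,
                     renderImages = FALSE)
  v <- relativeViability(s@luminescence, map)
  cvViab <- coefficientOfVariation(
    v$rel_viability[v$role == "solvent_control"])
  expect_gt(cvViab, 100 * cfg@cvTargets$viability * 0.5)
  expect_lt(cvViab, 100 * cfg@cvTargets$viability * 1.5)
  ctrl <- s@truth@wells[s@truth@wells$role == "solvent_control", ]
  cvSize <- coefficientOfVariation(pi * ctrl$radius_px^2)
  expect_gt(cvSize, 100 * cfg@cvTargets$size * 0.5)
  expect_lt(cvSize, 100 * cfg@cvTargets$size * 1.5)
})

test_that("rendered organoids present the features the pipeline gates on", {
  cfg <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0))
  acfg <- analysisConfig("primary")
  map <- primaryPlateMap("c1", 100, 1, plateId = "rnd")
  s <- simulatePlate(map, nullEffects("c1"), cfg, seed = 21, noise = FALSE)
  wl <- names(s@images)[1]
  m <- analyzeWell(s@images[[wl]], acfg)
  tw <- s@truth@wells[s@truth@wells$well == wl, ]
  expect_true(m$organoid_found)
  expect_identical(m$th_rois, tw$n_th_true)     # noise-free count equality
  # the denser Map2 population tolerates rare merges of near neighbours
  expect_gte(m$map2_rois, tw$n_map2_true - 2)
  expect_lte(m$map2_rois, tw$n_map2_true)
  # organoid with area ~4000 um^2 (radius ~36 px) fails the printed gate
  cfgSmall <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0),
                               organoid = list(radiusMean = 36,
                                               radiusCV = 0),
                               populations = list(th = list(n = 5),
                                                  map2 = list(n = 10)))
  sS <- simulatePlate(map, nullEffects("c1"), cfgSmall, seed = 21,
                      noise = FALSE)
  mS <- analyzeWell(sS@images[[wl]], acfg)
  expect_false(mS$organoid_found)
  expect_true(is.na(mS$th_sum))
})

test_that("wells with zero surviving TH cells yield no TH signal", {
  cfg <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0))
  eff <- list(kill = compoundEffect("kill", th = fourPL(0, 1, -3, 4)))
  map <- primaryPlateMap("kill", 100, 1, plateId = "z")
  s <- simulatePlate(map, eff, cfg, seed = 8, noise = FALSE)
  tw <- s@truth@wells
  wl <- tw$well[tw$compound_id == "kill" & !tw$lost]
  expect_equal(tw$n_th_true[tw$well == wl], 0)
  m <- analyzeWell(s@images[[wl]], analysisConfig("primary"))
  expect_false(m$th_signal_present)
  expect_true(is.na(m$th_sum))
})
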