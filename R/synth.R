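## Synthetic plate generator: dose-response survival, image rendering,
## luminescence, sample loss, and exported ground truth.

#' 4PL survival fraction at a concentration
#'
#' Evaluates `bottom + (top - bottom) / (1 + 10^((log10(c) - logIC50) * hill))`
#' — the variable-slope four-parameter logistic with the convention that a
#' positive Hill slope gives survival falling with dose from the `top`
#' (no-effect) plateau to `bottom`. The solvent concentration 0 maps to the
#' no-effect plateau (the limit as log-concentration goes to minus infinity:
#' `top` for positive Hill slopes).
#'
#' @param concentration concentration(s) in uM, >= 0
#' @param effect a [FourPLParams-class] with plateaus on the fraction scale
#' @return surviving fraction(s) in `[bottom, top]`, clamped to `[0, 1]`
#' @examples
#' survivalFraction(10, fourPL(0, 1, 1, 1))  # at IC50: 0.5
#' @export
survivalFraction <- function(concentration, effect) {
  stopifnot(all(concentration >= 0))
  x <- ifelse(concentration > 0, log10(concentration), -Inf)
  f <- ifelse(is.finite(x),
              effect@bottom + (effect@top - effect@bottom) /
                (1 + 10^((x - effect@logIC50) * effect@hill)),
              if (effect@hill > 0) effect@top else effect@bottom)
  pmin(1, pmax(0, f))
}

#' Deterministic per-well RNG substream seed
#'
#' Derived from (master seed, plate id, well) by a polynomial string hash so
#' that adding or removing a well never perturbs any other well's draws.
#'
#' @param master master seed (integer)
#' @param plateId plate identifier
#' @param well well coordinate
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
wellSeed <- function(master, plateId, well = "") {
  key <- paste0(plateId, "/", well)
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + (master %% 2147483647) * 48271) %% 2147483647)
}

#' Dose-dependent sample-loss probability
#'
#' Logistic in the viability fraction `v`, rescaled so that `p(1) = pFloor`
#' exactly (control conditions retain > 90% of samples for the default floor
#' of 0.05) and `p(0) = pMax` exactly; monotone non-increasing in `v`.
#'
#' @param v viability fraction(s) in `[0, 1]`
#' @param loss list(pFloor, pMax, steepness, midpoint)
#' @return loss probabilities
#' @export
lossProbability <- function(v, loss) {
  L <- function(u) plogis(-loss$steepness * (u - loss$midpoint))
  frac <- (L(v) - L(1)) / (L(0) - L(1))
  loss$pFloor + (loss$pMax - loss$pFloor) * frac
}

#' Draw Bernoulli sample-loss flags
#'
#' @param v viability fraction(s)
#' @param cfg a [SimulationConfig-class]
#' @return logical vector of lost flags (uses the current RNG stream)
#' @export
simulateSampleLoss <- function(v, cfg) {
  runif(length(v)) < lossProbability(v, cfg@loss)
}

#' Simulate technical-replicate luminescence readings for one well
#'
#' `reading = gain * perCellSignal * nCells * (1 + eps_well) * (1 + eps_rep)`
#' with `eps_well ~ N(0, wellCV)` shared across replicates and
#' `eps_rep ~ N(0, replicateCV)` per replicate. Two replicates in 3D mode,
#' one in 2D mode.
#'
#' @param nCells total surviving cells in the well
#' @param cfg a [SimulationConfig-class]
#' @param gain plate-level gain factor
#' @param replicates number of technical replicates (default from config)
#' @return numeric vector of readings
#' @export
simulateLuminescence <- function(nCells, cfg, gain = 1,
                                 replicates = cfg@luminescence$technicalReplicates) {
  lum <- cfg@luminescence
  wellFactor <- 1 + rnorm(1, 0, lum$wellCV)
  base <- gain * lum$perCellSignal * nCells * wellFactor
  pmax(0, base * (1 + rnorm(replicates, 0, lum$replicateCV)))
}

## Add a 2D Gaussian blob in place; returns the summed added intensity.
addBlob <- function(mat, x0, y0, amp, sigma) {
  n <- nrow(mat)
  r <- ceiling(4 * sigma)
  xs <- max(1, round(x0) - r):min(n, round(x0) + r)
  ys <- max(1, round(y0) - r):min(ncol(mat), round(y0) + r)
  g <- amp * exp(-(outer((xs - x0)^2, (ys - y0)^2, "+")) / (2 * sigma^2))
  mat[xs, ys] <- mat[xs, ys] + g
  list(mat = mat, integral = sum(g))
}

## Dart-throwing placement of n points in a disc with minimum separation.
placeInDisc <- function(n, cx, cy, radius, minSep) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  xs <- numeric(n); ys <- numeric(n); placed <- 0L; tries <- 0L
  while (placed < n && tries < 400L * n) {
    tries <- tries + 1L
    a <- runif(1, 0, 2 * pi); rr <- radius * sqrt(runif(1))
    x <- cx + rr * cos(a); y <- cy + rr * sin(a)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= minSep^2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  if (placed < n)
    stop("could not place ", n, " cells with separation ", minSep,
         " in organoid of radius ", radius)
  data.frame(x = xs, y = ys)
}

## Generate the per-well truth (geometry, surviving cells, dust) under the
## current RNG stream. Returns list(row, cells, dust).
generateWellTruth <- function(well, role, compoundId, concentration, effect,
                              cfg) {
  org <- cfg@organoid
  frame <- cfg@frame
  radius <- max(8, rnorm(1, org$radiusMean, org$radiusMean * org$radiusCV))
  cx <- frame / 2 + runif(1, -org$centerJitter, org$centerJitter)
  cy <- frame / 2 + runif(1, -org$centerJitter, org$centerJitter)
  if (radius + cfg@dust$margin >= frame / 2)
    stop("organoid (radius ", round(radius), " px) too large for a ", frame,
         " px frame")
  sfTH <- survivalFraction(concentration, effect@effectTH)
  sfMap2 <- survivalFraction(concentration, effect@effectMap2)
  sfViab <- survivalFraction(concentration, effect@effectViability)
  nThBase <- cfg@populations$th$n
  nMap2Base <- cfg@populations$map2$n
  nTh <- rbinom(1, nThBase, sfTH)
  nMap2 <- rbinom(1, nMap2Base, sfMap2)
  nViabCells <- rbinom(1, nThBase + nMap2Base, sfViab)
  inner <- radius - 7
  cells <- data.frame(x = numeric(0), y = numeric(0), plane = integer(0),
                      population = character(0), amplitude = numeric(0),
                      sigma = numeric(0))
  for (popName in c("th", "map2")) {
    pop <- cfg@populations[[popName]]
    nPop <- if (popName == "th") nTh else nMap2
    if (nPop > 0) {
      pos <- placeInDisc(nPop, cx, cy, inner,
                         pop$minSeparation %||% cfg@minSeparation)
      cells <- rbind(cells, data.frame(
        x = pos$x, y = pos$y,
        plane = sample.int(cfg@planes, nPop, replace = TRUE),
        population = popName,
        amplitude = rlnorm(nPop, pop$amplitudeMeanLog, pop$amplitudeSdLog),
        sigma = pop$sigma))
    }
  }
  nDust <- rpois(cfg@planes, cfg@dust$lambdaPerPlane)
  dust <- data.frame(x = numeric(0), y = numeric(0), plane = integer(0),
                     size = numeric(0), factor = numeric(0))
  for (p in seq_len(cfg@planes)) {
    if (nDust[p] == 0) next
    for (k in seq_len(nDust[p])) {
      repeat {  # uniform in frame, rejected until outside organoid + margin
        x <- runif(1, 3, frame - 3); y <- runif(1, 3, frame - 3)
        if ((x - cx)^2 + (y - cy)^2 > (radius + cfg@dust$margin)^2) break
      }
      dust <- rbind(dust, data.frame(
        x = x, y = y, plane = p,
        size = round(runif(1, cfg@dust$sizeRange[1], cfg@dust$sizeRange[2])),
        factor = runif(1, cfg@dust$brightnessFactor[1],
                       cfg@dust$brightnessFactor[2])))
    }
  }
  list(row = data.frame(well = well, role = role, compound_id = compoundId,
                        concentration_uM = concentration,
                        n_th_true = nTh, n_map2_true = nMap2,
                        n_viab_cells = nViabCells,
                        sf_th = sfTH, sf_map2 = sfMap2, sf_viability = sfViab,
                        center_x = cx, center_y = cy, radius_px = radius,
                        lost = FALSE, th_integral_true = NA_real_,
                        map2_integral_true = NA_real_),
       cells = cells, dust = dust)
}

#' Render the image stack for one well from its ground truth
#'
#' Produces a roughly circular organoid whose summed-channel region passes the
#' organoid gate at default thresholds: a bright nuclear (DAPI) disc with
#' nuclear spots, surviving TH+ cells as compact Gaussian blobs in the
#' dopaminergic channel, Map2+ blobs in the pan-neuronal channel, dust specks
#' strictly outside the organoid (small and dim enough to fail every gate),
#' a smooth planar background gradient in every channel, and — when `noise`
#' is `TRUE` — signal-proportional Gaussian noise plus an additive floor.
#'
#' @param truth a list as produced by the generator: `row` (one-row
#'   data.frame with organoid geometry), `cells`, `dust`
#' @param cfg a [SimulationConfig-class]
#' @param noise render with the configured noise model (set `FALSE` for
#'   noise-free oracle images)
#' @return list(stack = [ImageStack-class], thIntegral, map2Integral): the
#'   integrals are the summed rendered foreground intensities per population,
#'   the generator-side truth for intensity-integration checks
#' @export
renderOrganoidImage <- function(truth, cfg, noise = TRUE) {
  row <- truth$row
  frame <- cfg@frame
  if (row$radius_px + 2 >= frame / 2)
    stop("organoid larger than frame")
  nCh <- 3L
  arr <- array(0, c(frame, frame, nCh, cfg@planes))
  idx <- seq_len(frame)
  distsq <- outer((idx - row$center_x)^2, (idx - row$center_y)^2, "+")
  mask <- distsq <= row$radius_px^2
  # one smooth planar gradient direction per well, all channels
  ga <- runif(1, 0, 2 * pi)
  ramp <- outer(idx * cos(ga), idx * sin(ga), "+") / frame + 0.5
  thIntegral <- 0; map2Integral <- 0
  chOf <- c(th = 3L, map2 = 2L)
  for (p in seq_len(cfg@planes)) {
    planes <- vector("list", nCh)
    for (ch in seq_len(nCh)) {
      bg <- cfg@background[[CHANNEL_NAMES[ch]]]
      planes[[ch]] <- matrix(bg$base, frame, frame) + bg$gradient * ramp
    }
    # organoid body in the nuclear channel + nuclear spots
    org <- cfg@organoid
    planes[[1]] <- planes[[1]] + org$dapiBase * mask
    if (org$nucleiPerPlane > 0) {
      nuc <- placeInDisc(org$nucleiPerPlane, row$center_x, row$center_y,
                         row$radius_px - 3, 0)
      for (k in seq_len(nrow(nuc))) {
        res <- addBlob(planes[[1]], nuc$x[k], nuc$y[k], org$nucleusAmplitude,
                       org$nucleusSigma)
        planes[[1]] <- res$mat
      }
    }
    # surviving cells on this plane
    cc <- truth$cells[truth$cells$plane == p, , drop = FALSE]
    if (nrow(cc) > 0) for (k in seq_len(nrow(cc))) {
      ch <- chOf[[cc$population[k]]]
      res <- addBlob(planes[[ch]], cc$x[k], cc$y[k], cc$amplitude[k],
                     cc$sigma[k])
      planes[[ch]] <- res$mat
      if (cc$population[k] == "th") thIntegral <- thIntegral + res$integral
      else map2Integral <- map2Integral + res$integral
    }
    # dust outside the organoid, all channels, 2-3x local background
    dd <- truth$dust[truth$dust$plane == p, , drop = FALSE]
    if (nrow(dd) > 0) for (k in seq_len(nrow(dd))) {
      xs <- round(dd$x[k]) + seq_len(dd$size[k]) - 1L
      ys <- round(dd$y[k]) + seq_len(dd$size[k]) - 1L
      xs <- xs[xs >= 1 & xs <= frame]; ys <- ys[ys >= 1 & ys <= frame]
      for (ch in seq_len(nCh)) {
        bg <- cfg@background[[CHANNEL_NAMES[ch]]]
        planes[[ch]][xs, ys] <- planes[[ch]][xs, ys] +
          (dd$factor[k] - 1) * bg$base
      }
    }
    for (ch in seq_len(nCh)) {
      img <- planes[[ch]]
      if (noise) {
        img <- img * (1 + rnorm(length(img), 0, cfg@noise$cvSignal)) +
          rnorm(length(img), 0, cfg@noise$floorSd)
      }
      arr[, , ch, p] <- pmax(0, img)
    }
  }
  list(stack = imageStack(arr, pixelSize = cfg@pixelSize,
                          planeSpacing = cfg@planeSpacing),
       thIntegral = thIntegral, map2Integral = map2Integral)
}

#' Simulate a full plate: ground truth, images and luminescence
#'
#' Per well (deterministically seeded from `(seed, plateId, well)` so adding a
#' well never perturbs the others): surviving population counts are binomial
#' thinnings of the baseline counts at the compound's 4PL survival fraction;
#' dose-dependent Bernoulli sample loss removes wells (lost wells keep their
#' ground-truth row but have no image and no luminescence rows); retained
#' wells get a rendered [ImageStack-class] and technical-replicate
#' luminescence readings scaled by a plate-level gain.
#'
#' @param map a [PlateMap-class]
#' @param effects named list of [CompoundEffect-class] (by compound id)
#' @param cfg a [SimulationConfig-class]
#' @param seed master seed (integer)
#' @param renderImages set `FALSE` to skip image rendering (luminescence-only
#'   simulations, e.g. 2D culture mode)
#' @param noise render images with noise (default) or noise-free
#' @return a [SimulatedPlate-class]
#' @export
simulatePlate <- function(map, effects, cfg, seed, renderImages = TRUE,
                          noise = TRUE) {
  w <- map@wells[map@wells$role != "empty", , drop = FALSE]
  unknown <- setdiff(unique(w$compound_id[w$role == "treated"]),
                     names(effects))
  if (length(unknown))
    stop("unknown compound_id in layout: ", paste(unknown, collapse = ", "))
  set.seed(wellSeed(seed, map@plateId, "__plate__"))
  gain <- rlnorm(1, 0, cfg@luminescence$gainSdLog)
  rows <- vector("list", nrow(w))
  cells <- list(); dust <- list(); images <- list()
  lum <- list()
  noEff <- compoundEffect("none")
  for (i in seq_len(nrow(w))) {
    well <- w$well[i]
    set.seed(wellSeed(seed, map@plateId, well))
    eff <- if (w$role[i] == "treated") effects[[w$compound_id[i]]] else noEff
    conc <- if (w$role[i] == "treated") w$concentration_uM[i] else 0
    tr <- generateWellTruth(well, w$role[i], w$compound_id[i], conc, eff, cfg)
    tr$row$lost <- simulateSampleLoss(tr$row$sf_viability, cfg)
    if (!tr$row$lost) {
      if (renderImages) {
        rend <- renderOrganoidImage(tr, cfg, noise = noise)
        images[[well]] <- rend$stack
        tr$row$th_integral_true <- rend$thIntegral
        tr$row$map2_integral_true <- rend$map2Integral
      }
      lum[[well]] <- data.frame(
        plate = map@plateId, well = well,
        replicate = seq_len(cfg@luminescence$technicalReplicates),
        value = simulateLuminescence(tr$row$n_viab_cells, cfg, gain))
    }
    rows[[i]] <- tr$row
    cells[[well]] <- tr$cells
    dust[[well]] <- tr$dust
  }
  truth <- new("PlateGroundTruth", wells = do.call(rbind, rows),
               cells = cells, dust = dust, plateGain = gain)
  lumDf <- if (length(lum)) do.call(rbind, c(lum, make.row.names = FALSE))
           else data.frame(plate = character(0), well = character(0),
                           replicate = integer(0), value = numeric(0))
  new("SimulatedPlate", plateMap = map, truth = truth, images = images,
      luminescence = lumDf)
}

#' Build a primary-screen plate map
#'
#' One compound per treated well at a single screening concentration, plus
#' solvent-control wells (default four, the screen's per-plate DMSO count).
#'
#' @param compounds character vector of compound ids
#' @param concentration screening concentration in uM (default 100)
#' @param nControls number of solvent-control wells
#' @param plateId,cellLineId,exposureH plate metadata
#' @return a [PlateMap-class]
#' @export
primaryPlateMap <- function(compounds, concentration = 100, nControls = 4,
                            plateId = "plate1", cellLineId = "line1",
                            exposureH = 48) {
  coords <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  n <- length(compounds) + nControls
  if (n > 96) stop("layout exceeds 96 wells")
  ctrlIdx <- round(seq(1, n, length.out = nControls))
  role <- rep("treated", n); role[ctrlIdx] <- "solvent_control"
  cid <- character(n); conc <- numeric(n)
  cid[role == "treated"] <- compounds
  conc[role == "treated"] <- concentration
  wells <- data.frame(well = coords[seq_len(n)], compound_id = cid,
                      concentration_uM = conc,
                      solvent = ifelse(role == "solvent_control", "DMSO",
                                       "DMSO"),
                      role = role)
  new("PlateMap", plateId = plateId, cellLineId = cellLineId,
      exposureH = exposureH, wells = wells)
}

#' Build a dose-response plate map for one compound
#'
#' @param compound compound id
#' @param doses concentration series in uM (default the screening series
#'   0.01, 0.1, 1, 10, 50, 100, 200, 500, 1000)
#' @param wellsPerDose organoids per concentration (default 8)
#' @param nControls solvent-control wells (default 8)
#' @param plateId,cellLineId,exposureH plate metadata
#' @param solvent vehicle for treated wells
#' @return a [PlateMap-class]
#' @export
doseResponsePlateMap <- function(compound,
                                 doses = c(0.01, 0.1, 1, 10, 50, 100, 200,
                                           500, 1000),
                                 wellsPerDose = 8, nControls = 8,
                                 plateId = paste0("dr_", compound),
                                 cellLineId = "line1", exposureH = 48,
                                 solvent = "DMSO") {
  coords <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  n <- length(doses) * wellsPerDose + nControls
  if (n > 96) stop("layout exceeds 96 wells")
  wells <- data.frame(
    well = coords[seq_len(n)],
    compound_id = c(rep(compound, length(doses) * wellsPerDose),
                    rep("", nControls)),
    concentration_uM = c(rep(doses, each = wellsPerDose), rep(0, nControls)),
    solvent = solvent,
    role = c(rep("treated", length(doses) * wellsPerDose),
             rep("solvent_control", nControls)))
  new("PlateMap", plateId = plateId, cellLineId = cellLineId,
      exposureH = exposureH, wells = wells)
}
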