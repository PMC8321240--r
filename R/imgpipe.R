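## High-content image pipeline: organoid region detection and gating,
## background correction, cell-ROI detection/gating, intensity integration.

#' Per-pixel sum of all channels of one plane
#' @param stack an [ImageStack-class]
#' @param plane plane index (1-based)
#' @return numeric matrix
#' @export
sumChannels <- function(stack, plane) {
  d <- stack@data
  if (plane < 1 || plane > dim(d)[4]) stop("plane out of range")
  out <- d[, , 1, plane]
  for (ch in seq_len(dim(d)[3])[-1]) out <- out + d[, , ch, plane]
  out
}

#' Median filter with a circular footprint
#'
#' Each output pixel is the median of the input pixels within the circular
#' footprint of the given radius, with mirror (reflect) edge handling. Used
#' to remove small localized features (dust) from the channel sum before
#' organoid region detection.
#'
#' @param img numeric matrix
#' @param radius footprint radius in px (default 10)
#' @return filtered matrix
#' @export
medianFilterCircular <- function(img, radius = 10) {
  .cpp_median_filter(img, as.integer(radius))
}

#' Gaussian background correction
#'
#' Subtracts the Gaussian-smoothed image (standard deviation `sigma` px,
#' replicate edge handling) from the raw image; negative values are clipped
#' to 0. Removes smooth fluorescent background while retaining compact
#' cell-scale features.
#'
#' @param img numeric matrix
#' @param sigma Gaussian standard deviation in px
#' @return background-corrected (BC) matrix
#' @export
gaussianBackgroundCorrect <- function(img, sigma) {
  stopifnot(sigma > 0)
  radius <- 2 * ceiling(3 * sigma) + 1
  m <- min(dim(img)); if (m %% 2 == 0) m <- m - 1  # kernel must fit the image
  sm <- EBImage::gblur(img, sigma = sigma, radius = min(radius, m),
                       boundary = "replicate")
  pmax(img - sm, 0)
}

#' Sliding-parabola top-hat
#'
#' Estimates the background as the grayscale opening of the image with a
#' paraboloid structuring element `z(r) = -r^2 / curvature` and subtracts it
#' (clipping at 0). Larger curvature gives a flatter element, retaining more
#' of the image as background-free signal. The opening is computed exactly by
#' separable lower-envelope parabolic erosion/dilation.
#'
#' @param img numeric matrix
#' @param curvature paraboloid curvature parameter (> 0, default 10)
#' @return top-hat filtered matrix
#' @export
parabolaTophat <- function(img, curvature = 10) {
  pmax(img - .cpp_parabola_opening(img, curvature), 0)
}

## Chain-length perimeter of a binary mask via its oriented contour.
maskPerimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0) return(0)
  per <- 0
  for (ctr in oc) {
    if (nrow(ctr) < 2) next
    d <- sqrt(rowSums((ctr - ctr[c(2:nrow(ctr), 1), , drop = FALSE])^2))
    per <- per + sum(d)
  }
  per
}

#' Detect candidate organoid regions in a filtered channel-sum image
#'
#' Global Otsu threshold on the median-filtered channel sum, hole filling,
#' and 8-connected component labelling. Each component is returned with its
#' area (um^2), chain-length perimeter (um), roundness `4*pi*A/P^2` clamped
#' to `[0, 1]`, and mean nuclear intensity (computed on the raw nuclear
#' channel under the component mask).
#'
#' @param img median-filtered channel-sum matrix
#' @param nuclear raw nuclear-channel matrix (same shape)
#' @param pixelSize um/px
#' @return list of candidates, each `list(mask, areaPx, area, perimeter,
#'   roundness, meanNuclear)`; empty for blank/constant images
#' @export
findImageRegions <- function(img, nuclear, pixelSize = 1.0) {
  stopifnot(pixelSize > 0)
  rng <- range(img)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(list())
  thr <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)),
                       range = c(0, 1)) * diff(rng) + rng[1]
  bin <- img > thr
  if (!any(bin) || all(bin)) return(list())
  filled <- EBImage::fillHull(EBImage::Image(bin * 1)) > 0
  lab <- label8(filled)
  out <- list()
  for (l in seq_len(max(lab))) {
    m <- lab == l
    areaPx <- sum(m)
    per <- maskPerimeter(m)
    roundness <- if (per > 0) min(1, 4 * pi * areaPx / per^2) else 1
    out[[l]] <- list(mask = m, areaPx = areaPx,
                     area = areaPx * pixelSize^2,
                     perimeter = per * pixelSize,
                     roundness = roundness,
                     meanNuclear = mean(nuclear[m]))
  }
  out
}

## 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonal
## touching components are merged first by closing label equivalences over
## diagonal neighbours.
label8 <- function(bin) {
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (dr, dc) = (1,1) and (1,-1)
  pairs <- rbind(
    cbind(as.vector(lab[1:(nr - 1), 1:(nc - 1)]), as.vector(lab[2:nr, 2:nc])),
    cbind(as.vector(lab[2:nr, 1:(nc - 1)]), as.vector(lab[1:(nr - 1), 2:nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), findRoot, 1L)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Gate candidate organoid regions
#'
#' A candidate is retained iff `area > minArea` AND `roundness > minRoundness`
#' AND `meanNuclear > minNuclearMean` — strict inequalities, so
#' boundary-equal values are rejected. If several candidates pass, the one
#' with the largest area is the organoid.
#'
#' @param cands list of candidates from [findImageRegions()]
#' @param gate list(minArea, minRoundness, minNuclearMean) in um^2 / ratio /
#'   abu
#' @return the accepted candidate (with `$mask`), or `NULL` if none pass
#' @export
gateOrganoid <- function(cands, gate) {
  pass <- Filter(function(cd)
    cd$area > gate$minArea && cd$roundness > gate$minRoundness &&
      cd$meanNuclear > gate$minNuclearMean, cands)
  if (length(pass) == 0) return(NULL)
  pass[[which.max(vapply(pass, function(cd) cd$area, 0))]]
}

#' Detect cell ROIs within the organoid mask
#'
#' Local-maxima seeds above a robust noise floor (`max(median + k * MAD,
#' floor)` of the BC image inside the mask, minimum seed separation `s` px)
#' are grown by marker-based watershed (intensity-guided propagation) on the
#' BC image. Growth is restricted to mask pixels above a lower region floor
#' (`max(median + regionK * MAD, regionFloor)`) — hysteresis, so a segment
#' covers its cell's full footprint without bleeding into background. Each
#' segment is returned with its area, mean and maximum BC brightness, and
#' integrated raw-channel brightness.
#'
#' @param bc background-corrected matrix
#' @param mask logical organoid mask
#' @param raw raw-channel matrix for intensity integration
#' @param seeds list(k, minSeparation, floor), see [analysisConfig()]
#' @param pixelSize um/px
#' @return list of cell-ROI candidates, each `list(pixels, area, meanBC,
#'   maxBC, integratedRaw)`; `pixels` are linear indices into the raster
#' @export
findCells <- function(bc, mask, raw, seeds = list(k = 3, minSeparation = 4,
                                                  floor = 20, regionK = 1,
                                                  regionFloor = 8),
                      pixelSize = 1.0) {
  if (!any(mask)) stop("organoid mask is empty")
  vals <- bc[mask]
  thr <- max(median(vals) + seeds$k * mad(vals), seeds$floor)
  above <- mask & (bc > thr)
  if (!any(above)) return(list())
  brush <- EBImage::makeBrush(2 * seeds$minSeparation + 1, shape = "disc")
  mx <- EBImage::dilate(EBImage::Image(bc), brush)
  seedMask <- above & (bc >= as.matrix(EBImage::imageData(mx)))
  if (!any(seedMask)) return(list())
  thrRegion <- max(median(vals) + (seeds$regionK %||% seeds$k) * mad(vals),
                   seeds$regionFloor %||% seeds$floor)
  region <- mask & (bc > thrRegion)
  seedLab <- EBImage::bwlabel(EBImage::Image(seedMask * 1))
  seg <- EBImage::propagate(EBImage::Image(bc), seeds = seedLab,
                            mask = EBImage::Image(region * 1))
  seg <- as.matrix(EBImage::imageData(seg))
  out <- list()
  for (l in seq_len(max(seg))) {
    px <- which(seg == l)
    if (length(px) == 0) next
    out[[length(out) + 1]] <- list(
      pixels = px,
      area = length(px) * pixelSize^2,
      meanBC = mean(bc[px]),
      maxBC = max(bc[px]),
      integratedRaw = sum(raw[px]))
  }
  out
}

#' Gate cell ROIs by the active per-channel rule set
#'
#' All comparisons are strict, exactly as printed: primary TH+ needs
#' `area > 25` um^2 and mean BC brightness strictly between 200 and 2200 abu;
#' primary Map2+ needs `area > 10` um^2; dose-response TH+ needs `area > 10`
#' um^2 and maximum brightness `< 5000` abu.
#'
#' @param cands list of cell-ROI candidates from [findCells()]
#' @param gate per-channel gate list with `minArea` and optionally
#'   `meanBCRange` (length-2, exclusive bounds) or `maxBrightnessBelow`
#' @return the selected sublist
#' @export
gateCellROIs <- function(cands, gate) {
  Filter(function(cd) {
    if (!(cd$area > gate$minArea)) return(FALSE)
    if (!is.null(gate$meanBCRange) &&
        !(cd$meanBC > gate$meanBCRange[1] && cd$meanBC < gate$meanBCRange[2]))
      return(FALSE)
    if (!is.null(gate$maxBrightnessBelow) &&
        !(cd$maxBC < gate$maxBrightnessBelow))
      return(FALSE)
    TRUE
  }, cands)
}

#' Integrated raw-channel brightness over selected ROIs
#'
#' @param rois selected cell ROIs
#' @param raw raw-channel matrix
#' @return summed raw intensity over all ROI pixels (0 for an empty
#'   selection)
#' @export
integrateSelected <- function(rois, raw) {
  if (length(rois) == 0) return(0)
  sum(vapply(rois, function(r) sum(raw[r$pixels]), 0))
}

#' Analyse one well's image stack
#'
#' Per plane: organoid detection on the median-filtered channel sum and
#' gating; per-channel background correction (Gaussian for TH; Gaussian plus
#' sliding-parabola top-hat for Map2 in primary mode, Gaussian only in
#' dose-response mode); cell-ROI detection inside the organoid mask, gating,
#' and raw-channel intensity integration. Area and intensity sums accumulate
#' over planes. Degraded wells return flags, never exceptions:
#' `organoid_found` iff the gate passed on at least one plane, and each
#' channel's `signal_present` iff at least one selected ROI exists on at
#' least one plane; when a flag is `FALSE` the corresponding sum is `NA`,
#' not 0.
#'
#' @param stack an [ImageStack-class]
#' @param cfg an [AnalysisConfig-class]
#' @return list with `area_um2`, `th_sum`, `map2_sum`, `th_rois`,
#'   `map2_rois`, the three flags, and a per-plane data.frame `planes`
#' @export
analyzeWell <- function(stack, cfg) {
  nP <- dim(stack@data)[4]
  px <- cfg@pixelSize
  gates <- cfg@cellGate[[cfg@mode]]
  area <- 0; thSum <- 0; map2Sum <- 0; thN <- 0L; map2N <- 0L
  found <- FALSE
  planes <- vector("list", nP)
  for (p in seq_len(nP)) {
    nuclear <- stack@data[, , match("nuclear", stack@channels), p]
    pan <- stack@data[, , match("pan_neuronal", stack@channels), p]
    dopa <- stack@data[, , match("dopaminergic", stack@channels), p]
    med <- medianFilterCircular(sumChannels(stack, p),
                                cfg@filters$medianRadius)
    org <- gateOrganoid(findImageRegions(med, nuclear, px), cfg@organoidGate)
    if (is.null(org)) {
      planes[[p]] <- data.frame(plane = p, organoid = FALSE, area_um2 = NA,
                                th_sum = NA, map2_sum = NA, th_rois = 0L,
                                map2_rois = 0L)
      next
    }
    found <- TRUE
    bcTH <- gaussianBackgroundCorrect(dopa, cfg@filters$thGaussianSigma)
    bcM <- gaussianBackgroundCorrect(pan, cfg@filters$map2GaussianSigma)
    if (isTRUE(cfg@filters$map2UseParabola))
      bcM <- parabolaTophat(bcM, cfg@filters$parabolaCurvature)
    selTH <- gateCellROIs(findCells(bcTH, org$mask, dopa, cfg@seeds, px),
                          gates$dopaminergic)
    selM <- gateCellROIs(findCells(bcM, org$mask, pan, cfg@seeds, px),
                         gates$pan_neuronal)
    pTh <- integrateSelected(selTH, dopa)
    pM <- integrateSelected(selM, pan)
    area <- area + org$area
    thSum <- thSum + pTh; map2Sum <- map2Sum + pM
    thN <- thN + length(selTH); map2N <- map2N + length(selM)
    planes[[p]] <- data.frame(plane = p, organoid = TRUE, area_um2 = org$area,
                              th_sum = pTh, map2_sum = pM,
                              th_rois = length(selTH),
                              map2_rois = length(selM))
  }
  list(area_um2 = if (found) area else NA_real_,
       th_sum = if (found && thN > 0) thSum else NA_real_,
       map2_sum = if (found && map2N > 0) map2Sum else NA_real_,
       th_rois = thN, map2_rois = map2N,
       organoid_found = found,
       th_signal_present = found && thN > 0,
       map2_signal_present = found && map2N > 0,
       planes = do.call(rbind, planes))
}

#' Analyse all imaged wells of a simulated (or loaded) plate
#'
#' @param images named list of [ImageStack-class] by well
#' @param cfg an [AnalysisConfig-class]
#' @param plate plate identifier recorded in the output
#' @return data.frame, one row per well: plate, well, area_um2, th_sum,
#'   map2_sum, ROI counts and QC flags
#' @export
analyzeImages <- function(images, cfg, plate = "plate1") {
  rows <- lapply(names(images), function(wl) {
    m <- analyzeWell(images[[wl]], cfg)
    data.frame(plate = plate, well = wl, area_um2 = m$area_um2,
               th_sum = m$th_sum, map2_sum = m$map2_sum,
               th_rois = m$th_rois, map2_rois = m$map2_rois,
               organoid_found = m$organoid_found,
               th_signal_present = m$th_signal_present,
               map2_signal_present = m$map2_signal_present)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
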