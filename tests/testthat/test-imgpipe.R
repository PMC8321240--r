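test_that("channel sums equal the per-pixel loop oracle", {
  arr <- array(0, c(6, 6, 3, 1))
  arr[, , 1, 1] <- 10; arr[, , 2, 1] <- 20; arr[, , 3, 1] <- 30
  st <- imageStack(arr)
  expect_true(all(sumChannels(st, 1) == 60))
  set.seed(4)
  arr2 <- array(runif(6 * 6 * 3 * 2) * 100, c(6, 6, 3, 2))
  st2 <- imageStack(arr2)
  s <- sumChannels(st2, 2)
  for (i in 1:6) for (j in 1:6)
    expect_equal(s[i, j], arr2[i, j, 1, 2] + arr2[i, j, 2, 2] +
                   arr2[i, j, 3, 2])
  expect_error(sumChannels(st2, 3), "plane out of range")
})

test_that("circular median filter: constants, hot pixels, brute-force oracle", {
  const <- matrix(7, 24, 24)
  expect_equal(medianFilterCircular(const, 10), const)
  hot <- matrix(0, 32, 32); hot[16, 16] <- 1000
  expect_equal(medianFilterCircular(hot, 10)[16, 16], 0)
  set.seed(11)
  img <- matrix(runif(32 * 32) * 1000, 32, 32)
  for (r in c(2, 3, 5))
    expect_equal(medianFilterCircular(img, r), bruteMedianFilter(img, r))
})

test_that("region detection finds discs and ignores blank images", {
  expect_length(findImageRegions(matrix(0, 64, 64), matrix(0, 64, 64)), 0)
  expect_length(findImageRegions(matrix(5, 64, 64), matrix(0, 64, 64)), 0)
  idx <- seq_len(160)
  disc <- outer((idx - 80)^2, (idx - 80)^2, "+") <= 60^2
  img <- disc * 300 + 10
  nuc <- disc * 250
  cands <- findImageRegions(img, nuc)
  expect_length(cands, 1)
  expect_gte(sum(cands[[1]]$mask & disc) / sum(disc), 0.95)
  expect_gt(cands[[1]]$roundness, 0.8)
  expect_equal(cands[[1]]$meanNuclear, mean(nuc[cands[[1]]$mask]))
  # two separated discs
  d2 <- (outer((idx - 40)^2, (idx - 40)^2, "+") <= 25^2) |
    (outer((idx - 115)^2, (idx - 115)^2, "+") <= 25^2)
  expect_length(findImageRegions(d2 * 300 + 5, d2 * 200), 2)
})

test_that("diagonal-touching components are 8-connected", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE  # diagonal chain
  img <- m * 100 + 1
  cands <- findImageRegions(img, img)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$areaPx, 3)
})

test_that("organoid gating applies the printed thresholds strictly", {
  gate <- analysisConfig("primary")@organoidGate
  mk <- function(area, roundness, dapi)
    list(area = area, roundness = roundness, meanNuclear = dapi,
         mask = NULL, areaPx = NA, perimeter = NA)
  expect_false(is.null(gateOrganoid(list(mk(9500, 0.5, 200)), gate)))
  expect_null(gateOrganoid(list(mk(8999, 0.9, 250)), gate))
  expect_null(gateOrganoid(list(mk(20000, 0.39, 250)), gate))
  # boundary-equal values are rejected (strict inequalities as printed)
  expect_null(gateOrganoid(list(mk(9000, 0.5, 250)), gate))
  expect_null(gateOrganoid(list(mk(9500, 0.4, 250)), gate))
  expect_null(gateOrganoid(list(mk(9500, 0.5, 190)), gate))
  # largest passing candidate wins
  got <- gateOrganoid(list(mk(9500, 0.5, 200), mk(15000, 0.6, 300)), gate)
  expect_equal(got$area, 15000)
})

test_that("Gaussian background correction removes smooth structure only", {
  expect_true(all(gaussianBackgroundCorrect(matrix(50, 40, 40), 10) == 0))
  ramp <- outer(seq(0, 100, length.out = 64), rep(1, 64))
  bc <- gaussianBackgroundCorrect(ramp, 5)
  interior <- bc[17:48, 17:48]
  expect_lt(mean(interior), 1)  # < 1% of the 0-100 ramp range
  # impulse response vs a direct normalized-Gaussian convolution oracle
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1000
  bcImp <- gaussianBackgroundCorrect(imp, 4)
  expect_gt(bcImp[21, 21], 0)
  expect_lt(bcImp[21, 21], 1000)
  r <- 2 * ceiling(3 * 4) + 1
  off <- seq_len(r) - (r + 1) / 2
  k1 <- dnorm(off, 0, 4); K <- outer(k1, k1); K <- K / sum(K)
  expect_equal(bcImp[21, 21], 1000 - 1000 * K[(r + 1) / 2, (r + 1) / 2],
               tolerance = 1e-10)
  expect_equal(bcImp[21, 25], max(0 - 1000 * K[(r + 1) / 2, (r + 1) / 2 + 4], 0))
})

test_that("sliding-parabola top-hat: constants, self-fit, spike retention", {
  expect_true(all(parabolaTophat(matrix(123, 48, 48), 10) == 0))
  idx <- seq_len(64)
  cap <- pmax(500 - outer((idx - 32)^2, (idx - 32)^2, "+") / 10, 0)
  expect_lt(max(parabolaTophat(cap, 10)), 0.01 * 500)
  spike <- matrix(20, 48, 48); spike[25, 25] <- 1020
  th <- parabolaTophat(spike, 10)
  expect_gt(th[25, 25], 0.95 * 1000)
})

test_that("cell detection finds separated blobs inside the mask only", {
  n <- 96
  mask <- outer((seq_len(n) - 48)^2, (seq_len(n) - 48)^2, "+") <= 40^2
  bc <- matrix(0, n, n)
  centers <- rbind(c(30, 48), c(60, 40), c(48, 65), c(70, 60))
  for (k in seq_len(nrow(centers))) {
    xs <- pmax(1, centers[k, 1] - 8):pmin(n, centers[k, 1] + 8)
    ys <- pmax(1, centers[k, 2] - 8):pmin(n, centers[k, 2] + 8)
    bc[xs, ys] <- bc[xs, ys] +
      900 * exp(-(outer((xs - centers[k, 1])^2, (ys - centers[k, 2])^2,
                        "+")) / 8)
  }
  outside <- c(5, 5)  # blob outside the mask
  bc[3:7, 3:7] <- 800
  cells <- findCells(bc, mask, raw = bc)
  expect_length(cells, 4)
  expect_true(all(vapply(cells, function(cd) all(mask[cd$pixels]), TRUE)))
  expect_length(findCells(matrix(0, n, n), mask, raw = matrix(0, n, n)), 0)
  expect_error(findCells(bc, matrix(FALSE, n, n), bc), "mask is empty")
})

test_that("cell gating matches the printed rules and a brute predicate", {
  gates <- analysisConfig("primary")@cellGate
  gateTH <- gates$primary$dopaminergic
  mk <- function(area, meanBC, maxBC = 0)
    list(pixels = integer(0), area = area, meanBC = meanBC, maxBC = maxBC,
         integratedRaw = 0)
  expect_length(gateCellROIs(list(mk(30, 1000)), gateTH), 1)
  expect_length(gateCellROIs(list(mk(30, 2500)), gateTH), 0)
  expect_length(gateCellROIs(list(mk(30, 200)), gateTH), 0)   # boundary
  expect_length(gateCellROIs(list(mk(25, 1000)), gateTH), 0)  # boundary
  gateDR <- analysisConfig("dose_response")@cellGate$dose_response$dopaminergic
  expect_length(gateCellROIs(list(mk(15, 0, 5500)), gateDR), 0)
  expect_length(gateCellROIs(list(mk(15, 0, 4000)), gateDR), 1)
  # randomized equivalence with an independently coded predicate
  set.seed(99)
  for (rep in 1:20) {
    cands <- randomCellCandidates(30)
    for (g in list(gateTH, gateDR, gates$primary$pan_neuronal)) {
      got <- gateCellROIs(cands, g)
      want <- Filter(function(cd) bruteCellGate(cd, g), cands)
      expect_identical(got, want)
    }
  }
})

test_that("gating is idempotent and order-independent", {
  set.seed(5)
  gate <- analysisConfig("primary")@cellGate$primary$dopaminergic
  cands <- randomCellCandidates(40)
  sel <- gateCellROIs(cands, gate)
  expect_identical(gateCellROIs(sel, gate), sel)
  perm <- sample(length(cands))
  selPerm <- gateCellROIs(cands[perm], gate)
  expect_setequal(vapply(selPerm, function(x) x$meanBC, 0),
                  vapply(sel, function(x) x$meanBC, 0))
})

test_that("intensity integration is additive and equals the loop oracle", {
  raw <- matrix(runif(32 * 32) * 100, 32, 32)
  expect_equal(integrateSelected(list(), raw), 0)
  r1 <- list(pixels = 1:10); r2 <- list(pixels = 101:140)
  expect_equal(integrateSelected(list(r1, r2), raw),
               integrateSelected(list(r1), raw) +
                 integrateSelected(list(r2), raw))
  acc <- 0
  for (p in r1$pixels) acc <- acc + raw[p]
  for (p in r2$pixels) acc <- acc + raw[p]
  expect_equal(integrateSelected(list(r1, r2), raw), acc)
})

test_that("duplicating every plane exactly doubles the accumulated sums", {
  cfg <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0))
  map <- primaryPlateMap("c1", 100, 1, plateId = "dup")
  s <- simulatePlate(map, nullEffects("c1"), cfg, seed = 31)
  st <- s@images[[1]]
  st2 <- imageStack(st@data[, , , c(1, 1), drop = FALSE])
  acfg <- analysisConfig("primary")
  m1 <- analyzeWell(st, acfg)
  m2 <- analyzeWell(st2, acfg)
  expect_equal(m2$th_sum, 2 * m1$th_sum)
  expect_equal(m2$map2_sum, 2 * m1$map2_sum)
  expect_equal(m2$area_um2, 2 * m1$area_um2)
})

test_that("pipeline output is invariant to dust outside the organoid", {
  cfg <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0),
                          dust = list(lambdaPerPlane = 6))
  map <- primaryPlateMap("c1", 100, 1, plateId = "dust")
  s <- simulatePlate(map, nullEffects("c1"), cfg, seed = 17,
                     renderImages = FALSE)
  wl <- s@truth@wells$well[1]
  truth <- list(row = s@truth@wells[1, ], cells = s@truth@cells[[wl]],
                dust = s@truth@dust[[wl]])
  expect_gt(nrow(truth$dust), 0)
  noDust <- truth; noDust$dust <- truth$dust[0, ]
  set.seed(1234); withD <- renderOrganoidImage(truth, cfg)
  set.seed(1234); without <- renderOrganoidImage(noDust, cfg)
  acfg <- analysisConfig("primary")
  mD <- analyzeWell(withD$stack, acfg)
  m0 <- analyzeWell(without$stack, acfg)
  expect_equal(mD$th_sum, m0$th_sum)
  expect_equal(mD$map2_sum, m0$map2_sum)
  expect_equal(mD$area_um2, m0$area_um2)
  expect_identical(mD$th_rois, m0$th_rois)
})

test_that("scaling one channel scales its integrated sum by at most that gain", {
  cfg <- simulationConfig(planes = 1, loss = list(pFloor = 0, pMax = 0))
  map <- primaryPlateMap("c1", 100, 1, plateId = "gain")
  s <- simulatePlate(map, nullEffects("c1"), cfg, seed = 23, noise = FALSE)
  st <- s@images[[1]]
  g <- 1.5
  arr <- st@data
  arr[, , 3, ] <- arr[, , 3, ] * g
  stG <- imageStack(arr)
  acfg <- analysisConfig("primary")
  m1 <- analyzeWell(st, acfg)
  mG <- analyzeWell(stG, acfg)
  # gating on the scaled BC image may drop ROIs; the sum is bounded by g
  expect_lte(mG$th_sum, g * m1$th_sum * (1 + 1e-9))
  expect_gt(mG$th_sum, 0)
})
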