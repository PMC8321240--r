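# Independent oracles and fixture builders, coded separately from the
# package implementation paths they check.

# Brute-force circular-footprint median filter with mirror edges.
bruteMedianFilter <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  ref <- function(i, nn) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > nn, 2 * nn - i + 1, i)
  }
  grid <- expand.grid(a = -r:r, b = -r:r)
  grid <- grid[grid$a^2 + grid$b^2 <= r^2, ]
  out <- img
  for (i in seq_len(n)) for (j in seq_len(m)) {
    out[i, j] <- median(img[cbind(ref(i + grid$a, n), ref(j + grid$b, m))])
  }
  out
}

# Independently coded gate predicates (plain logical expressions).
bruteOrganoidGate <- function(cand, gate) {
  cand$area > gate$minArea && cand$roundness > gate$minRoundness &&
    cand$meanNuclear > gate$minNuclearMean
}

bruteCellGate <- function(cand, gate) {
  ok <- cand$area > gate$minArea
  if (!is.null(gate$meanBCRange))
    ok <- ok && cand$meanBC > gate$meanBCRange[1] &&
      cand$meanBC < gate$meanBCRange[2]
  if (!is.null(gate$maxBrightnessBelow))
    ok <- ok && cand$maxBC < gate$maxBrightnessBelow
  ok
}

# Closed-form pooled-variance t-test.
bruteTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Independent 4PL evaluation (survival convention: hill > 0 falls with dose).
brute4PL <- function(bottom, top, logIC50, hill, x) {
  bottom + (top - bottom) / (1 + 10^((x - logIC50) * hill))
}

# Random candidate-set generators for gate-equivalence checks.
randomOrganoidCandidates <- function(n) {
  lapply(seq_len(n), function(i)
    list(area = runif(1, 2000, 30000), roundness = runif(1),
         meanNuclear = runif(1, 0, 600),
         mask = NULL, areaPx = NA, perimeter = NA))
}

randomCellCandidates <- function(n) {
  lapply(seq_len(n), function(i)
    list(pixels = integer(0), area = runif(1, 1, 80),
         meanBC = runif(1, 0, 3000), maxBC = runif(1, 0, 7000),
         integratedRaw = runif(1, 0, 1e5)))
}

# A tiny valid plate-map CSV on disk; returns the path.
writeTestPlateMapCSV <- function(path, nCompounds = 6, nControls = 4,
                                 duplicateWell = NULL, dropControls = FALSE,
                                 negativeConc = FALSE) {
  coords <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  n <- nCompounds + nControls
  df <- data.frame(
    well = coords[seq_len(n)],
    compound_id = c(paste0("cpd", seq_len(nCompounds)), rep("", nControls)),
    concentration_uM = c(rep(100, nCompounds), rep(0, nControls)),
    solvent = "DMSO",
    role = c(rep("treated", nCompounds), rep("solvent_control", nControls)))
  if (!is.null(duplicateWell)) df$well[2:3] <- duplicateWell
  if (dropControls) df <- df[df$role != "solvent_control", ]
  if (negativeConc) df$concentration_uM[1] <- -5
  write.csv(df, path, row.names = FALSE)
  path
}

# Shared small effect tables.
nullEffects <- function(ids) {
  setNames(lapply(ids, compoundEffect), ids)
}
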