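## Readers and writers: plate maps (CSV), image stacks (multi-page TIFF with a
## JSON sidecar), luminescence and result tables (CSV), ground truth (JSON).

#' Construct an ImageStack from an array
#'
#' @param data 4D numeric array `[row, col, channel, plane]`, or a 3D array
#'   `[row, col, channel]` for a single plane
#' @param channels channel names for the 3rd dimension
#' @param pixelSize um/px (default 1; override for real acquisitions)
#' @param planeSpacing um between planes (default 36.6, the acquisition
#'   spacing used to avoid double-sampling morphological features)
#' @return an [ImageStack-class]
#' @export
imageStack <- function(data, channels = CHANNEL_NAMES, pixelSize = 1.0,
                       planeSpacing = 36.6) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  new("ImageStack", data = data, channels = channels, pixelSize = pixelSize,
      planeSpacing = planeSpacing)
}

#' Read a plate map from CSV
#'
#' Expected header: `well,compound_id,concentration_uM,solvent,role`.
#' Validation rejects malformed or duplicate well coordinates, negative
#' concentrations and plates without solvent-control wells, naming the
#' offending entry.
#'
#' @param path CSV file
#' @param plateId,cellLineId,exposureH plate metadata (not stored in the CSV)
#' @return a [PlateMap-class]
#' @export
readPlateMap <- function(path, plateId = basename(path), cellLineId = "line1",
                         exposureH = 48) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "compound_id", "concentration_uM", "solvent", "role")
  if (!all(need %in% names(df)))
    stop("plate map must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$compound_id <- as.character(df$compound_id)
  df$compound_id[is.na(df$compound_id)] <- ""
  new("PlateMap", plateId = plateId, cellLineId = cellLineId,
      exposureH = exposureH, wells = df)
}

#' Write a plate map to CSV
#' @param map a [PlateMap-class]
#' @param path output CSV path
#' @export
writePlateMap <- function(map, path) {
  write.csv(map@wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write an image stack as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pages are ordered plane-major (plane 1 channels 1..C, plane 2 channels
#' 1..C, ...). Intensities are rounded to integers and clipped to the 16-bit
#' range. Channel names and spatial calibration go to `<path>.json`.
#'
#' @param stack an [ImageStack-class]
#' @param path output `.tif` path
#' @export
writeImageStack <- function(stack, path) {
  d <- stack@data
  nC <- dim(d)[3]; nP <- dim(d)[4]
  pages <- vector("list", nC * nP)
  i <- 1L
  for (p in seq_len(nP)) for (ch in seq_len(nC)) {
    pages[[i]] <- pmin(pmax(round(d[, , ch, p]), 0), 65535) / 65535
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  jsonlite::write_json(
    list(channels = stack@channels, pixel_size_um = stack@pixelSize,
         plane_spacing_um = stack@planeSpacing, planes = nP),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' Inverse of [writeImageStack()]; bit-identical on integer pixel data within
#' the 16-bit range. Calibration defaults come from the JSON sidecar and may
#' be overridden.
#'
#' @param path `.tif` file (pages plane-major, see [writeImageStack()])
#' @param channelNames,pixelSize,planeSpacing overrides for the sidecar values
#' @return an [ImageStack-class]
#' @export
readImageStack <- function(path, channelNames = NULL, pixelSize = NULL,
                           planeSpacing = NULL) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  channelNames <- channelNames %||% meta$channels %||% CHANNEL_NAMES
  pixelSize <- pixelSize %||% meta$pixel_size_um %||% 1.0
  planeSpacing <- planeSpacing %||% meta$plane_spacing_um %||% 36.6
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nC <- length(channelNames)
  if (length(pages) %% nC != 0)
    stop("page count (", length(pages), ") not divisible by channel count (",
         nC, ")")
  nP <- length(pages) %/% nC
  dd <- dim(pages[[1]])
  arr <- array(0, c(dd[1], dd[2], nC, nP))
  i <- 1L
  for (p in seq_len(nP)) for (ch in seq_len(nC)) {
    arr[, , ch, p] <- pages[[i]]
    i <- i + 1L
  }
  imageStack(arr, channels = channelNames, pixelSize = pixelSize,
             planeSpacing = planeSpacing)
}

#' Write a results/measurement table to CSV
#'
#' Columns are written in a stable order (input order); missing values are
#' written as empty fields, never as 0.
#'
#' @param records a data.frame (or list of homogeneous rows)
#' @param path output CSV path
#' @export
writeResultsTable <- function(records, path) {
  df <- as.data.frame(records)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write results table to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a results/measurement table written by [writeResultsTable()]
#' @param path CSV file
#' @return data.frame (empty fields become `NA`)
#' @export
readResultsTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Read a per-well luminescence table
#'
#' Expected columns: `plate, well, replicate, value`.
#' @param path CSV file
#' @return data.frame
#' @export
readLuminescence <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "well", "replicate", "value")
  if (!all(need %in% names(df)))
    stop("luminescence table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Export plate ground truth as JSON
#' @param truth a [PlateGroundTruth-class]
#' @param path output `.json` path
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(plate_gain = truth@plateGain, wells = truth@wells,
         cells = truth@cells, dust = truth@dust),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
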