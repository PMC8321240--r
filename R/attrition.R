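## Sample-attrition "emulated survival curve": averaging remaining-sample
## counts, rounding, event construction over the concentration index,
## censoring, and the resulting step function.

#' Average remaining-sample counts across series
#'
#' Arithmetic mean per concentration grid point across compounds, cell lines
#' and readouts. All series must share the same concentration grid.
#'
#' @param counts a numeric matrix (series in rows, grid points in columns) or
#'   a list of equal-length numeric vectors
#' @return mean count per grid point
#' @export
averageRemaining <- function(counts) {
  if (is.list(counts)) {
    len <- vapply(counts, length, 0L)
    if (length(unique(len)) != 1)
      stop("misaligned concentration grids: series lengths ",
           paste(unique(len), collapse = ", "))
    counts <- do.call(rbind, counts)
  }
  colMeans(counts)
}

#' Round counts half-away-from-zero
#'
#' The tie rule of common spreadsheet rounding: 7.5 rounds to 8 (base R's
#' `round()` rounds half to even and is not used here).
#'
#' @param x non-negative mean counts
#' @return integer counts
#' @examples
#' roundCounts(c(7.4, 7.5, 7.6))  # 7 8 8
#' @export
roundCounts <- function(x) {
  stopifnot(all(x >= 0))
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Build the attrition event series from rounded counts
#'
#' Counts are indexed by x = 0 (solvent control) to K (highest tested
#' concentration, each concentration step incrementing x by 1). Every unit
#' drop of the rounded count at some x is an event (multiplicity = size of
#' the drop); a censoring entry is placed one step after the highest
#' concentration (x = K + 1) carrying the samples remaining at the end.
#' Count increases along x are rejected — the procedure presumes monotone
#' loss.
#'
#' @param counts integer remaining-sample counts over x = 0..K
#' @return an [AttritionSeries-class]
#' @examples
#' s <- buildAttritionSeries(c(8, 8, 8, 7, 7, 7, 7, 7, 7, 7))
#' s@events  # one event at x = 3
#' @export
buildAttritionSeries <- function(counts) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  K <- length(counts) - 1L
  drops <- diff(counts)
  if (any(drops > 0))
    stop("count increase along the concentration index: non-monotone input")
  ev <- which(drops < 0)
  events <- data.frame(x = as.integer(ev), multiplicity = as.integer(-drops[ev]))
  new("AttritionSeries", x = 0:K, counts = counts, events = events,
      censoredAt = K + 1L, nCensored = counts[K + 1L])
}

#' Kaplan-Meier-style step function of an attrition series
#'
#' Starts at 1.0 and drops by `multiplicity / initial count` at each event
#' x; flat through the censoring entry. With no censoring before the end,
#' this equals the remaining fraction `count[x] / count[0]`.
#'
#' @param series an [AttritionSeries-class]
#' @return data.frame(x, fraction) over x = 0..censoredAt
#' @export
stepCurve <- function(series) {
  n0 <- series@counts[1]
  xs <- 0:series@censoredAt
  frac <- rep(1, length(xs))
  for (i in seq_len(nrow(series@events))) {
    ev <- series@events[i, ]
    frac[xs >= ev$x] <- frac[xs >= ev$x] - ev$multiplicity / n0
  }
  data.frame(x = xs, fraction = frac)
}

#' Count remaining (non-lost) samples per concentration from ground truth
#'
#' @param truth a [PlateGroundTruth-class] from a dose-response plate
#' @return data.frame(concentration_uM, remaining) with the solvent control
#'   first
#' @export
remainingByConcentration <- function(truth) {
  w <- truth@wells
  agg <- stats::aggregate(!w$lost, by = list(concentration_uM = w$concentration_uM),
                          FUN = sum)
  names(agg)[2] <- "remaining"
  agg[order(agg$concentration_uM), ]
}
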