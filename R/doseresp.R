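## Four-parameter logistic dose-response fitting and IC50 extraction.

#' Log10-transform a concentration series including solvent controls
#'
#' Nonzero concentrations map to `log10(c)`. The solvent control (0 uM) is
#' placed at the log10 of the lowest tested nonzero concentration, since the
#' log of 0 is undefined — with the standard screening series starting at
#' 0.01 uM this is x = -2.
#'
#' @param concentration numeric vector in uM (0 allowed for solvent
#'   controls)
#' @return log10 concentrations
#' @examples
#' logTransformConcentrations(c(0, 0.01, 0.1, 1))  # first value -> -2
#' @export
logTransformConcentrations <- function(concentration) {
  stopifnot(all(concentration >= 0))
  nz <- concentration[concentration > 0]
  if (length(nz) == 0) stop("all-zero concentration series")
  x <- ifelse(concentration > 0, log10(concentration), log10(min(nz)))
  x
}

#' Evaluate a 4PL curve
#'
#' `y = bottom + (top - bottom) / (1 + 10^((x - logIC50) * hill))`; the
#' response at `x = logIC50` is the midpoint `(top + bottom) / 2`, and for
#' `hill > 0` the response falls from `top` (low dose) to `bottom` (high
#' dose).
#'
#' @param curve a [DoseResponseFit-class], [FourPLParams-class], or a list
#'   with fields bottom, top, logIC50, hill
#' @param x log10 concentration(s)
#' @return predicted response(s)
#' @export
predictFourPL <- function(curve, x) {
  p <- if (is(curve, "DoseResponseFit") || is(curve, "FourPLParams"))
    list(bottom = curve@bottom, top = curve@top, logIC50 = curve@logIC50,
         hill = curve@hill) else curve
  p$bottom + (p$top - p$bottom) / (1 + 10^((x - p$logIC50) * p$hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Levenberg-Marquardt least squares of the variable-slope 4PL on
#' log10-concentration x. Initialization heuristic: `top = max(y)`,
#' `bottom = min(y)`, `logIC50` = the x whose response is nearest the
#' half-range, Hill slope of magnitude 1 with sign taken from the y-trend.
#' No parameter bounds by default; optional box bounds may be supplied. The
#' convergence flag is honest: [ic50()] refuses to report for non-converged
#' or unidentifiable (near-constant response) fits.
#'
#' @param x log10 concentrations (use [logTransformConcentrations()])
#' @param y responses (e.g. percent of control)
#' @param start optional named list overriding the initialization
#' @param lower,upper optional bounds (length-4: bottom, top, logIC50, hill)
#' @return a [DoseResponseFit-class]
#' @export
fitFourPL <- function(x, y, start = NULL, lower = NULL, upper = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need >= 5 points to fit a 4PL")
  if (diff(range(x)) < 2)
    warning("concentration span below 2 log units; fit may be unstable")
  yr <- diff(range(y))
  if (yr < 1e-10 * max(1, abs(mean(y)))) {
    return(new("DoseResponseFit", bottom = mean(y), top = mean(y),
               logIC50 = NA_real_, hill = NA_real_, rss = 0,
               converged = FALSE, n = length(x),
               message = "constant response: curve unidentifiable"))
  }
  if (is.null(start)) {
    mid <- (max(y) + min(y)) / 2
    trend <- suppressWarnings(cor(x, y))
    if (!is.finite(trend)) trend <- -1
    start <- list(bottom = min(y), top = max(y),
                  logIC50 = x[which.min(abs(y - mid))],
                  hill = if (trend <= 0) 1 else -1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((x - logIC50) * hill)),
      data = data.frame(x = x, y = y), start = start,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 1024, maxfev = 10000)),
    error = function(e) e)
  if (!inherits(fit, "error")) {
    cf <- coef(fit)
    info <- fit$convInfo
    conv <- isTRUE(info$isConv) && is.finite(cf[["logIC50"]]) &&
      abs(cf[["hill"]]) > 1e-6
    msg <- if (conv) "converged" else
      if (abs(cf[["hill"]]) <= 1e-6) "hill ~ 0: curve unidentifiable"
      else info$stopMessage %||% "did not converge"
    return(new("DoseResponseFit", bottom = unname(cf["bottom"]),
               top = unname(cf["top"]), logIC50 = unname(cf["logIC50"]),
               hill = unname(cf["hill"]), rss = sum(resid(fit)^2),
               converged = conv, n = length(x), message = msg))
  }
  # Fall back to direct least squares (Nelder-Mead then BFGS) when the
  # LM path cannot even be initialized (e.g. rank-deficient Jacobian at the
  # start values on degenerate designs).
  rssFun <- function(p)
    sum((y - (p[1] + (p[2] - p[1]) / (1 + 10^((x - p[3]) * p[4]))))^2)
  p0 <- unlist(start)[c("bottom", "top", "logIC50", "hill")]
  op <- optim(p0, rssFun, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  op2 <- tryCatch(optim(op$par, rssFun, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14)),
                  error = function(e) op)
  if (op2$value <= op$value) op <- op2
  conv <- op$convergence == 0 && all(is.finite(op$par)) &&
    abs(op$par[4]) > 1e-6
  new("DoseResponseFit", bottom = unname(op$par[1]), top = unname(op$par[2]),
      logIC50 = unname(op$par[3]), hill = unname(op$par[4]),
      rss = op$value, converged = conv, n = length(x),
      message = if (conv) "converged (direct search fallback)"
                else "did not converge")
}

#' Fit a dose-response table (concentrations in uM, solvent rule applied)
#'
#' Convenience wrapper: transforms concentrations with
#' [logTransformConcentrations()] (solvent controls at the log10 of the
#' lowest tested dose) and fits with [fitFourPL()].
#'
#' @param concentration concentrations in uM (0 for solvent controls)
#' @param response responses (percent of control)
#' @param ... passed to [fitFourPL()]
#' @return a [DoseResponseFit-class]
#' @export
fitDoseResponse <- function(concentration, response, ...) {
  fitFourPL(logTransformConcentrations(concentration), response, ...)
}
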