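## Screening statistics: pooled-variance t-tests, Bonferroni-Dunn correction,
## the three comparison families, replicate correlation.

#' Two-sided pooled-variance (Student) unpaired t-test
#'
#' Assumes Gaussian distributions with the same standard deviation in both
#' populations; `df = n_a + n_b - 2`. Degenerate inputs are handled
#' explicitly: zero pooled variance with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means gives `p = 0` flagged degenerate.
#'
#' @param a,b numeric vectors (each n >= 2)
#' @return list(t, df, p, degenerate)
#' @examples
#' pooledTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
pooledTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both groups need n >= 2")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Bonferroni-Dunn multiple-testing correction
#'
#' `p_adj = min(1, m * p)`, the adjustment computed by the multiple-t-test
#' tools that name this procedure Bonferroni-Dunn.
#'
#' @param p raw p-values in `[0, 1]`
#' @param m family size (>= length of `p`; defaults to the number of tests)
#' @return adjusted p-values
#' @examples
#' bonferroniDunn(0.001, m = 84)  # 0.084
#' @export
bonferroniDunn <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= length(p))
  pmin(1, m * p)
}

#' Run one comparison family of the screen
#'
#' Families:
#' * `viability_vs_control` — one test per compound: treated wells' relative
#'   viability vs the solvent-control wells (`data` needs columns `id`
#'   (compound), `role`, `value`).
#' * `th_vs_map2` — one test per compound: per-well relative TH signal vs
#'   relative Map2 signal (`data` needs `id`, `th_rel`, `map2_rel`).
#' * `mode_2d_vs_3d` — one test per concentration: 2D vs 3D relative
#'   viability (`data` needs `id` (concentration), `mode` ("2D"/"3D"),
#'   `value`).
#'
#' The family size `m` for the Bonferroni-Dunn correction is the number of
#' tests actually performed; arms with n < 2 are marked untestable and
#' excluded from `m`. Wells lost to attrition simply reduce n — values are
#' never imputed.
#'
#' @param data a data.frame as described per family
#' @param family one of `"viability_vs_control"`, `"th_vs_map2"`,
#'   `"mode_2d_vs_3d"`
#' @param alpha significance level on adjusted p-values (default 0.05)
#' @return data.frame sorted by id: means and n per arm, t, df, p_raw,
#'   p_adj, significant, untestable
#' @export
screenCompare <- function(data, family = c("viability_vs_control",
                                           "th_vs_map2", "mode_2d_vs_3d"),
                          alpha = 0.05) {
  family <- match.arg(family)
  arms <- switch(family,
    viability_vs_control = {
      ctrl <- data$value[data$role == "solvent_control"]
      ids <- sort(unique(data$id[data$role == "treated"]))
      lapply(ids, function(i)
        list(id = i, a = data$value[data$role == "treated" & data$id == i],
             b = ctrl))
    },
    th_vs_map2 = {
      ids <- sort(unique(data$id))
      lapply(ids, function(i)
        list(id = i, a = data$th_rel[data$id == i],
             b = data$map2_rel[data$id == i]))
    },
    mode_2d_vs_3d = {
      ids <- sort(unique(data$id))
      lapply(ids, function(i)
        list(id = i, a = data$value[data$id == i & data$mode == "2D"],
             b = data$value[data$id == i & data$mode == "3D"]))
    })
  rows <- lapply(arms, function(ar) {
    testable <- length(ar$a) >= 2 && length(ar$b) >= 2
    if (testable) {
      tt <- pooledTTest(ar$a, ar$b)
      data.frame(id = ar$id, mean_a = mean(ar$a), mean_b = mean(ar$b),
                 n_a = length(ar$a), n_b = length(ar$b), t = tt$t,
                 df = tt$df, p_raw = tt$p, untestable = FALSE)
    } else {
      data.frame(id = ar$id,
                 mean_a = if (length(ar$a)) mean(ar$a) else NA_real_,
                 mean_b = if (length(ar$b)) mean(ar$b) else NA_real_,
                 n_a = length(ar$a), n_b = length(ar$b), t = NA_real_,
                 df = NA_real_, p_raw = NA_real_, untestable = TRUE)
    }
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  m <- sum(!res$untestable)
  res$m <- m
  res$p_adj <- NA_real_
  if (m > 0)
    res$p_adj[!res$untestable] <- bonferroniDunn(res$p_raw[!res$untestable],
                                                 m = m)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Squared Pearson correlation between paired replicate summaries
#'
#' @param x,y paired per-compound means from two replicates/plates or cell
#'   lines (n >= 3)
#' @return R^2
#' @export
replicateR2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("R^2 undefined: zero variance in one of the vectors")
  cor(x, y)^2
}
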