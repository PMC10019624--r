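# Growth-assay quantification: OD600 time-series AUC, spot-assay
# pixel-density ratios and pairwise significance with star labels.

#' Construct a growth curve
#'
#' @param times Time points in hours, strictly increasing, >= 2 points.
#' @param od OD600 readings, non-negative, same length as `times`.
#' @param strain,condition Optional labels.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, strain = NA_character_,
                         condition = NA_character_) {
  if (length(times) != length(od) || length(times) < 2L)
    stop("input error: need equal-length time/OD vectors with >= 2 points")
  if (any(diff(times) <= 0))
    stop("input error: times must be strictly increasing")
  if (any(od < 0))
    stop("input error: OD600 readings must be non-negative")
  structure(list(times = as.numeric(times), od = as.numeric(od),
                 strain = strain, condition = condition),
            class = "growth_curve")
}

#' Area under a growth curve
#'
#' Plain trapezoidal integral of OD600 over the observed time span
#' (OD x hours). No growth model is fitted.
#'
#' @param curve A [growth_curve()], or a numeric time vector if `od` is
#'   also given.
#' @param od OD readings when `curve` is a plain time vector.
#' @return The area under the curve.
#' @export
auc <- function(curve, od = NULL) {
  if (!inherits(curve, "growth_curve")) curve <- growth_curve(curve, od)
  t <- curve$times; y <- curve$od
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Relative growth from spot-assay pixel densities
#'
#' Ratio of growth under the ADAR-inducing condition to growth under
#' the repressing condition.
#'
#' @param inducing Pixel density under the inducing condition (>= 0).
#' @param repressing Pixel density under the repressing condition (> 0).
#' @return `inducing / repressing` (vectorized).
#' @export
relative_growth <- function(inducing, repressing) {
  if (any(inducing < 0) || any(repressing < 0))
    stop("input error: pixel densities must be non-negative")
  if (any(repressing == 0))
    stop("undefined ratio: repressing-condition density is zero")
  inducing / repressing
}

#' Pairwise group comparison with significance stars
#'
#' Two-sided Welch t-tests between every pair of groups, labelled with
#' the figure-legend star convention ([star_label()]). If both groups of
#' a pair are degenerate (zero variance), an exact-equality shortcut is
#' used: p = 1 when the means are equal, p = 0 otherwise.
#'
#' @param values Numeric vector of replicate measurements.
#' @param groups Group label per value; every group needs >= 2 values.
#' @return A data frame: `group1`, `group2`, `mean1`, `mean2`, `p`,
#'   `label`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("input error: every group needs at least two values")
  gs <- names(sizes)
  if (length(gs) < 2L) stop("input error: need at least two groups")
  pairs <- utils::combn(gs, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    mean1 = NA_real_, mean2 = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    out$mean1[i] <- mean(a); out$mean2[i] <- mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      out$p[i] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      out$p[i] <- t.test(a, b, var.equal = FALSE)$p.value
    }
  }
  out$label <- star_label(out$p)
  out
}
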