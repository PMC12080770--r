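# Entropy weight method and the composite fatigue index F.
#
# The index is a weighted sum of the min-max normalized reaction time (R) and
# Borg rating (B), F = w_R R + w_B B, with weights derived objectively from
# the dispersion of the two features: per-feature min-max normalization, a
# +0.001 shift to keep logarithms finite, per-sample proportions, information
# entropy e_j, difference coefficients g_j = 1 - e_j, and weights
# w_j = g_j / sum(g). A more dispersed feature has lower entropy and a larger
# weight. Both Borg and reaction time are positive indicators (larger = more
# fatigued), so no direction inversion is applied.

#' Min-max normalize a feature matrix
#'
#' Per-feature `(x - min) / (max - min)`, mapping each column to \[0, 1\].
#' A constant column (max = min) is mapped to all zeros, the only choice
#' under which a non-discriminating feature ends up with entropy 1 and weight
#' 0 downstream.
#'
#' @param x numeric matrix (samples x features) or a raw [FeatureMatrix-class].
#' @return A [FeatureMatrix-class] with stage `"normalized"`.
#' @examples
#' featureValues(minmaxNormalize(cbind(a = c(0, 5, 10))))
#' @export
minmaxNormalize <- function(x) {
  if (is(x, "FeatureMatrix")) {
    if (x@stage != "raw")
      stop(sprintf("minmaxNormalize expects a raw matrix, got stage '%s'", x@stage),
           call. = FALSE)
    x <- x@values
  }
  x <- as.matrix(x)
  if (!length(x) || nrow(x) < 2)
    stop("need a matrix with at least 2 samples", call. = FALSE)
  out <- apply(x, 2, function(col) {
    rng <- range(col)
    if (rng[1] == rng[2]) rep(0, length(col))
    else (col - rng[1]) / (rng[2] - rng[1])
  })
  dimnames(out) <- dimnames(x)
  FeatureMatrix(out, stage = "normalized")
}

#' Shift a normalized matrix by +0.001
#'
#' Adds exactly 0.001 to every entry of a normalized matrix so that all
#' values are strictly positive before the entropy logarithms. Applying it to
#' a raw or already-shifted matrix is rejected by the stage guard.
#'
#' @param x a [FeatureMatrix-class] with stage `"normalized"`.
#' @return A [FeatureMatrix-class] with stage `"shifted"`.
#' @export
shiftFeatures <- function(x) {
  if (!is(x, "FeatureMatrix") || x@stage != "normalized")
    stop("shiftFeatures expects a FeatureMatrix at stage 'normalized'",
         call. = FALSE)
  FeatureMatrix(x@values + 0.001, stage = "shifted")
}

#' Entropy weights of a shifted feature matrix
#'
#' For each feature j over n samples: proportions
#' `p_ij = x_ij / sum_i(x_ij)`, entropy
#' `e_j = -(1/ln n) * sum_i p_ij ln p_ij`, difference coefficient
#' `g_j = 1 - e_j` and weight `w_j = g_j / sum(g)`. Natural logarithms
#' throughout. Errors if every feature is constant (no discriminating
#' feature).
#'
#' @param x a [FeatureMatrix-class] with stage `"shifted"`.
#' @return An [EntropyWeights-class].
#' @examples
#' m <- shiftFeatures(minmaxNormalize(cbind(rt = c(310, 360, 450),
#'                                          borg = c(8, 12, 19))))
#' featureWeights(entropyWeights(m))
#' @export
entropyWeights <- function(x) {
  if (!is(x, "FeatureMatrix") || x@stage != "shifted")
    stop("entropyWeights expects a FeatureMatrix at stage 'shifted'", call. = FALSE)
  v <- x@values
  n <- nrow(v)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  p <- sweep(v, 2, colSums(v), "/")
  e <- -colSums(p * log(p)) / log(n)
  g <- 1 - e
  # guard tiny negative coefficients from floating error on uniform columns
  g[abs(g) < 1e-14] <- 0
  if (all(g == 0))
    stop("no discriminating feature: every feature is constant", call. = FALSE)
  w <- g / sum(g)
  new("EntropyWeights", p = p, e = e, g = g, w = w, n = as.integer(n))
}

#' Entropy weights straight from raw features
#'
#' Convenience composition of [minmaxNormalize()], [shiftFeatures()] and
#' [entropyWeights()].
#'
#' @param x numeric matrix of raw feature values (samples x features).
#' @return An [EntropyWeights-class].
#' @export
computeWeights <- function(x) entropyWeights(shiftFeatures(minmaxNormalize(x)))

#' Published reference weights for the composite index
#'
#' The entropy weights reported for the original study cohort,
#' `F = 0.39 R + 0.61 B` (R = normalized reaction time, B = normalized Borg
#' rating). The underlying raw data are not deposited, so these are recorded
#' reference constants, not recomputable values; [computeWeights()] derives
#' cohort-specific weights from data.
#'
#' @return Named numeric vector `c(reaction_time = 0.39, borg = 0.61)`.
#' @export
referenceWeights <- function() c(reaction_time = 0.39, borg = 0.61)

#' Composite fatigue index F
#'
#' `F = w_R * R + w_B * B` where `R` is the normalized reaction time and `B`
#' the normalized Borg rating, both in \[0, 1\]. Weights are keyed by feature
#' name, never by column position. F is clipped to \[0, 1\] only when
#' floating error exceeds the bounds by less than 1e-9.
#'
#' @param R normalized reaction time value(s) in \[0, 1\].
#' @param B normalized Borg value(s) in \[0, 1\].
#' @param weights an [EntropyWeights-class] over features named
#'   `reaction_time` and `borg`, or a named numeric vector with those two
#'   names summing to 1. Default: the published [referenceWeights()].
#' @return Numeric vector of fatigue index values in \[0, 1\].
#' @examples
#' compositeIndex(0.21, 0.31)  # lower edge of the moderate band
#' @export
compositeIndex <- function(R, B, weights = referenceWeights()) {
  if (is(weights, "EntropyWeights")) weights <- weights@w
  need <- c("reaction_time", "borg")
  if (is.null(names(weights)) || !all(need %in% names(weights)))
    stop("weights must be named 'reaction_time' and 'borg'", call. = FALSE)
  w <- weights[need]
  if (abs(sum(w) - 1) > 1e-8) stop("the two weights must sum to 1", call. = FALSE)
  if (length(R) != length(B)) stop("R and B must have equal length", call. = FALSE)
  tol <- 1e-9
  if (any(R < -tol | R > 1 + tol)) stop("R must lie in [0, 1]", call. = FALSE)
  if (any(B < -tol | B > 1 + tol)) stop("B must lie in [0, 1]", call. = FALSE)
  f <- unname(w[1] * R + w[2] * B)
  if (any(f < -tol | f > 1 + tol))
    stop("composite index escaped [0, 1] beyond floating tolerance", call. = FALSE)
  pmin(1, pmax(0, f))
}

#' Canonical 3-level fatigue bands
#'
#' Breakpoints of the mild / moderate / severe classification of the
#' composite index: mild F in \[0, 0.27), moderate \[0.27, 0.66), severe
#' \[0.66, 1\]. Boundaries belong to the upper level.
#'
#' @return Numeric vector of breakpoints `c(0, 0.27, 0.66, 1)`.
#' @export
referenceFatigueBands <- function() c(0, 0.27, 0.66, 1)

#' Classify a fatigue index into the 3-level grading
#'
#' Half-open bands with boundaries belonging to the upper level; the top band
#' is closed at 1.
#'
#' @param f fatigue index value(s) in \[0, 1\].
#' @param breaks increasing breakpoints (first 0, last 1); default the
#'   canonical [referenceFatigueBands()].
#' @return Integer level(s) with levels' names as a `"labels"` attribute-free
#'   factor-like convention: 1 = mild, 2 = moderate, 3 = severe.
#' @examples
#' classifyLevel(c(0.10, 0.27, 0.80))
#' @export
classifyLevel <- function(f, breaks = referenceFatigueBands()) {
  tol <- 1e-9
  if (any(!is.finite(f)) || any(f < -tol | f > 1 + tol))
    stop("fatigue index must lie in [0, 1]", call. = FALSE)
  f <- pmin(1, pmax(0, f))
  lv <- findInterval(f, breaks, rightmost.closed = TRUE, left.open = FALSE)
  as.integer(lv)
}
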