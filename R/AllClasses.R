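#' @import methods
NULL

#' RR-interval series for one subject-stage
#'
#' Container for an ordered series of RR intervals (milliseconds) recorded
#' during a single exercise stage, together with its subject and stage labels.
#' RR intervals are the times between successive R-peaks of the ECG; all HRV
#' features derive from this series.
#'
#' @slot intervals numeric vector of RR intervals in milliseconds, all > 0.
#' @slot subjectId single character subject label.
#' @slot stage single integer stage index (1-based).
#'
#' @seealso [hrvFeatures()], [simulateRR()], [readRRI()]
#' @export
setClass("RRISeries",
  representation(intervals = "numeric", subjectId = "character", stage = "integer"),
  prototype(intervals = numeric(0), subjectId = NA_character_, stage = NA_integer_)
)

setValidity("RRISeries", function(object) {
  msg <- character(0)
  if (length(object@intervals) && (!all(is.finite(object@intervals)) ||
                                   any(object@intervals <= 0)))
    msg <- c(msg, "all RR intervals must be finite and > 0")
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must have length 1")
  if (length(object@stage) != 1L) msg <- c(msg, "stage must have length 1")
  if (length(msg)) msg else TRUE
})

#' Construct an RRISeries
#'
#' @param intervals numeric vector of RR intervals in milliseconds.
#' @param subjectId subject label (coerced to character).
#' @param stage stage index (coerced to integer).
#' @return An [RRISeries-class] object.
#' @examples
#' rri <- RRISeries(rep(1000, 240), subjectId = "s1", stage = 1)
#' nBeats(rri)
#' @export
RRISeries <- function(intervals, subjectId = NA_character_, stage = NA_integer_) {
  new("RRISeries", intervals = as.numeric(intervals),
      subjectId = as.character(subjectId), stage = as.integer(stage))
}

#' @describeIn RRISeries number of RR intervals in the series.
#' @param x an `RRISeries`.
#' @export
nBeats <- function(x) length(x@intervals)

#' @describeIn RRISeries accessor for the interval vector (ms).
#' @export
rrIntervals <- function(x) x@intervals

#' @describeIn RRISeries accessor for the subject label.
#' @export
subjectId <- function(x) x@subjectId

#' @describeIn RRISeries accessor for the stage index.
#' @export
stageIndex <- function(x) x@stage

setMethod("show", "RRISeries", function(object) {
  n <- length(object@intervals)
  cat(sprintf("RRISeries: subject %s, stage %s, %d beats (%.1f s)\n",
              object@subjectId, object@stage, n, sum(object@intervals) / 1000))
  if (n) cat(sprintf("  mean RR %.1f ms, HR %.1f bpm\n",
                     mean(object@intervals), 60000 / mean(object@intervals)))
})

#' Staged feature matrix for entropy weighting
#'
#' A samples-by-features matrix tagged with its processing stage. The entropy
#' weighting pipeline moves a matrix through three stages: `"raw"` (original
#' units), `"normalized"` (per-feature min-max to \[0, 1\]) and `"shifted"`
#' (normalized + 0.001, so every entry is strictly positive before taking
#' logarithms). Stage tags guard against applying a step out of order.
#'
#' @slot values numeric matrix, n samples x m features (column names kept).
#' @slot stage one of `"raw"`, `"normalized"`, `"shifted"`.
#'
#' @seealso [minmaxNormalize()], [shiftFeatures()], [entropyWeights()]
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", stage = "character"),
  prototype(stage = "raw")
)

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (!(object@stage %in% c("raw", "normalized", "shifted")))
    msg <- c(msg, "stage must be 'raw', 'normalized' or 'shifted'")
  tol <- 1e-9
  if (is.numeric(v) && length(v)) {
    if (object@stage == "normalized" && (min(v) < -tol || max(v) > 1 + tol))
      msg <- c(msg, "normalized values must lie in [0, 1]")
    if (object@stage == "shifted" && (min(v) < 0.001 - tol || max(v) > 1.001 + tol))
      msg <- c(msg, "shifted values must lie in [0.001, 1.001]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (samples in rows, features in columns).
#' @param stage processing-stage tag, default `"raw"`.
#' @return A [FeatureMatrix-class].
#' @export
FeatureMatrix <- function(values, stage = "raw") {
  new("FeatureMatrix", values = as.matrix(values), stage = stage)
}

#' @describeIn FeatureMatrix accessor for the numeric matrix.
#' @param x a `FeatureMatrix`.
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix accessor for the processing-stage tag.
#' @export
processingStage <- function(x) x@stage

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s): %d samples x %d features\n",
              object@stage, nrow(object@values), ncol(object@values)))
})

#' Entropy-method feature weights
#'
#' Result of the entropy weight method: per-sample proportions, per-feature
#' information entropy, difference coefficients and the final weights. A
#' feature whose normalized values are more dispersed has lower entropy, a
#' larger difference coefficient, and hence a larger weight.
#'
#' @slot p proportion matrix p_ij (each column sums to 1).
#' @slot e per-feature entropy, in \[0, 1\].
#' @slot g per-feature difference coefficient, g = 1 - e.
#' @slot w per-feature weight, w >= 0 and sum(w) = 1.
#' @slot n number of samples the weights were computed from.
#'
#' @seealso [entropyWeights()]
#' @export
setClass("EntropyWeights",
  representation(p = "matrix", e = "numeric", g = "numeric", w = "numeric",
                 n = "integer")
)

setValidity("EntropyWeights", function(object) {
  msg <- character(0)
  tol <- 1e-8
  if (any(object@w < -tol)) msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@w) - 1) > tol) msg <- c(msg, "weights must sum to 1")
  if (any(abs(object@g - (1 - object@e)) > tol))
    msg <- c(msg, "difference coefficients must equal 1 - entropy")
  if (length(msg)) msg else TRUE
})

#' @describeIn EntropyWeights accessor for the weight vector.
#' @param x an `EntropyWeights` object.
#' @export
featureWeights <- function(x) x@w

#' @describeIn EntropyWeights accessor for the per-feature entropies.
#' @export
featureEntropy <- function(x) x@e

setMethod("show", "EntropyWeights", function(object) {
  cat(sprintf("EntropyWeights over %d samples\n", object@n))
  print(round(rbind(entropy = object@e, difference = object@g, weight = object@w), 4))
})

#' K-means clustering result
#'
#' Output of the seeded multi-restart Lloyd algorithm: the best-of-replicates
#' model by within-cluster sum of squares, its labels and centroids, and the
#' per-iteration within-SS trace of the winning replicate (non-increasing by
#' construction of Lloyd's algorithm).
#'
#' @slot k number of clusters.
#' @slot centroids k x d matrix of cluster centres.
#' @slot labels integer cluster index per sample (1..k).
#' @slot withinSS total within-cluster sum of squared distances.
#' @slot ssHistory within-SS after each Lloyd iteration of the best replicate.
#' @slot iterations iterations run by the best replicate.
#' @slot replicates number of seeded restarts examined.
#' @slot seed base seed used for the restarts.
#'
#' @seealso [kmeansFit()], [selectK()]
#' @export
setClass("ClusterModel",
  representation(k = "integer", centroids = "matrix", labels = "integer",
                 withinSS = "numeric", ssHistory = "numeric",
                 iterations = "integer", replicates = "integer", seed = "integer")
)

setValidity("ClusterModel", function(object) {
  msg <- character(0)
  if (nrow(object@centroids) != object@k) msg <- c(msg, "need one centroid per cluster")
  if (length(object@labels) && (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (is.unsorted(-object@ssHistory)) msg <- c(msg, "within-SS trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClusterModel accessor for the labels.
#' @param x a `ClusterModel`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterModel accessor for the centroid matrix.
#' @export
clusterCentroids <- function(x) x@centroids

#' @describeIn ClusterModel accessor for the within-cluster sum of squares.
#' @export
withinSS <- function(x) x@withinSS

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, %d samples, within-SS %.4g (best of %d replicates)\n",
              object@k, length(object@labels), object@withinSS, object@replicates))
})

#' Fatigue grade thresholds
#'
#' Per-level intervals for the clustering features (reaction time y1 and Borg
#' rating y2, both min-max normalized), optionally combined into composite
#' fatigue index (F) intervals by entropy weights, and optionally consolidated
#' into a coarser set of levels with a recorded consolidation map.
#'
#' @slot intervals named list of L x 2 matrices (`lo`, `hi` columns), one per
#'   feature, levels ordered by ascending weighted centroid.
#' @slot fIntervals L x 2 matrix of composite-index intervals, or a 0-row
#'   matrix before weighting.
#' @slot map integer vector mapping each original level to its consolidated
#'   level (identity before consolidation).
#'
#' @seealso [clusterThresholds()], [weightedThresholds()], [consolidateLevels()]
#' @export
setClass("GradeThresholds",
  representation(intervals = "list", fIntervals = "matrix", map = "integer"),
  prototype(fIntervals = matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("lo", "hi"))))
)

setValidity("GradeThresholds", function(object) {
  msg <- character(0)
  for (nm in names(object@intervals)) {
    iv <- object@intervals[[nm]]
    if (!is.matrix(iv) || ncol(iv) != 2) {
      msg <- c(msg, sprintf("intervals[['%s']] must be an L x 2 matrix", nm))
    } else if (any(iv[, 1] > iv[, 2] + 1e-12)) {
      msg <- c(msg, sprintf("intervals[['%s']] must have lo <= hi", nm))
    }
  }
  if (nrow(object@fIntervals) && any(object@fIntervals[, 1] > object@fIntervals[, 2] + 1e-12))
    msg <- c(msg, "F intervals must have lo <= hi")
  if (length(msg)) msg else TRUE
})

#' @describeIn GradeThresholds accessor for the per-feature interval list.
#' @param x a `GradeThresholds`.
#' @export
levelIntervals <- function(x) x@intervals

#' @describeIn GradeThresholds accessor for the composite-index intervals.
#' @export
fatigueBands <- function(x) x@fIntervals

#' @describeIn GradeThresholds accessor for the consolidation map.
#' @export
consolidationMap <- function(x) x@map

setMethod("show", "GradeThresholds", function(object) {
  L <- if (length(object@intervals)) nrow(object@intervals[[1]]) else nrow(object@fIntervals)
  cat(sprintf("GradeThresholds: %d levels (features: %s)\n",
              L, paste(names(object@intervals), collapse = ", ")))
  if (nrow(object@fIntervals)) {
    cat("  F bands:\n")
    for (i in seq_len(nrow(object@fIntervals)))
      cat(sprintf("    level %d: (%.2f, %.2f)\n", i,
                  object@fIntervals[i, 1], object@fIntervals[i, 2]))
  }
})

#' Synthetic graded-treadmill cohort
#'
#' Holds everything one simulated cohort produces: an RR-interval series per
#' subject-stage, the observation table (Borg rating, reaction time, speed and
#' the latent true fatigue per subject-stage), the subject profiles drawn, and
#' the protocol configuration used.
#'
#' @slot series list of [RRISeries-class], one per subject-stage, in
#'   subject-major order.
#' @slot observations data.frame with columns `subject`, `stage`, `speed_kmh`,
#'   `borg`, `rt_ms`, `true_fatigue`.
#' @slot profiles data.frame of per-subject generator parameters.
#' @slot config the protocol configuration list used.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("FatigueCohort",
  representation(series = "list", observations = "data.frame",
                 profiles = "data.frame", config = "list")
)

setValidity("FatigueCohort", function(object) {
  if (length(object@series) != nrow(object@observations))
    return("need exactly one RR series per observation row")
  TRUE
})

#' @describeIn FatigueCohort accessor for the observation table.
#' @param x a `FatigueCohort`.
#' @export
observations <- function(x) x@observations

#' @describeIn FatigueCohort accessor for the list of RR series.
#' @export
rrSeries <- function(x) x@series

setMethod("show", "FatigueCohort", function(object) {
  cat(sprintf("FatigueCohort: %d subjects x %d stages = %d observations\n",
              object@config$nSubjects, object@config$nStages,
              nrow(object@observations)))
})

#' Trained 10-8-1 fatigue prediction network
#'
#' A single-hidden-layer feedforward network (tanh hidden units, linear
#' output) trained by full-batch gradient descent to map the ten HR/HRV
#' features to the composite fatigue index, together with the \[-1, 1\]
#' min-max scaling fitted on the training split and the per-epoch training
#' MSE history.
#'
#' @slot W1 hidden x inputs weight matrix.
#' @slot b1 hidden biases.
#' @slot W2 1 x hidden output weights.
#' @slot b2 output bias (length 1).
#' @slot xScale list with `lo`/`hi` per input feature (training split).
#' @slot yScale list with `lo`/`hi` of the training target.
#' @slot config the training configuration used.
#' @slot history per-epoch training MSE on the scaled target
#'   (non-increasing; index 1 is the pre-training loss).
#' @slot seed initialization seed.
#'
#' @seealso [trainFatigueMLP()], [predict,FatigueMLP-method]
#' @export
setClass("FatigueMLP",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 xScale = "list", yScale = "list", config = "list",
                 history = "numeric", seed = "integer")
)

setValidity("FatigueMLP", function(object) {
  msg <- character(0)
  if (nrow(object@W1) != length(object@b1))
    msg <- c(msg, "W1 rows must match b1 length")
  if (ncol(object@W2) != nrow(object@W1))
    msg <- c(msg, "W2 columns must match hidden layer size")
  if (length(object@b2) != 1L) msg <- c(msg, "b2 must be scalar")
  if (length(object@history) > 1 && any(diff(object@history) > 1e-12))
    msg <- c(msg, "training history must be non-increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FatigueMLP", function(object) {
  cat(sprintf("FatigueMLP: %d-%d-1 network, %d epochs, final training MSE %.3g\n",
              ncol(object@W1), nrow(object@W1), length(object@history) - 1L,
              object@history[length(object@history)]))
})
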