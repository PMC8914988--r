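#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' SleeveFrames: a stack of raw 20x10 pressure images
#'
#' Container for raw pressure frames from a textile sensor sleeve. Each frame
#' is a \code{gridRows x gridCols} matrix of non-negative 12-bit sensor
#' readings (0--4095), one frame per (subject, round, activity) instance.
#' Frames are held as a 3-dimensional array \code{[row, col, frame]} together
#' with per-frame metadata (\code{subject_id}, \code{round_id},
#' \code{activity}).
#'
#' @slot values numeric array, \code{dim = c(rows, cols, n)}; all entries >= 0.
#' @slot frameData \code{DataFrame} with one row per frame; must contain
#'   columns \code{subject_id}, \code{round_id} and \code{activity}.
#'
#' @seealso [SleeveFrames()] constructor, [frameArray()], [frameData()],
#'   [preprocessDataset()]
#' @export
setClass("SleeveFrames",
  representation(values = "array", frameData = "DataFrame"))

setValidity("SleeveFrames", function(object) {
  v <- object@values
  fd <- object@frameData
  msg <- character()
  if (length(dim(v)) != 3L)
    msg <- c(msg, "'values' must be a 3-d array [row, col, frame]")
  else {
    if (dim(v)[3] != nrow(fd))
      msg <- c(msg, "number of frames must match nrow(frameData)")
    if (length(v) && min(v) < 0)
      msg <- c(msg, "pressure values must be non-negative")
  }
  need <- c("subject_id", "round_id", "activity")
  miss <- setdiff(need, colnames(fd))
  if (length(miss))
    msg <- c(msg, paste0("frameData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SleeveFrames object
#'
#' @param values numeric array \code{[row, col, frame]} of non-negative
#'   pressure readings.
#' @param frameData a \code{DataFrame} or \code{data.frame} with columns
#'   \code{subject_id}, \code{round_id}, \code{activity} (one row per frame).
#' @return A [SleeveFrames-class] object.
#' @examples
#' v <- array(0, c(20, 10, 2))
#' fd <- data.frame(subject_id = "S1", round_id = 1L,
#'                  activity = c("a1", "a2"))
#' SleeveFrames(v, fd)
#' @export
SleeveFrames <- function(values, frameData) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (is.data.frame(frameData)) frameData <- DataFrame(frameData)
  new("SleeveFrames", values = values, frameData = frameData)
}

#' SleeveSamples: preprocessed sample pairs
#'
#' Each activity instance carries two processed images: the smoothed image
#' (raw frame upsampled 3x by bilinear interpolation then smoothed with a 5x5
#' Gaussian, 60x30) and the normalized image (the smoothed image rescaled by
#' per-subject anthropometric ratios, embedded on an 84x42 zero canvas and
#' shifted by its round's exposure-image offset). Both are retained: size and
#' position normalization can discard information, so the feature extractor
#' sees the pair.
#'
#' @slot smoothed numeric array \code{[60, 30, n]}.
#' @slot normalized numeric array \code{[84, 42, n]}.
#' @slot sampleData \code{DataFrame} with \code{subject_id}, \code{round_id},
#'   \code{activity} per sample.
#' @slot roundOffsets data.frame of per-round (row, col) shifts applied during
#'   alignment; offsets average to zero across rounds.
#'
#' @seealso [preprocessDataset()], [extractFeatures()]
#' @export
setClass("SleeveSamples",
  representation(smoothed = "array", normalized = "array",
                 sampleData = "DataFrame", roundOffsets = "data.frame"))

setValidity("SleeveSamples", function(object) {
  msg <- character()
  n <- nrow(object@sampleData)
  if (length(dim(object@smoothed)) != 3L || length(dim(object@normalized)) != 3L)
    return("image slots must be 3-d arrays")
  if (dim(object@smoothed)[3] != n || dim(object@normalized)[3] != n)
    msg <- c(msg, "image stacks and sampleData disagree on sample count")
  if (length(object@smoothed) && min(object@smoothed) < 0)
    msg <- c(msg, "smoothed images must be non-negative")
  if (length(object@normalized) && min(object@normalized) < -1e-9)
    msg <- c(msg, "normalized images must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SleeveEval: result of one cross-validated evaluation
#'
#' Holds the scheme ("kfold" or "loso"), the classifier id, macro-averaged
#' metrics, the per-fold breakdown and the pooled confusion matrix. Accuracy,
#' macro precision and macro recall are averaged over folds; macro F1 is the
#' harmonic combination 2PR/(P+R) of the averaged precision and recall, so the
#' F1 identity holds exactly on the emitted object.
#'
#' @slot scheme character, "kfold" or "loso".
#' @slot classifier character id.
#' @slot accuracy,macroP,macroR,macroF1 numeric in [0, 1].
#' @slot perFold data.frame with one row per fold.
#' @slot confusion integer matrix, rows = true class, cols = predicted.
#' @export
setClass("SleeveEval",
  representation(scheme = "character", classifier = "character",
                 accuracy = "numeric", macroP = "numeric", macroR = "numeric",
                 macroF1 = "numeric", perFold = "data.frame",
                 confusion = "matrix"))

setValidity("SleeveEval", function(object) {
  m <- c(object@accuracy, object@macroP, object@macroR, object@macroF1)
  if (any(m < -1e-12 | m > 1 + 1e-12))
    return("metrics must lie in [0, 1]")
  if (any(object@confusion < 0))
    return("confusion counts must be non-negative")
  TRUE
})

#' @describeIn SleeveFrames-class number of frames
#' @param x,object a \code{SleeveFrames} object
#' @export
setMethod("length", "SleeveFrames", function(x) dim(x@values)[3])

#' Accessors for sleeve containers
#'
#' \code{frameArray} returns the raw \code{[row, col, frame]} array;
#' \code{frameData}/\code{sampleData} return per-instance metadata;
#' \code{smoothedImages} and \code{normalizedImages} return the processed
#' stacks; \code{roundOffsets} the per-round alignment shifts.
#'
#' @param x a [SleeveFrames-class] or [SleeveSamples-class] object.
#' @return An array, \code{DataFrame} or data.frame as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameArray", function(x) standardGeneric("frameArray"))
#' @rdname accessors
#' @export
setMethod("frameArray", "SleeveFrames", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))
#' @rdname accessors
#' @export
setMethod("frameData", "SleeveFrames", function(x) x@frameData)

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setMethod("sampleData", "SleeveSamples", function(x) x@sampleData)

#' @rdname accessors
#' @export
setGeneric("smoothedImages", function(x) standardGeneric("smoothedImages"))
#' @rdname accessors
#' @export
setMethod("smoothedImages", "SleeveSamples", function(x) x@smoothed)

#' @rdname accessors
#' @export
setGeneric("normalizedImages", function(x) standardGeneric("normalizedImages"))
#' @rdname accessors
#' @export
setMethod("normalizedImages", "SleeveSamples", function(x) x@normalized)

#' @rdname accessors
#' @export
setGeneric("roundOffsets", function(x) standardGeneric("roundOffsets"))
#' @rdname accessors
#' @export
setMethod("roundOffsets", "SleeveSamples", function(x) x@roundOffsets)

#' @describeIn SleeveSamples-class number of samples
#' @param x a \code{SleeveSamples} object
#' @export
setMethod("length", "SleeveSamples", function(x) nrow(x@sampleData))

#' Subset frames
#' @param x a [SleeveFrames-class] object
#' @param i frame indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "SleeveFrames", function(x, i, j, ..., drop = FALSE) {
  new("SleeveFrames", values = x@values[, , i, drop = FALSE],
      frameData = x@frameData[i, , drop = FALSE])
})

setMethod("show", "SleeveFrames", function(object) {
  d <- dim(object@values)
  fd <- object@frameData
  cat(sprintf("SleeveFrames: %d frame(s) of %dx%d\n", d[3], d[1], d[2]))
  cat(sprintf("  subjects: %d  rounds: %d  activities: %d\n",
              length(unique(fd$subject_id)), length(unique(fd$round_id)),
              length(unique(fd$activity))))
})

setMethod("show", "SleeveSamples", function(object) {
  ds <- dim(object@smoothed); dn <- dim(object@normalized)
  cat(sprintf("SleeveSamples: %d sample(s)\n", nrow(object@sampleData)))
  cat(sprintf("  smoothed: %dx%d  normalized: %dx%d\n",
              ds[1], ds[2], dn[1], dn[2]))
})

setMethod("show", "SleeveEval", function(object) {
  cat(sprintf("SleeveEval [%s, %s]\n", object@scheme, object@classifier))
  cat(sprintf("  accuracy %.4f  macroP %.4f  macroR %.4f  macroF1 %.4f\n",
              object@accuracy, object@macroP, object@macroR, object@macroF1))
  cat(sprintf("  %d fold(s), %d test sample(s)\n",
              nrow(object@perFold), sum(object@confusion)))
})

#' Metric accessors for evaluation results
#'
#' @param x a [SleeveEval-class] object.
#' @return \code{evalMetrics} returns a named numeric vector (accuracy,
#'   macroP, macroR, macroF1); \code{confusionMatrix} the pooled confusion
#'   matrix; \code{perFoldMetrics} the per-fold breakdown.
#' @name eval-accessors
NULL

#' @rdname eval-accessors
#' @export
setGeneric("evalMetrics", function(x) standardGeneric("evalMetrics"))
#' @rdname eval-accessors
#' @export
setMethod("evalMetrics", "SleeveEval", function(x)
  c(accuracy = x@accuracy, macroP = x@macroP, macroR = x@macroR,
    macroF1 = x@macroF1))

#' @rdname eval-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname eval-accessors
#' @export
setMethod("confusionMatrix", "SleeveEval", function(x) x@confusion)

#' @rdname eval-accessors
#' @export
setGeneric("perFoldMetrics", function(x) standardGeneric("perFoldMetrics"))
#' @rdname eval-accessors
#' @export
setMethod("perFoldMetrics", "SleeveEval", function(x) x@perFold)
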