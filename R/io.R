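#' @importFrom utils read.csv write.csv
NULL

## stable pressure-column names, row-major: p_0_0 .. p_19_9
pressureColumns <- function(rows = 20L, cols = 10L) {
  as.vector(t(outer(0:(rows - 1), 0:(cols - 1),
                    function(r, c) sprintf("p_%d_%d", r, c))))
}

#' Write raw frames to CSV
#'
#' One row per frame: \code{subject_id}, \code{round_id}, \code{activity}
#' followed by the 200 pressure columns \code{p_r_c} in row-major order
#' (r = 0..19 along the arm, c = 0..9 around it). This is the package's
#' documented frame dialect; [readFrames()] reads it back losslessly.
#'
#' @param frames a [SleeveFrames-class] object.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFrames <- function(frames, path) {
  stopifnot(is(frames, "SleeveFrames"))
  v <- frameArray(frames)
  d <- dim(v)
  flat <- t(apply(v, 3, function(m) as.vector(t(m))))  # row-major per frame
  if (d[3] == 1L) flat <- matrix(flat, nrow = 1L)
  colnames(flat) <- pressureColumns(d[1], d[2])
  df <- cbind(as.data.frame(frameData(frames)), as.data.frame(flat))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read raw frames from CSV
#'
#' Expects the dialect written by [writeFrames()]. Structural problems are
#' reported precisely: missing pressure columns are named; non-numeric or
#' negative readings are reported with their row numbers.
#'
#' @param path CSV path.
#' @param rows,cols expected grid size, default 20 x 10.
#' @return A [SleeveFrames-class] object (zero frames, with a warning, for a
#'   header-only file).
#' @export
readFrames <- function(path, rows = 20L, cols = 10L) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "round_id", "activity")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing label column(s): ", paste(miss, collapse = ", "))
  pcols <- pressureColumns(rows, cols)
  missp <- setdiff(pcols, colnames(df))
  if (length(missp))
    stop(sprintf("missing %d pressure column(s), e.g. %s", length(missp),
                 paste(utils::head(missp, 3), collapse = ", ")))
  n <- nrow(df)
  if (n == 0L) {
    warning("no frames in ", path)
    return(SleeveFrames(array(0, c(rows, cols, 0)),
                        S4Vectors::DataFrame(subject_id = character(0),
                                             round_id = integer(0),
                                             activity = character(0))))
  }
  pm <- as.matrix(df[, pcols])
  if (!is.numeric(pm)) {
    bad <- which(apply(df[, pcols], 1, function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric pressure value(s) in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyNA(pm))
    stop("missing pressure value(s) in row(s): ",
         paste(utils::head(which(rowSums(is.na(pm)) > 0), 5), collapse = ", "))
  if (min(pm) < 0)
    stop("negative pressure value(s) in row(s): ",
         paste(utils::head(which(apply(pm, 1, min) < 0), 5), collapse = ", "))
  values <- array(0, c(rows, cols, n))
  for (i in seq_len(n))
    values[, , i] <- matrix(pm[i, ], rows, cols, byrow = TRUE)
  SleeveFrames(values, df[, need])
}

#' Write / read an anthropometrics table
#' @param anthropometrics data.frame with \code{subject_id},
#'   \code{forearm_cm}, \code{biceps_cm}.
#' @param path CSV path.
#' @return \code{path} invisibly; \code{readAnthropometrics} returns the
#'   validated data.frame.
#' @export
writeAnthropometrics <- function(anthropometrics, path) {
  write.csv(anthropometrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnthropometrics
#' @export
readAnthropometrics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "forearm_cm", "biceps_cm")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$forearm_cm <= 0) || any(df$biceps_cm <= 0))
    stop("anthropometric lengths must be strictly positive")
  df
}

#' Write extracted features to CSV
#'
#' One row per sample: the label columns then the 200 named feature columns
#' in stable order. Values round-trip at full double precision.
#'
#' @param se \code{SummarizedExperiment} from [extractFeatures()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(se, path) {
  mat <- t(assay(se))
  df <- cbind(as.data.frame(colData(se)), as.data.frame(mat))
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a feature table written by [writeFeatures()]
#' @param path CSV path.
#' @return A \code{SummarizedExperiment} with assay \code{features}.
#' @export
readFeatures <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  featCols <- grep("\\.Feat[0-9]+$", colnames(df), value = TRUE)
  if (length(featCols) == 0) stop("no feature columns found in ", path)
  mat <- t(as.matrix(df[, featCols]))
  SummarizedExperiment(assays = list(features = mat),
    colData = S4Vectors::DataFrame(df[, setdiff(colnames(df), featCols),
                                      drop = FALSE]))
}

#' Write an evaluation result as JSON
#'
#' Serializes scheme, classifier, the four macro metrics, the per-fold
#' breakdown and the pooled confusion matrix.
#'
#' @param result a [SleeveEval-class] object.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(result, path) {
  stopifnot(is(result, "SleeveEval"))
  obj <- list(scheme = result@scheme, classifier = result@classifier,
              metrics = as.list(evalMetrics(result)),
              perFold = perFoldMetrics(result),
              confusion = list(labels = rownames(confusionMatrix(result)),
                               counts = unname(confusionMatrix(result))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
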