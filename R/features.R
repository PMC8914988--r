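#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## pixels counted as "active" (area semantics) are >= this many sensor units
ACTIVITY_THRESHOLD <- 2

## coordinate grids, 0-based: x = column, y = row (origin at the upper-left
## pixel centre, short side = x axis)
coordGrids <- function(image) {
  h <- nrow(image); w <- ncol(image)
  list(x = matrix(0:(w - 1), h, w, byrow = TRUE),
       y = matrix(0:(h - 1), h, w))
}

## unweighted centroid of the active region and pressure-weighted centre of
## mass, both as c(x, y); empty support falls back to the image centre
centroidAndCom <- function(image, thr = ACTIVITY_THRESHOLD) {
  g <- coordGrids(image)
  center <- c((ncol(image) - 1) / 2, (nrow(image) - 1) / 2)
  act <- image >= thr
  centroid <- if (any(act)) c(mean(g$x[act]), mean(g$y[act])) else center
  tot <- sum(image)
  com <- if (tot > 0) c(sum(g$x * image), sum(g$y * image)) / tot else center
  list(centroid = centroid, com = com)
}

#' Statistical features (Feat1-Feat8)
#'
#' Over all pixel values of one image: maximum, median, sum, range
#' (maximum - median), mean, population variance, mean absolute deviation
#' about the mean, and Shannon entropy (natural log) of the pressure-mass
#' distribution p_i = v_i / sum(v). An all-zero image yields eight zeros.
#'
#' @param image numeric matrix.
#' @return named numeric vector \code{Feat1..Feat8}.
#' @examples
#' statisticalFeatures(matrix(c(1, 2, 3, 6), 2, 2))
#' @export
statisticalFeatures <- function(image) {
  v <- as.numeric(image)
  stopifnot(length(v) > 0)
  med <- median(v)
  tot <- sum(v)
  ent <- 0
  if (tot > 0) {
    p <- v[v > 0] / tot
    ent <- -sum(p * log(p))
  }
  out <- c(max(v), med, tot, max(v) - med, mean(v),
           mean((v - mean(v))^2), mean(abs(v - mean(v))), ent)
  names(out) <- paste0("Feat", 1:8)
  out
}

#' Minimal pixel coverage holding a pressure fraction
#'
#' Sorts pixels in descending order and returns the smallest number of
#' pixels whose cumulative sum reaches \code{q} of the total pressure,
#' divided by the total pixel count. 0 for a pressureless image.
#'
#' @param image numeric matrix.
#' @param q fraction in (0, 1).
#' @return coverage fraction in [0, 1].
#' @export
coverageQuantile <- function(image, q) {
  if (!is.numeric(q) || q <= 0 || q >= 1)
    stop("'q' must lie strictly between 0 and 1")
  tot <- sum(image)
  if (tot <= 0) return(0)
  cum <- cumsum(sort(as.numeric(image), decreasing = TRUE))
  k <- which(cum >= q * tot - 1e-12)[1]
  k / length(image)
}

#' Coverage over the four fixed regions (Feat33-Feat36)
#'
#' The image is split at the upper third of the long side
#' (rows < floor(H/3)) and the midpoint of the short side
#' (cols < floor(W/2)), giving four rectangular blocks
#' (top-left, top-right, bottom-left, bottom-right). Each value is the
#' fraction of that block's pixels with strictly positive pressure.
#'
#' @param image numeric matrix.
#' @return numeric vector of length 4.
#' @export
regionCoverage <- function(image) {
  h <- nrow(image); w <- ncol(image)
  rs <- floor(h / 3); cs <- floor(w / 2)
  cov <- function(rows, cols) {
    if (length(rows) == 0 || length(cols) == 0) return(0)
    mean(image[rows, cols, drop = FALSE] > 0)
  }
  c(cov(seq_len(rs), seq_len(cs)),
    cov(seq_len(rs), setdiff(seq_len(w), seq_len(cs))),
    cov(setdiff(seq_len(h), seq_len(rs)), seq_len(cs)),
    cov(setdiff(seq_len(h), seq_len(rs)), setdiff(seq_len(w), seq_len(cs))))
}

## the 12-value geometric block reused for the full and masked image:
## centroid x/y, com x/y, distances to the origin, angles to the +x axis,
## and the bounding rectangle (width, height, aspect, w*h) of active pixels
geomBlock <- function(image, thr = ACTIVITY_THRESHOLD) {
  cc <- centroidAndCom(image, thr)
  act <- image >= thr
  if (any(act)) {
    g <- coordGrids(image)
    wdt <- max(g$x[act]) - min(g$x[act]) + 1
    hgt <- max(g$y[act]) - min(g$y[act]) + 1
    bbox <- c(wdt, hgt, wdt / hgt, wdt * hgt)
  } else bbox <- c(0, 0, 0, 0)
  c(cc$centroid, cc$com,
    sqrt(sum(cc$centroid^2)), sqrt(sum(cc$com^2)),
    atan2(cc$centroid[2], cc$centroid[1]), atan2(cc$com[2], cc$com[1]),
    bbox)
}

## ratio of two side statistics, kept finite: 0/0 -> 1, a/0 -> 1e6 cap
guardRatio <- function(a, b) {
  if (b == 0) {
    if (a == 0) return(1)
    return(1e6)
  }
  min(a / b, 1e6)
}

## six symmetry values for one split: per-side active area, per-side
## pressure, area ratio, pressure ratio. A pixel with coordinate < split
## belongs to the first side (strict), making the split an exact partition.
splitStats <- function(image, coord, split, thr = ACTIVITY_THRESHOLD) {
  first <- coord < split
  act <- image >= thr
  areaA <- sum(act & first); areaB <- sum(act & !first)
  pressA <- sum(image[first]); pressB <- sum(image[!first])
  c(areaA, areaB, pressA, pressB,
    guardRatio(areaA, areaB), guardRatio(pressA, pressB))
}

## the 24-value symmetry block for one image: splits at the com x, com y,
## centroid x and centroid y coordinates
symBlock <- function(image, thr = ACTIVITY_THRESHOLD) {
  cc <- centroidAndCom(image, thr)
  g <- coordGrids(image)
  c(splitStats(image, g$x, cc$com[1], thr),
    splitStats(image, g$y, cc$com[2], thr),
    splitStats(image, g$x, cc$centroid[1], thr),
    splitStats(image, g$y, cc$centroid[2], thr))
}

#' Geometric features (Feat9-Feat52)
#'
#' Feat9-10 centroid x/y (unweighted mean coordinate of pixels at or above
#' the activity threshold of 2 sensor units); Feat11-12 centre of mass
#' (pressure-weighted); Feat13-14 their Euclidean distances to the origin
#' (upper-left pixel centre); Feat15-16 their angles to the positive x axis
#' (radians); Feat17-20 bounding rectangle width, height, aspect ratio and
#' w*h of the active pixels; Feat21 active-pixel count (area); Feat22-28
#' Hu's seven invariant moments; Feat29 coverage (fraction of strictly
#' positive pixels); Feat30-32 minimal coverage holding 25/50/75\% of total
#' pressure; Feat33-36 region coverage; Feat37 number of contours
#' (8-connected regions above the mean-value threshold); Feat38-40 maximum
#' contour area / pressure / intensity; Feat41-52 = Feat9-20 recomputed on
#' the image masked to its maximum-pressure contour.
#'
#' @param image numeric matrix of non-negative pressures.
#' @return named numeric vector \code{Feat9..Feat52}, all finite.
#' @export
geometricFeatures <- function(image) {
  cs <- contourStats(image)
  msk <- maskedImage(image, cs)
  contourMax <- if (cs$n > 0)
    c(max(cs$stats$area), max(cs$stats$pressure), max(cs$stats$intensity))
  else c(0, 0, 0)
  out <- c(geomBlock(image),
           sum(image >= ACTIVITY_THRESHOLD),
           huMoments(image),
           mean(image > 0),
           coverageQuantile(image, 0.25), coverageQuantile(image, 0.5),
           coverageQuantile(image, 0.75),
           regionCoverage(image),
           cs$n, contourMax,
           geomBlock(msk))
  names(out) <- paste0("Feat", 9:52)
  out
}

#' Symmetry features (Feat53-Feat100)
#'
#' The image is split by the x coordinate of the centre of mass into left
#' and right parts (a pixel belongs left iff its x < com x, so the split is
#' an exact partition): Feat53-54 per-side active area, Feat55-56 per-side
#' pressure, Feat57 area ratio (left/right), Feat58 pressure ratio. The same
#' six values are computed for the com y split (upper/lower, Feat59-64) and
#' for the centroid x and y splits (Feat65-76). Feat77-100 repeat all 24
#' values on the image masked to its maximum-pressure contour. Ratios are
#' guarded (0/0 = 1; finite cap of 1e6) so every value is finite.
#'
#' @param image numeric matrix of non-negative pressures.
#' @return named numeric vector \code{Feat53..Feat100}.
#' @export
symmetryFeatures <- function(image) {
  out <- c(symBlock(image), symBlock(maskedImage(image)))
  names(out) <- paste0("Feat", 53:100)
  out
}

#' All 100 static features of one pressure image
#'
#' Concatenation of [statisticalFeatures()], [geometricFeatures()] and
#' [symmetryFeatures()]. Always exactly 100 finite values, for any
#' non-negative input including all-zero images.
#'
#' @param image numeric matrix of non-negative pressures.
#' @return named numeric vector \code{Feat1..Feat100}.
#' @export
imageFeatures <- function(image) {
  out <- c(statisticalFeatures(image), geometricFeatures(image),
           symmetryFeatures(image))
  stopifnot(length(out) == 100L, all(is.finite(out)))
  out
}

#' Stable names of the 100-image / 200-sample feature set
#'
#' @param images which image copies to name; default both.
#' @return character vector of feature names, \code{"smoothed.Feat1"} ...
#'   \code{"normalized.Feat100"}.
#' @export
featureSetNames <- function(images = c("smoothed", "normalized")) {
  as.vector(vapply(images, function(p) paste0(p, ".Feat", 1:100),
                   character(100)))
}

#' A 38-feature baseline subset
#'
#' A compact spatial descriptor set used as the reference arm of the
#' feature-set ablation: the eight statistical features, centroid/centre of
#' mass coordinates and distances (Feat9-14), bounding rectangle (Feat17-20),
#' active area (Feat21), Hu moments (Feat22-28), coverages (Feat29-32),
#' region coverages (Feat33-36) and contour statistics (Feat37-40). This is
#' a synthetic stand-in assembled from this package's own features in the
#' spirit of earlier 38-feature spatial sets; it is not a reproduction of
#' any published list.
#'
#' @return character vector of 38 \code{FeatN} names.
#' @export
baselineFeatureNames <- function() {
  paste0("Feat", c(1:14, 17:40))
}

#' Extract the 200-feature vectors of preprocessed samples
#'
#' Computes the 100 static features on the smoothed (60x30) image and again
#' on the normalized (84x42) image of every sample and stacks them into a
#' \code{SummarizedExperiment}: assay \code{features} is a 200 x n matrix
#' (rows \code{smoothed.Feat1 .. normalized.Feat100}), with the sample
#' labels in \code{colData}.
#'
#' @param samples a [SleeveSamples-class] object.
#' @return A \code{SummarizedExperiment}.
#' @examples
#' ds <- generateDataset(syntheticConfig(nSubjects = 1, nRounds = 1, seed = 1))
#' ss <- preprocessDataset(ds$frames, ds$anthropometrics)
#' se <- extractFeatures(ss)
#' dim(SummarizedExperiment::assay(se))  # 200 x 18
#' @export
extractFeatures <- function(samples) {
  stopifnot(is(samples, "SleeveSamples"))
  n <- length(samples)
  sm <- smoothedImages(samples); nm <- normalizedImages(samples)
  mat <- matrix(0, 200L, n, dimnames = list(featureSetNames(), NULL))
  for (i in seq_len(n))
    mat[, i] <- c(imageFeatures(sm[, , i]), imageFeatures(nm[, , i]))
  SummarizedExperiment(assays = list(features = mat),
                       colData = sampleData(samples))
}
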