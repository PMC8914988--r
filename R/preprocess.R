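#' @importFrom stats rnorm runif var
NULL

## Corner-aligned bilinear resampling core. Output pixel (r, c) (0-based)
## samples the input at (r * (H-1)/(Hout-1), c * (W-1)/(Wout-1)), so the four
## image corners map onto each other and constant images are reproduced
## exactly. A degenerate axis (input or output extent 1) collapses to
## coordinate 0.
bilinearResize <- function(image, outRows, outCols) {
  h <- nrow(image); w <- ncol(image)
  rs <- if (outRows > 1L && h > 1L) (seq_len(outRows) - 1) * (h - 1) / (outRows - 1) else rep(0, outRows)
  cs <- if (outCols > 1L && w > 1L) (seq_len(outCols) - 1) * (w - 1) / (outCols - 1) else rep(0, outCols)
  r0 <- pmin(floor(rs), h - 1 - (h > 1))      # keep r0+1 a valid row
  c0 <- pmin(floor(cs), w - 1 - (w > 1))
  fr <- rs - r0; fc <- cs - c0
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  ## outer-product expansion of the four bilinear terms
  A <- image[r0 + 1, c0 + 1, drop = FALSE]
  B <- image[r0 + 1, c1 + 1, drop = FALSE]
  C <- image[r1 + 1, c0 + 1, drop = FALSE]
  D <- image[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, outRows, outCols)
  wc <- matrix(fc, outRows, outCols, byrow = TRUE)
  A * (1 - wr) * (1 - wc) + B * (1 - wr) * wc + C * wr * (1 - wc) + D * wr * wc
}

#' Upsample a pressure image by an integer factor
#'
#' Bilinear upsampling with the corner-aligned sample-position convention:
#' output pixel centres are spread uniformly so that the first and last
#' samples of each axis coincide with the input's first and last pixel
#' centres. A 20x10 frame upsampled by 3 becomes 60x30. Constant images are
#' reproduced exactly.
#'
#' @param image numeric matrix (H x W).
#' @param factor positive integer upsampling factor.
#' @return numeric matrix of dimension \code{(H*factor) x (W*factor)}.
#' @examples
#' dim(upsampleBilinear(matrix(runif(200), 20, 10), 3))  # 60 30
#' @export
upsampleBilinear <- function(image, factor = 3L) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("'factor' must be a positive integer")
  if (factor == 1L) return(image)
  bilinearResize(image, nrow(image) * factor, ncol(image) * factor)
}

#' 5x5 Gaussian kernel
#'
#' @param sigma positive standard deviation in pixels (default 1).
#' @param size odd kernel size (default 5).
#' @return A normalized \code{size x size} kernel summing to 1.
#' @export
gaussianKernel <- function(sigma = 1, size = 5L) {
  stopifnot(sigma > 0, size %% 2 == 1)
  r <- (size - 1L) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

## reflect indices 1..n about the borders (symmetric padding, edge repeated:
## for n=5, pad 2: indices 2 1 | 1..5 | 5 4)
reflectIndex <- function(idx, n) {
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  ifelse(idx > n, 2L * n + 1L - idx, idx)
}

#' Smooth an image with a 5x5 Gaussian filter
#'
#' Convolution with a normalized Gaussian kernel using reflective (symmetric)
#' border handling, so constants are preserved and edges are not darkened.
#' The kernel is separable; the filter is applied along rows then columns.
#'
#' @param image numeric matrix, at least \code{size x size}.
#' @param sigma kernel standard deviation in pixels; default 1.
#' @param size odd kernel size; default 5.
#' @return Smoothed matrix of the same dimension; non-negative inputs stay
#'   non-negative.
#' @export
gaussianSmooth <- function(image, sigma = 1, size = 5L) {
  stopifnot(is.matrix(image))
  size <- as.integer(size)
  if (nrow(image) < size || ncol(image) < size)
    stop(sprintf("image (%dx%d) is smaller than the %dx%d kernel",
                 nrow(image), ncol(image), size, size))
  r <- (size - 1L) / 2L
  g <- exp(-((-r):r)^2 / (2 * sigma^2)); g <- g / sum(g)
  h <- nrow(image); w <- ncol(image)
  ## rows
  out <- matrix(0, h, w)
  for (k in seq_len(size)) {
    idx <- reflectIndex(seq_len(h) + (k - 1L - r), h)
    out <- out + g[k] * image[idx, , drop = FALSE]
  }
  res <- matrix(0, h, w)
  for (k in seq_len(size)) {
    idx <- reflectIndex(seq_len(w) + (k - 1L - r), w)
    res <- res + g[k] * out[, idx, drop = FALSE]
  }
  res
}

#' Per-subject anthropometric scale ratios
#'
#' The row ratio alpha is the cohort mean forearm length divided by the
#' subject's forearm length; the column ratio beta is the cohort mean biceps
#' circumference divided by the subject's. Rows run along the arm (forearm
#' length), columns around it (biceps circumference). Scaling a subject's
#' image by (alpha, beta) maps it towards the cohort-average body size:
#' larger subjects shrink, smaller subjects grow.
#'
#' @param subjectId id of the subject to scale.
#' @param anthropometrics data.frame with columns \code{subject_id},
#'   \code{forearm_cm}, \code{biceps_cm} for the whole cohort.
#' @return list with elements \code{alpha} (row ratio) and \code{beta}
#'   (column ratio), both strictly positive.
#' @examples
#' a <- data.frame(subject_id = c("S1", "S2"),
#'                 forearm_cm = c(20, 30), biceps_cm = c(29, 29))
#' computeScaleRatios("S1", a)  # alpha = 25/20 = 1.25, beta = 1
#' @export
computeScaleRatios <- function(subjectId, anthropometrics) {
  need <- c("subject_id", "forearm_cm", "biceps_cm")
  miss <- setdiff(need, colnames(anthropometrics))
  if (length(miss))
    stop("anthropometrics lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(anthropometrics) == 0) stop("empty anthropometrics cohort")
  if (any(anthropometrics$forearm_cm <= 0) || any(anthropometrics$biceps_cm <= 0))
    stop("anthropometric lengths must be strictly positive")
  i <- match(subjectId, anthropometrics$subject_id)
  if (is.na(i)) stop("unknown subject_id: ", subjectId)
  list(alpha = mean(anthropometrics$forearm_cm) / anthropometrics$forearm_cm[i],
       beta  = mean(anthropometrics$biceps_cm) / anthropometrics$biceps_cm[i])
}

#' Rescale an image by row/column ratios
#'
#' Bilinear resampling of the rows by \code{alpha} and the columns by
#' \code{beta} to dimension \code{(round(H*alpha), round(W*beta))}.
#' Ratios of exactly 1 are the identity.
#'
#' @param image numeric matrix.
#' @param ratios list with \code{alpha} and \code{beta}, e.g. from
#'   [computeScaleRatios()].
#' @return Resized matrix.
#' @export
scaleImage <- function(image, ratios) {
  stopifnot(is.matrix(image))
  alpha <- ratios$alpha; beta <- ratios$beta
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("scale ratios must be strictly positive")
  hn <- round(nrow(image) * alpha); wn <- round(ncol(image) * beta)
  if (hn < 1 || wn < 1)
    stop("scaling would collapse the image to an empty dimension")
  if (hn == nrow(image) && wn == ncol(image) && alpha == 1 && beta == 1)
    return(image)
  bilinearResize(image, hn, wn)
}

#' Exposure image of one wearing round
#'
#' Sums all frames of a round elementwise and locates the pressure-weighted
#' centre of mass. The exposure image accumulates everywhere the sleeve
#' touched anything during the round, so its centre of mass tracks how the
#' sleeve sat on the arm for that wearing.
#'
#' @param frames list of numeric matrices (all the same dimension), or a 3-d
#'   array \code{[row, col, frame]}.
#' @return list with \code{image} (the elementwise sum) and \code{com}
#'   (c(row, col), 0-based fractional pixels; \code{NA} if the sum is all
#'   zero, with a warning).
#' @export
exposureImage <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (length(frames) == 0) stop("a round must contain at least one frame")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames of a round must share one dimension")
  img <- Reduce(`+`, frames)
  list(image = img, com = centerOfMassRC(img))
}

## pressure-weighted centre of mass in (row, col), 0-based; NA if massless
centerOfMassRC <- function(img) {
  tot <- sum(img)
  if (tot <= 0) {
    warning("all-zero exposure image: centre of mass undefined")
    return(c(NA_real_, NA_real_))
  }
  r <- sum(rowSums(img) * (seq_len(nrow(img)) - 1)) / tot
  c <- sum(colSums(img) * (seq_len(ncol(img)) - 1)) / tot
  c(r, c)
}

#' Per-round alignment offsets from exposure-image centres of mass
#'
#' The target position is the mean of all rounds' exposure centres of mass;
#' each round's offset is target minus its own centre, so offsets average to
#' (0, 0) across rounds.
#'
#' @param coms matrix or data.frame with one row per round, columns
#'   (row, col), as produced by [exposureImage()].
#' @return matrix of offsets (\code{drow}, \code{dcol}), one row per round.
#' @export
computeRoundOffsets <- function(coms) {
  coms <- as.matrix(coms)
  if (nrow(coms) == 0 || any(!is.finite(coms)))
    stop("need at least one round with a defined centre of mass")
  target <- colMeans(coms)
  off <- cbind(target[1] - coms[, 1], target[2] - coms[, 2])
  colnames(off) <- c("drow", "dcol")
  off
}

## translate by a possibly fractional (drow, dcol) via bilinear sampling;
## content shifted past the border is discarded, vacated pixels are zero
shiftImage <- function(image, drow, dcol) {
  h <- nrow(image); w <- ncol(image)
  rs <- (seq_len(h) - 1) - drow
  cs <- (seq_len(w) - 1) - dcol
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  pick <- function(ri, ci) {
    ok_r <- ri >= 0 & ri <= h - 1
    ok_c <- ci >= 0 & ci <= w - 1
    m <- matrix(0, h, w)
    if (any(ok_r) && any(ok_c))
      m[ok_r, ok_c] <- image[ri[ok_r] + 1, ci[ok_c] + 1, drop = FALSE]
    m
  }
  wr <- matrix(fr, h, w); wc <- matrix(fc, h, w, byrow = TRUE)
  pick(r0, c0) * (1 - wr) * (1 - wc) +
    pick(r0, c0 + 1) * (1 - wr) * wc +
    pick(r0 + 1, c0) * wr * (1 - wc) +
    pick(r0 + 1, c0 + 1) * wr * wc
}

#' Embed an image on a zero canvas and apply a rigid shift
#'
#' The input (nominally a scaled image near 60x30) is centred on an
#' \code{outRows x outCols} zero canvas (default 84x42) and then translated
#' by \code{offset = c(drow, dcol)}. Fractional offsets are applied by
#' bilinear resampling. Content shifted beyond the canvas is cropped; inputs
#' larger than the canvas are cropped to it with a warning.
#'
#' @param image numeric matrix.
#' @param offset numeric c(drow, dcol), default c(0, 0).
#' @param outRows,outCols canvas size, default 84 x 42.
#' @return \code{outRows x outCols} matrix, non-negative if the input is.
#' @export
shiftAndPad <- function(image, offset = c(0, 0), outRows = 84L, outCols = 42L) {
  stopifnot(is.matrix(image), length(offset) == 2, all(is.finite(offset)))
  h <- nrow(image); w <- ncol(image)
  if (h > outRows || w > outCols) {
    warning(sprintf("input %dx%d larger than %dx%d canvas: cropping",
                    h, w, outRows, outCols))
    image <- image[seq_len(min(h, outRows)), seq_len(min(w, outCols)), drop = FALSE]
    h <- nrow(image); w <- ncol(image)
  }
  canvas <- matrix(0, outRows, outCols)
  r0 <- floor((outRows - h) / 2); c0 <- floor((outCols - w) / 2)
  canvas[r0 + seq_len(h), c0 + seq_len(w)] <- image
  if (all(offset == 0)) canvas else shiftImage(canvas, offset[1], offset[2])
}

#' Preprocess a dataset of raw frames into sample pairs
#'
#' For every raw 20x10 frame: upsample 3x (bilinear) and smooth with a 5x5
#' Gaussian to obtain the 60x30 smoothed image; then rescale by the subject's
#' anthropometric ratios, embed on an 84x42 zero canvas and shift by the
#' round's alignment offset to obtain the normalized image. Round offsets are
#' estimated from the exposure image (elementwise sum) of each
#' (subject, round) group of embedded scaled frames: the offset moves each
#' round's exposure centre of mass onto the mean centre over all rounds.
#' Both images are kept per sample; the pipeline doubles the image count
#' rather than overwriting the original.
#'
#' @param frames a [SleeveFrames-class] object.
#' @param anthropometrics cohort table with \code{subject_id},
#'   \code{forearm_cm}, \code{biceps_cm}; every subject in \code{frames} must
#'   appear.
#' @param sigma Gaussian smoothing standard deviation (pixels), default 1.
#' @param upsampleFactor integer upsampling factor, default 3.
#' @param canvas c(rows, cols) of the final normalized image, default
#'   c(84, 42).
#' @return A [SleeveSamples-class] object.
#' @examples
#' cfg <- syntheticConfig(nSubjects = 2, nRounds = 2, seed = 1)
#' ds <- generateDataset(cfg)
#' ss <- preprocessDataset(ds$frames, ds$anthropometrics)
#' ss
#' @export
preprocessDataset <- function(frames, anthropometrics, sigma = 1,
                              upsampleFactor = 3L, canvas = c(84L, 42L)) {
  stopifnot(is(frames, "SleeveFrames"))
  fd <- as.data.frame(frameData(frames))
  n <- length(frames)
  unknown <- setdiff(unique(fd$subject_id), anthropometrics$subject_id)
  if (length(unknown))
    stop("no anthropometrics for subject(s): ", paste(unknown, collapse = ", "))
  v <- frameArray(frames)
  if (n == 0L)
    return(new("SleeveSamples",
               smoothed = array(0, c(dim(v)[1] * upsampleFactor,
                                     dim(v)[2] * upsampleFactor, 0)),
               normalized = array(0, c(canvas[1], canvas[2], 0)),
               sampleData = frameData(frames),
               roundOffsets = data.frame(subject_id = character(0),
                                         round_id = character(0),
                                         drow = numeric(0),
                                         dcol = numeric(0))))
  outSm <- array(0, c(dim(v)[1] * upsampleFactor, dim(v)[2] * upsampleFactor, n))
  embedded <- vector("list", n)
  ratios <- lapply(unique(fd$subject_id), computeScaleRatios,
                   anthropometrics = anthropometrics)
  names(ratios) <- unique(fd$subject_id)
  for (i in seq_len(n)) {
    sm <- gaussianSmooth(upsampleBilinear(v[, , i], upsampleFactor), sigma = sigma)
    outSm[, , i] <- sm
    sc <- scaleImage(sm, ratios[[fd$subject_id[i]]])
    embedded[[i]] <- shiftAndPad(sc, c(0, 0), canvas[1], canvas[2])
  }
  ## per-(subject, round) exposure images on the embedded canvases
  key <- paste(fd$subject_id, fd$round_id, sep = "\r")
  ukey <- unique(key)
  coms <- t(vapply(ukey, function(k) {
    suppressWarnings(exposureImage(embedded[key == k])$com)
  }, numeric(2)))
  valid <- is.finite(coms[, 1])
  if (!any(valid)) {
    ## pressureless dataset: nothing to align, keep zero offsets
    warning("all exposure images are zero; no shift applied")
    off <- matrix(0, nrow(coms), 2, dimnames = list(NULL, c("drow", "dcol")))
  } else {
    target <- colMeans(coms[valid, , drop = FALSE])
    off <- cbind(drow = ifelse(valid, target[1] - coms[, 1], 0),
                 dcol = ifelse(valid, target[2] - coms[, 2], 0))
  }
  outNorm <- array(0, c(canvas[1], canvas[2], n))
  for (i in seq_len(n)) {
    k <- match(key[i], ukey)
    img <- shiftImage(embedded[[i]], off[k, 1], off[k, 2])
    img[img < 0] <- 0          # clamp tiny negative interpolation residue
    outNorm[, , i] <- img
  }
  offDf <- data.frame(subject_id = sub("\r.*", "", ukey),
                      round_id = sub(".*\r", "", ukey),
                      drow = off[, 1], dcol = off[, 2],
                      stringsAsFactors = FALSE)
  new("SleeveSamples", smoothed = outSm, normalized = outNorm,
      sampleData = frameData(frames), roundOffsets = offDf)
}
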