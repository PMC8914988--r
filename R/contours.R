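#' Label connected regions of a binary image
#'
#' 8-connectivity flood fill (iterative queue). Used to delineate the
#' "contours" of a pressure image: the connected regions of the binarized
#' image.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of the same dimension; 0 = background, regions
#'   numbered 1..k in order of their first pixel in row-major scan.
#' @export
labelRegions <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  stackR <- integer(h * w); stackC <- integer(h * w)
  k <- 0L
  ## row-major scan so that region ids follow first-found row-major order
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    k <- k + 1L
    top <- 1L; stackR[1] <- r; stackC[1] <- c
    lab[r, c] <- k
    while (top > 0L) {
      pr <- stackR[top]; pc <- stackC[top]; top <- top - 1L
      for (j in 1:8) {
        rr <- pr + dr[j]; cc <- pc + dc[j]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          top <- top + 1L
          stackR[top] <- rr; stackC[top] <- cc
        }
      }
    }
  }
  lab
}

#' Contour statistics of a pressure image
#'
#' Binarizes the image at the mean of all its pixels and labels the
#' 8-connected regions above threshold ("contours"). For each contour the
#' area (pixel count), pressure (sum of the original pixel values) and
#' intensity (pressure / area) are reported.
#'
#' @param image numeric matrix.
#' @return list with \code{threshold}, \code{labels} (integer matrix),
#'   \code{n} (number of contours) and \code{stats} (data.frame with columns
#'   \code{area}, \code{pressure}, \code{intensity}; zero rows if the image
#'   has no above-mean pixels).
#' @export
contourStats <- function(image) {
  thr <- mean(image)
  mask <- image > thr
  lab <- labelRegions(mask)
  k <- max(lab)
  if (k == 0L)
    return(list(threshold = thr, labels = lab, n = 0L,
                stats = data.frame(area = numeric(0), pressure = numeric(0),
                                   intensity = numeric(0))))
  area <- tabulate(lab[lab > 0], nbins = k)
  pressure <- vapply(seq_len(k), function(i) sum(image[lab == i]), numeric(1))
  list(threshold = thr, labels = lab, n = k,
       stats = data.frame(area = area, pressure = pressure,
                          intensity = pressure / area))
}

#' Mask an image to its maximum-pressure contour
#'
#' Zeroes every pixel outside the contour (connected above-mean region) with
#' the largest total pressure. Ties are broken by the region whose first
#' pixel comes earliest in row-major order. An image with no contours masks
#' to all zeros.
#'
#' @param image numeric matrix.
#' @param cs optional precomputed [contourStats()] result.
#' @return numeric matrix of the same dimension.
#' @export
maskedImage <- function(image, cs = contourStats(image)) {
  if (cs$n == 0L) return(matrix(0, nrow(image), ncol(image)))
  best <- which(cs$stats$pressure == max(cs$stats$pressure))[1]
  out <- matrix(0, nrow(image), ncol(image))
  sel <- cs$labels == best
  out[sel] <- image[sel]
  out
}

#' Hu's seven invariant moments
#'
#' Computed from the intensity image: raw moments m_pq = sum x^p y^q I(x,y)
#' with x = column, y = row (0-based); central moments about the centre of
#' mass; normalized central moments eta_pq = mu_pq / mu_00^(1+(p+q)/2); and
#' the seven classical rotation/translation/scale-invariant combinations.
#' An all-zero image returns seven zeros.
#'
#' @param image numeric matrix of non-negative intensities.
#' @return numeric vector of length 7.
#' @export
huMoments <- function(image) {
  h <- nrow(image); w <- ncol(image)
  x <- matrix(0:(w - 1), h, w, byrow = TRUE)
  y <- matrix(0:(h - 1), h, w)
  m00 <- sum(image)
  if (m00 <= 0) return(numeric(7))
  xb <- sum(x * image) / m00
  yb <- sum(y * image) / m00
  dx <- x - xb; dy <- y - yb
  mu <- function(p, q) sum(dx^p * dy^q * image)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}
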