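# Independent oracles used across the suite. These deliberately re-derive
# results with different algorithms than the package implementation.

# brute-force corner-aligned bilinear interpolation, evaluated pixel by pixel
bruteBilinear <- function(image, outRows, outCols) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, outRows, outCols)
  for (r in seq_len(outRows)) {
    for (c in seq_len(outCols)) {
      y <- if (outRows > 1 && h > 1) (r - 1) * (h - 1) / (outRows - 1) else 0
      x <- if (outCols > 1 && w > 1) (c - 1) * (w - 1) / (outCols - 1) else 0
      y0 <- min(floor(y), h - 1); x0 <- min(floor(x), w - 1)
      y1 <- min(y0 + 1, h - 1);   x1 <- min(x0 + 1, w - 1)
      fy <- y - y0; fx <- x - x0
      out[r, c] <- image[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        image[y0 + 1, x1 + 1] * (1 - fy) * fx +
        image[y1 + 1, x0 + 1] * fy * (1 - fx) +
        image[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out
}

# union-find connected-component labeler (8-connectivity) on a binary mask;
# returns the number of components and their sizes, sorted
unionFindComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  parent <- seq_len(h * w)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  lin <- function(r, c) (c - 1) * h + r
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if ((dr | dc) && rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          mask[rr, cc])
        union(lin(r, c), lin(rr, cc))
    }
  }
  roots <- vapply(which(mask), function(i) as.integer(find(i)), integer(1))
  sizes <- as.integer(table(roots))
  list(n = length(sizes), sizes = sort(sizes))
}

# weighted-mean centre of mass, 0-based (row, col)
bruteCom <- function(img) {
  tot <- sum(img)
  r <- 0; c <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    r <- r + (i - 1) * img[i, j]
    c <- c + (j - 1) * img[i, j]
  }
  c(r, c) / tot
}

# small default generator configuration used by several suites
smallConfig <- function(seed = 1, ...) {
  syntheticConfig(nSubjects = 2, nRounds = 2, seed = seed, ...)
}
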