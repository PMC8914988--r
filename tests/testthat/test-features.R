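test_that("statistical features match hand-computed values", {
  z <- statisticalFeatures(matrix(0, 4, 4))
  expect_equal(unname(z), rep(0, 8))

  img <- matrix(c(1, 3, 2, 6), 2, 2)   # values 1, 2, 3, 6
  f <- statisticalFeatures(img)
  entropy <- -sum(c(1, 2, 3, 6) / 12 * log(c(1, 2, 3, 6) / 12))
  expect_equal(unname(f), c(6, 2.5, 12, 3.5, 3, 3.5, 1.5, entropy))

  const <- statisticalFeatures(matrix(5, 3, 3))
  expect_equal(unname(const[6:8]), c(0, 0, log(9)))
})

test_that("coverage quantiles follow the cumulative-sum definition", {
  one <- matrix(0, 5, 4); one[2, 2] <- 9
  for (q in c(0.25, 0.5, 0.75))
    expect_equal(coverageQuantile(one, q), 1 / 20)

  unif <- matrix(2, 6, 5)
  expect_equal(coverageQuantile(unif, 0.5), ceiling(0.5 * 30) / 30)

  set.seed(1)
  for (i in 1:20) {
    img <- matrix(rpois(40, 3), 8, 5)
    r <- vapply(c(0.25, 0.5, 0.75), coverageQuantile, numeric(1), image = img)
    expect_true(all(diff(r) >= 0))
  }
  expect_error(coverageQuantile(unif, 0), "between")
  expect_error(coverageQuantile(unif, 1), "between")
})

test_that("region coverage splits at the upper third and the column midpoint", {
  expect_equal(regionCoverage(matrix(0, 84, 42)), rep(0, 4))
  expect_equal(regionCoverage(matrix(1, 84, 42)), rep(1, 4))
  img <- matrix(0, 84, 42); img[5, 3] <- 7
  expect_equal(regionCoverage(img), c(1 / (28 * 21), 0, 0, 0))
})

test_that("single-pixel geometry is located exactly", {
  img <- matrix(0, 9, 7); img[4, 6] <- 10    # 0-based (row 3, col 5)
  g <- geometricFeatures(img)
  expect_equal(unname(g[c("Feat9", "Feat10")]), c(5, 3))   # centroid (x, y)
  expect_equal(unname(g[c("Feat11", "Feat12")]), c(5, 3))  # com (x, y)
  expect_equal(unname(g["Feat13"]), sqrt(25 + 9))
  expect_equal(unname(g["Feat15"]), atan2(3, 5))
  expect_equal(unname(g[c("Feat17", "Feat18", "Feat19", "Feat20")]),
               c(1, 1, 1, 1))
  expect_equal(unname(g["Feat21"]), 1)       # one pixel above threshold 2
  expect_equal(unname(g["Feat37"]), 1)       # one contour
})

test_that("Hu moments agree with an independent reference and are invariant", {
  img <- matrix(c(0,0,0,0,0,0, 0,1,2,1,0,0, 0,2,9,2,1,0,
                  0,1,2,4,1,0, 0,0,1,1,0,0), 5, 6, byrow = TRUE)
  # reference values computed with scikit-image moments_hu on this matrix
  ref <- c(4.51895044e-02, 1.44630426e-04, 6.62551135e-07, 2.62760162e-06,
           -3.46696121e-12, 3.16001653e-08)
  hu <- huMoments(img)
  expect_equal(hu[1:6], ref, tolerance = 1e-6)
  expect_lt(abs(hu[7]), 1e-20)

  # translation invariance on a padded canvas
  pad <- matrix(0, 20, 20); pad[3:7, 3:8] <- img
  shifted <- matrix(0, 20, 20); shifted[9:13, 10:15] <- img
  expect_equal(huMoments(pad), huMoments(shifted), tolerance = 1e-9)

  # scale invariance under 2x bilinear upscaling (5% relative)
  blob <- outer(dnorm(1:15, 8, 2.5), dnorm(1:15, 7, 2))
  up <- upsampleBilinear(blob, 2)
  h1 <- huMoments(blob); h2 <- huMoments(up)
  expect_equal(h2[1:4], h1[1:4], tolerance = 0.05)

  # exact invariance under a proper 90-degree rotation
  sq <- matrix(0, 16, 16); sq[4:8, 5:10] <- img
  rot <- t(sq)[, rev(seq_len(16))]   # 90-degree rotation
  expect_equal(huMoments(rot), huMoments(sq), tolerance = 1e-6)

  expect_equal(huMoments(matrix(0, 5, 5)), numeric(7))
})

test_that("contour statistics agree with a union-find oracle on random images", {
  set.seed(77)
  for (i in 1:100) {
    img <- matrix(rbinom(100, 1, runif(1, 0.2, 0.7)) * runif(100, 1, 9),
                  10, 10)
    cs <- contourStats(img)
    oracle <- unionFindComponents(img > mean(img))
    expect_equal(cs$n, oracle$n)
    expect_equal(sort(cs$stats$area), oracle$sizes)
    # per-contour identities
    if (cs$n > 0) {
      expect_true(all(cs$stats$area >= 1))
      expect_equal(cs$stats$intensity, cs$stats$pressure / cs$stats$area)
      expect_equal(sum(cs$stats$pressure), sum(img[img > mean(img)]))
    }
  }
})

test_that("two disjoint equal blobs yield two contours and a row-major mask tie-break", {
  img <- matrix(0, 12, 12)
  img[2:3, 2:3] <- 5      # blob 1: 4 px, pressure 20
  img[8:9, 8:9] <- 5      # blob 2: equal pressure
  cs <- contourStats(img)
  expect_equal(cs$n, 2L)
  expect_equal(cs$stats$area, c(4L, 4L))
  msk <- maskedImage(img)
  expect_equal(sum(msk > 0), 4L)
  expect_true(all(which(msk > 0, arr.ind = TRUE)[, "row"] <= 3))  # first in row-major order

  img[8:9, 8:9] <- 6      # now blob 2 dominates
  msk2 <- maskedImage(img)
  expect_true(all(which(msk2 > 0, arr.ind = TRUE)[, "row"] >= 8))
})

test_that("area is monotone under pointwise pixel increase", {
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(runif(60, 0, 6), 6, 10)
    b <- a + matrix(runif(60, 0, 3), 6, 10)
    fa <- geometricFeatures(a); fb <- geometricFeatures(b)
    expect_gte(fb["Feat21"], fa["Feat21"])
  }
})

test_that("symmetry features partition pressure and handle degenerate sides", {
  # mirror-symmetric image about its central column
  img <- matrix(0, 6, 7)
  img[3:4, c(2, 6)] <- 4   # mass placed off-centre, mirrored about column 4
  s <- symmetryFeatures(img)
  expect_equal(unname(s["Feat57"]), 1)  # area ratio
  expect_equal(unname(s["Feat58"]), 1)  # pressure ratio

  # hand-computed two-pixel case: masses 1 at x = 0 and 3 at x = 3 (width 4)
  two <- matrix(0, 1, 4); two[1, 1] <- 1; two[1, 4] <- 3
  s2 <- symmetryFeatures(two)
  expect_equal(unname(s2["Feat55"]), 1)      # left pressure (x < com_x = 2.25)
  expect_equal(unname(s2["Feat56"]), 3)      # right pressure
  expect_equal(unname(s2["Feat58"]), 1 / 3)  # pressure ratio left/right

  # all active pixels strictly left of the split: capped area ratio, finite
  left <- matrix(0, 3, 6); left[2, 1] <- 5; left[2, 4] <- 1
  sl <- symmetryFeatures(left)   # com_x = 0.5; only x = 0 is active (>= 2)
  expect_true(all(is.finite(sl)))
  expect_equal(unname(sl["Feat57"]), 1e6)
  expect_equal(unname(sl["Feat58"]), 5)

  # the strict-left rule makes every split an exact partition
  set.seed(8)
  for (i in 1:10) {
    img <- matrix(rpois(48, 2), 6, 8)
    f <- symmetryFeatures(img)
    expect_equal(unname(f["Feat55"] + f["Feat56"]), sum(img))
    expect_equal(unname(f["Feat61"] + f["Feat62"]), sum(img))
  }
})

test_that("every image yields exactly 100 finite features", {
  cases <- list(matrix(0, 20, 10),
                matrix(5, 20, 10),
                matrix(c(rep(0, 199), 7), 20, 10),
                matrix(runif(200, 0, 4095), 20, 10),
                matrix(rpois(2520, 1), 84, 30))
  for (img in cases) {
    f <- imageFeatures(img)
    expect_length(f, 100L)
    expect_true(all(is.finite(f)))
    expect_identical(names(f), paste0("Feat", 1:100))
  }
})

test_that("sample extraction concatenates both images with stable names", {
  ds <- generateDataset(syntheticConfig(nSubjects = 1, nRounds = 1, seed = 6))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  se <- extractFeatures(ss)
  mat <- SummarizedExperiment::assay(se)
  expect_equal(dim(mat), c(200L, 18L))
  expect_identical(rownames(mat), featureSetNames())
  expect_true(all(is.finite(mat)))
  i <- 7L
  expect_equal(unname(mat[1:100, i]),
               unname(imageFeatures(smoothedImages(ss)[, , i])))
  expect_equal(unname(mat[101:200, i]),
               unname(imageFeatures(normalizedImages(ss)[, , i])))
  expect_length(baselineFeatureNames(), 38L)
})
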