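test_that("bilinear upsampling matches a per-pixel oracle and its contracts", {
  frame <- matrix(runif(200, 0, 4095), 20, 10)
  up <- upsampleBilinear(frame, 3)
  expect_equal(dim(up), c(60L, 30L))
  expect_equal(up, bruteBilinear(frame, 60, 30), tolerance = 1e-12)

  expect_equal(upsampleBilinear(matrix(7, 4, 4), 5), matrix(7, 20, 20))

  tiny <- matrix(c(0, 6), 1, 2)
  expect_equal(as.numeric(upsampleBilinear(tiny, 3)),
               as.numeric(bruteBilinear(tiny, 3, 6)))
  expect_equal(unname(upsampleBilinear(tiny, 3)[1, ]),
               c(0, 1.2, 2.4, 3.6, 4.8, 6))

  expect_error(upsampleBilinear(frame, 0), "factor")
})

test_that("Gaussian smoothing preserves constants, mass and non-negativity", {
  expect_equal(gaussianSmooth(matrix(3.5, 8, 8)), matrix(3.5, 8, 8))
  expect_equal(gaussianSmooth(matrix(0, 6, 6)), matrix(0, 6, 6))

  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  sm <- gaussianSmooth(imp, sigma = 1)
  k <- gaussianKernel(1, 5)
  expect_equal(sm[4:8, 4:8], k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_true(all(sm >= 0))

  expect_error(gaussianSmooth(matrix(1, 4, 4)), "smaller")
})

test_that("scale ratios follow the cohort-mean over subject-length rule", {
  cohort <- data.frame(subject_id = c("A", "B"),
                       forearm_cm = c(20, 30), biceps_cm = c(25, 35))
  r <- computeScaleRatios("A", cohort)
  expect_equal(r$alpha, 25 / 20)
  expect_equal(r$beta, 30 / 25)

  single <- data.frame(subject_id = "X", forearm_cm = 25.5, biceps_cm = 29)
  r1 <- computeScaleRatios("X", single)
  expect_equal(r1$alpha, 1)
  expect_equal(r1$beta, 1)

  expect_error(computeScaleRatios("Z", cohort), "unknown")
  bad <- cohort; bad$forearm_cm[1] <- -1
  expect_error(computeScaleRatios("A", bad), "positive")
})

test_that("image scaling honours the shape contract and identity", {
  img <- matrix(runif(1800), 60, 30)
  expect_identical(scaleImage(img, list(alpha = 1, beta = 1)), img)
  half <- scaleImage(img, list(alpha = 0.5, beta = 0.5))
  expect_equal(dim(half), c(30L, 15L))
  expect_error(scaleImage(img, list(alpha = 0.001, beta = 1)), "empty|collapse")
  expect_error(scaleImage(img, list(alpha = -1, beta = 1)), "positive")
})

test_that("exposure image sums frames and locates the centre of mass", {
  f1 <- matrix(0, 5, 5); f1[3, 2] <- 4
  e1 <- exposureImage(list(f1))
  expect_equal(e1$com, c(2, 1))          # 0-based (row, col)

  f2 <- matrix(0, 5, 5); f2[1, 1] <- 2
  f3 <- matrix(0, 5, 5); f3[3, 3] <- 2
  e2 <- exposureImage(list(f2, f3))
  expect_equal(e2$com, c(1, 1))

  set.seed(42)
  frames <- replicate(18, matrix(rpois(25, 4), 5, 5), simplify = FALSE)
  e3 <- exposureImage(frames)
  expect_equal(e3$image, Reduce(`+`, frames))
  expect_equal(e3$com, bruteCom(e3$image), tolerance = 1e-12)

  expect_error(exposureImage(list()), "at least one")
  expect_warning(z <- exposureImage(list(matrix(0, 3, 3))), "undefined")
  expect_true(all(is.na(z$com)))
})

test_that("round offsets recentre on the mean exposure centre", {
  expect_equal(unname(computeRoundOffsets(matrix(c(7, 3), 1))), matrix(0, 1, 2))
  off <- computeRoundOffsets(rbind(c(10, 5), c(14, 7)))
  expect_equal(unname(off), rbind(c(2, 1), c(-2, -1)))
  many <- matrix(runif(10), 5, 2)
  expect_equal(colMeans(computeRoundOffsets(many)), c(drow = 0, dcol = 0),
               tolerance = 1e-12)
})

test_that("shift-and-pad embeds centrally and translates exactly", {
  img <- matrix(runif(1800), 60, 30)
  canvas <- shiftAndPad(img, c(0, 0))
  expect_equal(dim(canvas), c(84L, 42L))
  expect_equal(canvas[13:72, 7:36], img)
  expect_equal(sum(canvas), sum(img))

  dot <- matrix(0, 60, 30); dot[30, 15] <- 5
  moved <- shiftAndPad(dot, c(2, 1))
  expect_equal(which(moved != 0, arr.ind = TRUE)[1, ],
               c(row = 12 + 30 + 2, col = 6 + 15 + 1))

  expect_warning(big <- shiftAndPad(matrix(1, 90, 50), c(0, 0)), "cropping")
  expect_equal(dim(big), c(84L, 42L))
})

test_that("preprocessing produces the 60x30 / 84x42 sample pair per frame", {
  ds <- generateDataset(smallConfig(seed = 21))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  expect_s4_class(ss, "SleeveSamples")
  expect_equal(length(ss), length(ds$frames))
  expect_equal(dim(smoothedImages(ss))[1:2], c(60L, 30L))
  expect_equal(dim(normalizedImages(ss))[1:2], c(84L, 42L))
  expect_true(min(smoothedImages(ss)) >= 0)
  expect_true(min(normalizedImages(ss)) >= 0)
  # one offset row per (subject, round), averaging to zero
  off <- roundOffsets(ss)
  expect_equal(nrow(off), 4L)
  expect_equal(mean(off$drow), 0, tolerance = 1e-9)
  expect_equal(mean(off$dcol), 0, tolerance = 1e-9)
})

test_that("cohort-mean subjects pass through scaling unchanged", {
  ds <- generateDataset(syntheticConfig(nSubjects = 1, nRounds = 1, seed = 2,
                                        roundOffsetSd = 0))
  # single-subject cohort: alpha = beta = 1, shift = 0: the normalized image
  # is exactly the embedded smoothed image
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  sm <- smoothedImages(ss)[, , 1]
  nm <- normalizedImages(ss)[, , 1]
  expect_lt(max(abs(nm[13:72, 7:36] - sm)), 1e-9)
})

test_that("degenerate preprocessing inputs are handled gracefully", {
  ds <- generateDataset(smallConfig(seed = 4))
  empty <- ds$frames[integer(0)]
  out <- preprocessDataset(empty, ds$anthropometrics)
  expect_equal(length(out), 0L)

  zeros <- SleeveFrames(array(0, c(20, 10, 4)),
                        data.frame(subject_id = "S01",
                                   round_id = rep(1:2, each = 2),
                                   activity = rep(c("a", "b"), 2)))
  anth <- data.frame(subject_id = "S01", forearm_cm = 25, biceps_cm = 29)
  expect_warning(zz <- preprocessDataset(zeros, anth), "zero")
  expect_equal(max(normalizedImages(zz)), 0)

  expect_error(preprocessDataset(ds$frames,
                                 ds$anthropometrics[1, , drop = FALSE]),
               "anthropometrics")
})

test_that("applying the computed offsets realigns exposure centres of mass", {
  ds <- generateDataset(syntheticConfig(nSubjects = 3, nRounds = 3, seed = 31,
                                        roundOffsetSd = 1.5))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  fd <- as.data.frame(sampleData(ss))
  key <- paste(fd$subject_id, fd$round_id)
  nm <- normalizedImages(ss)
  coms <- t(sapply(unique(key), function(k) {
    exposureImage(nm[, , key == k])$com
  }))
  target <- colMeans(coms)
  dev <- sqrt(rowSums(sweep(coms, 2, target)^2))
  expect_lt(max(dev), 0.5)
})

test_that("normalization shrinks between-subject contact-area differences", {
  ds <- generateDataset(syntheticConfig(nSubjects = 5, nRounds = 2, seed = 13))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  meta <- as.data.frame(sampleData(ss))
  pre <- log(pmax(apply(smoothedImages(ss), 3, contactArea), 1))
  post <- log(pmax(apply(normalizedImages(ss), 3, contactArea), 1))
  vPre <- var(tapply(pre, meta$subject_id, mean))
  vPost <- var(tapply(post, meta$subject_id, mean))
  expect_lt(vPost, vPre)
})
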