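#' Default activity archetypes
#'
#' Eighteen contact-pattern archetypes shipped with the package, one per
#' emulated daily activity. Each archetype is a set of anisotropic Gaussian
#' pressure blobs on the 20x10 sensor grid (0-based grid coordinates), chosen
#' to resemble the unimodal/bimodal contact patches a sleeve records when the
#' forearm or elbow rests against surfaces. Users may supply their own table
#' with the same columns to [syntheticConfig()].
#'
#' @return data.frame with columns \code{activity}, \code{label},
#'   \code{blob}, \code{center_row}, \code{center_col}, \code{row_spread},
#'   \code{col_spread}, \code{amplitude}.
#' @export
defaultActivityArchetypes <- function() {
  path <- system.file("extdata", "activity_archetypes.csv",
                      package = "pressureHAR", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic sleeve-data generator
#'
#' Describes a synthetic recording campaign: \code{nSubjects} people each
#' wear the sleeve for \code{nRounds} rounds and perform every activity once
#' per round, yielding one averaged 20x10 pressure image per
#' (subject, round, activity).
#'
#' Three nuisance effects of real recordings are emulated:
#' \itemize{
#'   \item body size: each subject's sampled forearm length and biceps
#'     circumference determine row/column size factors that magnify or shrink
#'     the contact pattern (blob centres and spreads scale about the image
#'     origin), so larger subjects produce larger contact areas. The strength
#'     is controlled by \code{sizeEffect} (0 = off, 1 = fully proportional to
#'     the anthropometric ratio).
#'   \item re-wearing offsets: one rigid integer pixel shift per
#'     (subject, round), rounded from Gaussian draws with sd
#'     \code{roundOffsetSd}, applied to every frame of the round.
#'   \item sensor noise: additive Gaussian noise (sd \code{noiseSd}, sensor
#'     units); readings below \code{zeroFloor} are reported as 0 (quiescent
#'     sensor floor), values are clipped to \code{[0, adcMax]} and rounded to
#'     integers (12-bit ADC).
#' }
#'
#' @param nSubjects,nRounds positive integers.
#' @param activities character vector of activity ids; default all 18
#'   archetypes in \code{blobSpec}.
#' @param gridRows,gridCols sensor grid size, default 20 x 10.
#' @param adcMax sensor ceiling, default 4095.
#' @param blobSpec archetype table, default [defaultActivityArchetypes()].
#' @param sizeEffect multiplicative strength of the subject-size effect in
#'   [0, 1]; default 1.
#' @param roundOffsetSd sd (pixels) of the per-round rigid shift; default 1.
#' @param noiseSd sensor-unit sd of additive noise; default 25.
#' @param zeroFloor sensor floor: noisy readings below it report 0;
#'   default 50.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(nSubjects = 2, nRounds = 3, seed = 7)
#' @export
syntheticConfig <- function(nSubjects = 14L, nRounds = 10L, activities = NULL,
                            gridRows = 20L, gridCols = 10L, adcMax = 4095,
                            blobSpec = NULL, sizeEffect = 1,
                            roundOffsetSd = 1, noiseSd = 25, zeroFloor = 50,
                            seed = 1L) {
  if (nSubjects < 1 || nRounds < 1)
    stop("nSubjects and nRounds must be >= 1")
  if (adcMax <= 0) stop("adcMax must be positive")
  if (noiseSd < 0 || roundOffsetSd < 0)
    stop("noiseSd and roundOffsetSd must be non-negative")
  if (is.null(blobSpec)) blobSpec <- defaultActivityArchetypes()
  need <- c("activity", "center_row", "center_col", "row_spread",
            "col_spread", "amplitude")
  miss <- setdiff(need, colnames(blobSpec))
  if (length(miss))
    stop("blobSpec lacks column(s): ", paste(miss, collapse = ", "))
  if (any(blobSpec$center_row < 0 | blobSpec$center_row > gridRows - 1 |
          blobSpec$center_col < 0 | blobSpec$center_col > gridCols - 1))
    stop("blob centre outside the sensor grid")
  if (is.null(activities)) activities <- unique(blobSpec$activity)
  if (!all(activities %in% blobSpec$activity))
    stop("activities missing from blobSpec: ",
         paste(setdiff(activities, blobSpec$activity), collapse = ", "))
  structure(list(nSubjects = as.integer(nSubjects),
                 nRounds = as.integer(nRounds), activities = activities,
                 gridRows = as.integer(gridRows),
                 gridCols = as.integer(gridCols), adcMax = adcMax,
                 blobSpec = blobSpec, sizeEffect = sizeEffect,
                 roundOffsetSd = roundOffsetSd, noiseSd = noiseSd,
                 zeroFloor = zeroFloor, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

## truncated-normal draws by rejection (deterministic under the current RNG)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a subject anthropometrics table
#'
#' Forearm length is drawn from a truncated normal with mean 25.5 cm, sd
#' 1.8 cm on [23, 28] cm; biceps circumference from mean 29.0 cm, sd 4.7 cm
#' on [21, 38] cm — the published ranges for adult cohorts wearing
#' forearm-length sensor sleeves.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used.
#' @return data.frame with columns \code{subject_id}, \code{forearm_cm},
#'   \code{biceps_cm}.
#' @examples
#' generateAnthropometrics(3, seed = 1)
#' @export
generateAnthropometrics <- function(nSubjects, seed = NULL) {
  if (nSubjects < 1) stop("nSubjects must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(nSubjects)),
    forearm_cm = rtruncnorm(nSubjects, 25.5, 1.8, 23, 28),
    biceps_cm  = rtruncnorm(nSubjects, 29.0, 4.7, 21, 38),
    stringsAsFactors = FALSE)
}

## evaluate the summed Gaussian blobs of one activity for one subject/round
renderActivity <- function(blobs, gridRows, gridCols, sRow, sCol, dr, dc) {
  rr <- matrix(0:(gridRows - 1), gridRows, gridCols)
  cc <- matrix(0:(gridCols - 1), gridRows, gridCols, byrow = TRUE)
  img <- matrix(0, gridRows, gridCols)
  for (b in seq_len(nrow(blobs))) {
    r0 <- blobs$center_row[b] * sRow + dr
    c0 <- blobs$center_col[b] * sCol + dc
    sr <- blobs$row_spread[b] * sRow
    sc <- blobs$col_spread[b] * sCol
    img <- img + blobs$amplitude[b] *
      exp(-((rr - r0)^2 / (2 * sr^2) + (cc - c0)^2 / (2 * sc^2)))
  }
  img
}

#' Generate a synthetic sleeve dataset
#'
#' Produces exactly \code{nSubjects * nRounds * length(activities)} labelled
#' 20x10 frames plus the cohort anthropometrics. Subject size factors are
#' derived deterministically from the sampled anthropometrics
#' (rows ~ forearm length, columns ~ biceps circumference, each relative to
#' the cohort mean), so the anthropometric scaling of the preprocessing
#' pipeline can provably undo the size effect. All frames of one
#' (subject, round) share a single integer rigid offset. Fully reproducible
#' from \code{config$seed}.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with \code{frames} (a [SleeveFrames-class]) and
#'   \code{anthropometrics} (data.frame).
#' @examples
#' ds <- generateDataset(syntheticConfig(nSubjects = 1, nRounds = 1, seed = 1))
#' length(ds$frames)  # 18
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  anthro <- generateAnthropometrics(config$nSubjects, seed = NULL)
  sRow <- 1 + config$sizeEffect * (anthro$forearm_cm / mean(anthro$forearm_cm) - 1)
  sCol <- 1 + config$sizeEffect * (anthro$biceps_cm / mean(anthro$biceps_cm) - 1)
  acts <- config$activities
  n <- config$nSubjects * config$nRounds * length(acts)
  values <- array(0, c(config$gridRows, config$gridCols, n))
  subj <- character(n); rnd <- integer(n); act <- character(n)
  blobsByAct <- split(config$blobSpec, config$blobSpec$activity)
  i <- 0L
  for (s in seq_len(config$nSubjects)) {
    for (r in seq_len(config$nRounds)) {
      off <- round(rnorm(2, 0, config$roundOffsetSd))
      for (a in acts) {
        i <- i + 1L
        img <- renderActivity(blobsByAct[[a]], config$gridRows,
                              config$gridCols, sRow[s], sCol[s],
                              off[1], off[2])
        if (config$noiseSd > 0)
          img <- img + matrix(rnorm(length(img), 0, config$noiseSd),
                              nrow(img), ncol(img))
        img[img < config$zeroFloor] <- 0
        img <- round(pmin(pmax(img, 0), config$adcMax))
        values[, , i] <- img
        subj[i] <- anthro$subject_id[s]; rnd[i] <- r; act[i] <- a
      }
    }
  }
  fd <- DataFrame(subject_id = subj, round_id = rnd, activity = act)
  list(frames = new("SleeveFrames", values = values, frameData = fd),
       anthropometrics = anthro)
}

#' Contact area of a processed pressure image
#'
#' Number of pixels above a contact threshold. The default threshold of 200
#' sensor units sits well above the smoothed quiescent noise floor of the
#' generator, so the count measures the physical contact patch rather than
#' background speckle. Used in the size-normalization recovery analysis:
#' on synthetic data the between-subject variance of mean contact area
#' shrinks after anthropometric scaling.
#'
#' @param image numeric matrix.
#' @param threshold contact threshold in sensor units, default 200.
#' @return integer pixel count.
#' @export
contactArea <- function(image, threshold = 200) {
  sum(image > threshold)
}
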