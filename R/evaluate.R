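#' @importFrom stats median predict
NULL

#' Min-max feature normalization
#'
#' Per-feature affine map (v - min) / (max - min) with the minimum and
#' maximum taken on the training split only. Constant training features map
#' to 0 everywhere; values of other splits are clipped to [0, 1].
#'
#' @param train numeric matrix (samples x features) the scaler is fitted on.
#' @param other optional matrix with the same columns to transform with the
#'   training scaler.
#' @return list with \code{train}, \code{other} (or NULL) and the fitted
#'   \code{min}/\code{range} vectors.
#' @examples
#' minmaxNormalize(matrix(c(0, 5, 10), 3, 1))$train
#' @export
minmaxNormalize <- function(train, other = NULL) {
  train <- as.matrix(train)
  if (!is.null(other)) {
    other <- as.matrix(other)
    if (ncol(other) != ncol(train) ||
        !identical(colnames(other), colnames(train)))
      stop("feature columns of 'other' do not match 'train'")
  }
  lo <- apply(train, 2, min)
  rg <- apply(train, 2, max) - lo
  scale01 <- function(m) {
    out <- sweep(m, 2, lo, "-")
    const <- rg == 0
    out[, !const] <- sweep(out[, !const, drop = FALSE], 2, rg[!const], "/")
    out[, const] <- 0
    pmin(pmax(out, 0), 1)
  }
  list(train = scale01(train),
       other = if (is.null(other)) NULL else scale01(other),
       min = lo, range = rg)
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Accuracy is trace/total. Per-class precision P_i is the correct count
#' over the column (predicted-as-i) total, recall R_i over the row (true-i)
#' total, each taken as 0 when the denominator is 0. Macro precision and
#' recall are the unweighted class means, and macro F1 is their harmonic
#' combination 2PR/(P+R).
#'
#' @param cm square count matrix, rows = true class, cols = predicted.
#' @return named numeric vector (accuracy, macroP, macroR, macroF1).
#' @examples
#' macroMetrics(matrix(c(2, 0, 1, 3), 2, 2))
#' @export
macroMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0 || nrow(cm) != ncol(cm))
    stop("confusion matrix must be square and non-empty")
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  d <- diag(cm)
  P <- ifelse(colSums(cm) > 0, d / colSums(cm), 0)
  R <- ifelse(rowSums(cm) > 0, d / rowSums(cm), 0)
  mp <- mean(P); mr <- mean(R)
  c(accuracy = sum(d) / tot, macroP = mp, macroR = mr,
    macroF1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0)
}

#' Classical classifier configurations
#'
#' Returns the pinned configuration of one of the six supported classical
#' classifiers: polynomial-kernel SVM, 5-nearest-neighbour, l2-penalized
#' multinomial logistic regression (weight decay, up to 8000 iterations),
#' random forest (balanced class weights, Gini, log2 features, fixed random
#' state 40), decision tree (fixed random state 40) and Gaussian naive
#' Bayes. Hyperparameters not pinned here take the defaults of the
#' underlying R implementation (e1071, class, nnet, randomForest, rpart).
#'
#' @param algorithm one of "svm", "knn", "lr", "rf", "dt", "nb".
#' @return list with \code{algorithm} and \code{params}.
#' @export
classifierConfig <- function(algorithm = c("svm", "knn", "lr", "rf", "dt", "nb")) {
  algorithm <- match.arg(algorithm)
  params <- switch(algorithm,
    svm = list(kernel = "polynomial"),
    knn = list(k = 5),
    lr  = list(decay = 1e-4, maxit = 8000, randomState = 40),
    rf  = list(criterion = "gini", maxFeatures = "log2",
               classWeight = "balanced", randomState = 40),
    dt  = list(randomState = 40),
    nb  = list())
  list(algorithm = algorithm, params = params)
}

## fit one classifier on a (samples x features) matrix; returns an object
## understood by predictClassifier(). Gaussian NB drops zero-variance
## training columns (its class-conditional density is undefined at sd = 0).
trainClassifier <- function(config, x, y) {
  y <- droplevels(as.factor(y))
  switch(config$algorithm,
    svm = list(kind = "svm",
               fit = e1071::svm(x, y, kernel = config$params$kernel,
                                scale = FALSE)),
    knn = list(kind = "knn", x = x, y = y, k = config$params$k),
    lr  = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      set.seed(config$params$randomState)
      fit <- nnet::multinom(.y ~ ., data = df, decay = config$params$decay,
                            maxit = config$params$maxit,
                            MaxNWts = 1e6, trace = FALSE)
      list(kind = "lr", fit = fit)
    },
    rf  = {
      set.seed(config$params$randomState)
      tab <- table(y)
      cw <- as.numeric(sum(tab) / (length(tab) * tab))
      names(cw) <- names(tab)
      list(kind = "rf",
           fit = randomForest::randomForest(
             x, y, mtry = max(1, floor(log2(ncol(x)))), classwt = cw))
    },
    dt  = {
      set.seed(config$params$randomState)
      df <- data.frame(.y = y, x, check.names = FALSE)
      list(kind = "dt", fit = rpart::rpart(.y ~ ., data = df,
                                           method = "class"))
    },
    nb  = {
      keep <- apply(x, 2, function(col) stats::var(col) > 1e-12)
      if (!any(keep)) keep[1] <- TRUE
      list(kind = "nb", keep = keep,
           fit = e1071::naiveBayes(x[, keep, drop = FALSE], y))
    },
    stop("unknown algorithm id: ", config$algorithm))
}

predictClassifier <- function(model, x) {
  switch(model$kind,
    svm = predict(model$fit, x),
    knn = class::knn(model$x, x, model$y, k = model$k),
    lr  = predict(model$fit, newdata = data.frame(x, check.names = FALSE),
                  type = "class"),
    rf  = predict(model$fit, x),
    dt  = predict(model$fit, newdata = data.frame(x, check.names = FALSE),
                  type = "class"),
    nb  = predict(model$fit, x[, model$keep, drop = FALSE]))
}

## seeded stratified fold assignment: within each class, shuffled indices
## are dealt round-robin over folds
stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## shared fold-evaluation loop for kfold/loso over any train/predict pair
runFolds <- function(x, y, fold, config, scheme, classifierId,
                     normalize = TRUE) {
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  folds <- sort(unique(fold))
  pooled <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  per <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    te <- fold == folds[fi]
    xtr <- x[!te, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (normalize) {
      nm <- minmaxNormalize(xtr, xte)
      xtr <- nm$train; xte <- nm$other
    }
    model <- trainClassifier(config, xtr, y[!te])
    pred <- factor(as.character(predictClassifier(model, xte)), levels = lev)
    cm <- table(factor(y[te], levels = lev), pred)
    pooled <- pooled + as.matrix(unclass(cm))
    m <- macroMetrics(cm)
    per[[fi]] <- data.frame(fold = folds[fi], n = sum(te), t(m))
  }
  per <- do.call(rbind, per)
  mp <- mean(per$macroP); mr <- mean(per$macroR)
  new("SleeveEval", scheme = scheme, classifier = classifierId,
      accuracy = mean(per$accuracy), macroP = mp, macroR = mr,
      macroF1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0,
      perFold = per, confusion = pooled)
}

## accept features as a SummarizedExperiment (200 x n) or samples x features
## matrix; returns list(x, meta)
featureInput <- function(features) {
  if (is(features, "SummarizedExperiment")) {
    list(x = t(assay(features)), meta = as.data.frame(colData(features)))
  } else {
    list(x = as.matrix(features), meta = NULL)
  }
}

#' Stratified k-fold cross-validated evaluation
#'
#' Splits the samples into k stratified folds with a seeded shuffle; each
#' fold serves once as the 10\%-style test split while the rest trains the
#' classifier. Min-max normalization is fitted on each training split only.
#' Accuracy, macro precision and macro recall are averaged over folds
#' (macro F1 is the harmonic combination of the averaged P and R); the
#' confusion matrix is pooled over folds.
#'
#' @param features a \code{SummarizedExperiment} from [extractFeatures()] or
#'   a samples x features matrix.
#' @param labels class labels; taken from \code{colData(features)$activity}
#'   when omitted and available.
#' @param config a [classifierConfig()]; default polynomial-kernel SVM.
#' @param k number of folds, default 10.
#' @param seed RNG seed for the fold shuffle.
#' @param normalize fit min-max scaling per training split (default TRUE).
#' @return A [SleeveEval-class] object.
#' @export
runKFold <- function(features, labels = NULL, config = classifierConfig("svm"),
                     k = 10L, seed = 1L, normalize = TRUE) {
  if (k < 2) stop("k must be >= 2")
  fi <- featureInput(features)
  if (is.null(labels)) labels <- fi$meta$activity
  if (is.null(labels)) stop("labels are required")
  y <- droplevels(as.factor(labels))
  if (min(table(y)) < k)
    warning("fewer than k samples in some class; folds will be unbalanced")
  fold <- stratifiedFolds(y, k, seed)
  runFolds(fi$x, y, fold, config, "kfold", config$algorithm,
           normalize = normalize)
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: the subject's samples are the test set, all other
#' subjects train the classifier. Measures generalization to unseen people.
#' Normalization, metric averaging and pooling as in [runKFold()].
#'
#' @param features as in [runKFold()].
#' @param labels class labels (default \code{colData(features)$activity}).
#' @param subjects subject ids per sample (default
#'   \code{colData(features)$subject_id}).
#' @param config a [classifierConfig()].
#' @param normalize fit min-max scaling per training split (default TRUE).
#' @return A [SleeveEval-class] object.
#' @export
runLOSO <- function(features, labels = NULL, subjects = NULL,
                    config = classifierConfig("svm"), normalize = TRUE) {
  fi <- featureInput(features)
  if (is.null(labels)) labels <- fi$meta$activity
  if (is.null(subjects)) subjects <- fi$meta$subject_id
  if (is.null(labels) || is.null(subjects))
    stop("labels and subjects are required")
  us <- unique(subjects)
  if (length(us) < 2) stop("leave-one-subject-out needs at least 2 subjects")
  fold <- match(subjects, us)
  runFolds(fi$x, labels, fold, config, "loso", config$algorithm,
           normalize = normalize)
}

#' Ablation grid: size/shift normalization x feature set
#'
#' Evaluates every classifier under the four combinations of
#' \itemize{
#'   \item A: the anthropometric scaling + exposure-shift normalization.
#'     With A, features from both the smoothed and the normalized image are
#'     used; without A, only the smoothed-image features enter the
#'     classifier.
#'   \item B: the full 100-feature set per image versus the 38-feature
#'     baseline subset ([baselineFeatureNames()]).
#' }
#' under both the 10-fold and the LOSO scheme, producing one row per
#' classifier with eight accuracy columns.
#'
#' @param frames a [SleeveFrames-class] dataset.
#' @param anthropometrics the cohort anthropometrics table.
#' @param classifiers character vector of classifier ids.
#' @param k folds for the k-fold arm, default 10.
#' @param seed RNG seed for fold assignment.
#' @return data.frame with columns \code{classifier} and
#'   \code{<scheme>.<withA|noA>.<withB|noB>} accuracies.
#' @export
runAblation <- function(frames, anthropometrics,
                        classifiers = c("svm", "knn", "lr", "rf", "dt", "nb"),
                        k = 10L, seed = 1L) {
  samples <- preprocessDataset(frames, anthropometrics)
  se <- extractFeatures(samples)
  x <- t(assay(se))
  meta <- as.data.frame(colData(se))
  sets <- list(
    withA.withB = featureSetNames(),
    noA.withB   = featureSetNames("smoothed"),
    withA.noB   = as.vector(outer(c("smoothed.", "normalized."),
                                  baselineFeatureNames(), paste0)),
    noA.noB     = paste0("smoothed.", baselineFeatureNames()))
  out <- lapply(classifiers, function(cl) {
    cfg <- classifierConfig(cl)
    row <- list(classifier = cl)
    for (scheme in c("kfold", "loso")) {
      for (s in names(sets)) {
        xs <- x[, sets[[s]], drop = FALSE]
        ev <- if (scheme == "kfold")
          runKFold(xs, meta$activity, cfg, k = k, seed = seed)
        else
          runLOSO(xs, meta$activity, meta$subject_id, cfg)
        row[[paste(scheme, s, sep = ".")]] <- unname(evalMetrics(ev)["accuracy"])
      }
    }
    as.data.frame(row)
  })
  do.call(rbind, out)
}
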