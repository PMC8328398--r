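## Evaluation protocol: stratified 80:20 split, repeated stratified 3-fold
## CV inside the training split with per-fold consensus feature selection,
## four classifiers, rank-based AUC and threshold metrics.

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half.  Equals the normalized count of concordant pairs.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels two-class labels.
#' @param positiveClass the positive label (default `"rebounder"`).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels, positiveClass = "rebounder") {
  pos <- labels == positiveClass
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy, sensitivity and specificity at a score threshold
#'
#' Predictions are positive (rebounder) when `score >= threshold`.
#'
#' @inheritParams auc
#' @param threshold decision threshold on the score.
#' @return named numeric(3): ACC, Sens, Spec.
#' @export
confusionMetrics <- function(scores, labels, threshold = 0.5,
                             positiveClass = "rebounder") {
  pos <- labels == positiveClass
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pred <- scores >= threshold
  c(ACC = mean(pred == pos),
    Sens = sum(pred & pos) / sum(pos),
    Spec = sum(!pred & !pos) / sum(!pos))
}

#' CvResult: cross-validated metric summary for one classifier
#'
#' @slot classifier classifier name.
#' @slot metrics 4 x 2 matrix (AUC/ACC/Sens/Spec by mean/sd) over the
#'   iteration x fold evaluations.
#' @slot scores per-eye mean out-of-fold prediction score.
#' @slot heldout named numeric(4) of held-out test-split metrics (NA when
#'   the protocol uses the full cohort for training).
#' @export
setClass("CvResult",
  representation(classifier = "character", metrics = "matrix",
                 scores = "numeric", heldout = "numeric"))

setMethod("show", "CvResult", function(object) {
  m <- object@metrics
  cat(sprintf("CvResult [%s]: %s\n", object@classifier,
              paste(sprintf("%s %.3f+/-%.3f", rownames(m), m[, 1], m[, 2]),
                    collapse = ", ")))
})

stratifiedSplit <- function(f, fraction) {
  idx <- integer(0)
  for (lv in levels(f)) {
    i <- which(f == lv)
    nTake <- round(length(i) * fraction)
    nTake <- max(min(nTake, length(i)), if (fraction < 1) 1L else length(i))
    idx <- c(idx, sample(i, nTake))
  }
  sort(idx)
}

stratifiedFolds <- function(f, nFolds) {
  fold <- integer(length(f))
  for (lv in levels(f)) {
    i <- sample(which(f == lv))
    fold[i] <- rep_len(seq_len(nFolds), length(i))
  }
  fold
}

fitAndScore <- function(clf, xTrain, yTrain, xTest, positiveClass, seed) {
  df <- data.frame(xTrain)
  dfT <- data.frame(xTest)
  colnames(dfT) <- colnames(df)
  withRNG(seed, tryCatch(switch(clf,
    LDA = {
      fit <- MASS::lda(df, grouping = yTrain)
      predict(fit, dfT)$posterior[, positiveClass]
    },
    QDA = {
      fit <- MASS::qda(df, grouping = yTrain)
      predict(fit, dfT)$posterior[, positiveClass]
    },
    RF = {
      fit <- randomForest::randomForest(df, y = yTrain, ntree = 100)
      predict(fit, dfT, type = "prob")[, positiveClass]
    },
    SVM = {
      fit <- e1071::svm(df, yTrain, kernel = "linear", probability = TRUE)
      attr(predict(fit, dfT, probability = TRUE),
           "probabilities")[, positiveClass]
    }), error = function(e) rep(NA_real_, nrow(dfT))))
}

#' Run the repeated cross-validation evaluation protocol
#'
#' The cohort is split 80:20 (stratified, seeded).  Within the training
#' split, each iteration draws a stratified `nFolds`-fold partition; in
#' every fold, features are z-normalized with fold-train statistics
#' (missing values imputed to 0 after normalization), the three-method
#' consensus picks two features on fold-train only, and each classifier is
#' fit on those two features and scored on fold-test.  Metrics are pooled
#' as mean and sd over all iteration x fold evaluations.  A final model per
#' classifier (selection and normalization on the full training split) is
#' scored on the held-out 20% and reported separately.
#'
#' @param table a [FeatureTable-class] or numeric matrix of raw
#'   (unnormalized) features.
#' @param labels class labels, one per row.
#' @param protocol an [EvalProtocol-class].
#' @param normalize `"fold"` (refit inside each fold; default) or
#'   `"cohort"` (single cohort-wide normalization, the study's phrasing).
#' @return named list of [CvResult-class] objects, one per classifier, with
#'   attributes `best` (classifier with highest mean AUC) and
#'   `selectionAudit` (per iteration/fold consensus audit data.frame).
#' @export
runProtocol <- function(table, labels, protocol = evalProtocol(),
                        normalize = c("fold", "cohort")) {
  normalize <- match.arg(normalize)
  m <- if (is(table, "FeatureTable")) featureValues(table) else table
  f <- asLabelFactor(labels, protocol@positiveClass)
  pos <- protocol@positiveClass
  seed <- protocol@seed

  trainIdx <- withRNG(seed, stratifiedSplit(f, protocol@trainFraction))
  testIdx <- setdiff(seq_len(nrow(m)), trainIdx)
  if (min(table(f[trainIdx])) < protocol@nFolds)
    stop("too few eyes per class in the training split for ",
         protocol@nFolds, "-fold CV")

  mTr <- m[trainIdx, , drop = FALSE]
  fTr <- droplevels(f[trainIdx])
  cohortNorm <- znormalizeMatrix(mTr)

  classifiers <- protocol@classifiers
  metricNames <- c("AUC", "ACC", "Sens", "Spec")
  acc <- lapply(classifiers, function(x)
    matrix(NA_real_, protocol@nIterations * protocol@nFolds, 4,
           dimnames = list(NULL, metricNames)))
  names(acc) <- classifiers
  scoreSum <- matrix(0, length(trainIdx), length(classifiers),
                     dimnames = list(NULL, classifiers))
  scoreCnt <- scoreSum
  audit <- vector("list", protocol@nIterations * protocol@nFolds)

  row <- 0L
  for (iter in seq_len(protocol@nIterations)) {
    folds <- withRNG(seed + iter, {
      for (attempt in 1:20) {
        fl <- stratifiedFolds(fTr, protocol@nFolds)
        ok <- all(vapply(seq_len(protocol@nFolds), function(k)
          nlevels(droplevels(fTr[fl == k])) == 2L, logical(1)))
        if (ok) break
        warning("degenerate fold redrawn (iteration ", iter, ")")
      }
      fl
    })
    for (k in seq_len(protocol@nFolds)) {
      row <- row + 1L
      isTest <- folds == k
      xTr <- mTr[!isTest, , drop = FALSE]
      xTe <- mTr[isTest, , drop = FALSE]
      yTr <- droplevels(fTr[!isTest])
      yTe <- fTr[isTest]

      if (normalize == "fold") {
        nrm <- znormalizeMatrix(xTr)
        xTrN <- nrm$m
        xTeN <- znormalizeMatrix(xTe, nrm$center, nrm$scale)$m
      } else {
        xTrN <- cohortNorm$m[!isTest, , drop = FALSE]
        xTeN <- cohortNorm$m[isTest, , drop = FALSE]
      }
      xTrN[!is.finite(xTrN)] <- 0
      xTeN[!is.finite(xTeN)] <- 0

      sel <- consensusTop2(list(rankTtest(xTrN, yTr),
                                rankWilcoxon(xTrN, yTr),
                                rankMrmr(xTrN, yTr, k = 15L)), k = 15L)
      audit[[row]] <- data.frame(
        iteration = iter, fold = k,
        selected1 = sel$selected[1], selected2 = sel$selected[2],
        n_intersection = length(sel$intersection),
        fallback = sel$fallback)

      x2Tr <- xTrN[, sel$selected, drop = FALSE]
      x2Te <- xTeN[, sel$selected, drop = FALSE]
      for (ci in seq_along(classifiers)) {
        sc <- fitAndScore(classifiers[ci], x2Tr, yTr, x2Te, pos,
                          seed + iter * 131L + k)
        if (all(is.na(sc))) next
        lab <- as.character(yTe)
        acc[[ci]][row, ] <- c(auc(sc, lab, pos),
                              confusionMetrics(sc, lab, 0.5, pos))
        scoreSum[isTest, ci] <- scoreSum[isTest, ci] + sc
        scoreCnt[isTest, ci] <- scoreCnt[isTest, ci] + 1
      }
    }
  }

  # held-out evaluation: selection + normalization on the full training split
  heldout <- matrix(NA_real_, length(classifiers), 4,
                    dimnames = list(classifiers, metricNames))
  if (length(testIdx) > 0 && nlevels(droplevels(f[testIdx])) == 2L) {
    xTeN <- znormalizeMatrix(m[testIdx, , drop = FALSE],
                             cohortNorm$center, cohortNorm$scale)$m
    xTrN <- cohortNorm$m
    xTrN[!is.finite(xTrN)] <- 0
    xTeN[!is.finite(xTeN)] <- 0
    sel <- consensusTop2(list(rankTtest(xTrN, fTr),
                              rankWilcoxon(xTrN, fTr),
                              rankMrmr(xTrN, fTr, k = 15L)), k = 15L)
    for (ci in seq_along(classifiers)) {
      sc <- fitAndScore(classifiers[ci], xTrN[, sel$selected, drop = FALSE],
                        fTr, xTeN[, sel$selected, drop = FALSE], pos,
                        seed + 777L)
      if (all(is.na(sc))) next
      lab <- as.character(f[testIdx])
      heldout[ci, ] <- c(auc(sc, lab, pos),
                         confusionMetrics(sc, lab, 0.5, pos))
    }
  }

  ids <- rownames(m)[trainIdx]
  results <- lapply(seq_along(classifiers), function(ci) {
    mm <- acc[[ci]]
    metrics <- cbind(mean = colMeans(mm, na.rm = TRUE),
                     sd = apply(mm, 2, stats::sd, na.rm = TRUE))
    sc <- ifelse(scoreCnt[, ci] > 0, scoreSum[, ci] / scoreCnt[, ci],
                 NA_real_)
    names(sc) <- ids
    new("CvResult", classifier = classifiers[ci], metrics = metrics,
        scores = sc, heldout = heldout[ci, ])
  })
  names(results) <- classifiers
  best <- classifiers[which.max(vapply(results, function(r)
    r@metrics["AUC", "mean"], numeric(1)))]
  attr(results, "best") <- best
  attr(results, "selectionAudit") <- do.call(rbind, audit)
  results
}

#' Summarize protocol results as a table
#'
#' @param results the list returned by [runProtocol()].
#' @return data.frame: classifier x metric with mean and sd columns.
#' @export
cvSummary <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(classifier = r@classifier,
               metric = rownames(r@metrics),
               mean = r@metrics[, "mean"], sd = r@metrics[, "sd"],
               row.names = NULL)
  }))
}
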