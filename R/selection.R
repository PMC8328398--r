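## Consensus feature selection: Welch t-test, Wilcoxon rank-sum and mRmR
## rankings; top-15 per method; two best from the intersection.

asLabelFactor <- function(labels, positiveClass = "rebounder") {
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop("labels must contain exactly 2 classes, got ", nlevels(f))
  stats::relevel(f, ref = setdiff(levels(f), positiveClass)[1])
}

rankedList <- function(method, names, scores) {
  # deterministic order: ascending score, lexicographic name tie-break
  ord <- order(scores, names, method = "radix")
  structure(list(method = method, features = names[ord],
                 scores = scores[ord]), class = "RankedList")
}

#' @export
print.RankedList <- function(x, ...) {
  cat(sprintf("RankedList (%s): %d features; top: %s\n", x$method,
              length(x$features),
              paste(utils::head(x$features, 3), collapse = ", ")))
  invisible(x)
}

#' Rank features by two-sample tests
#'
#' `rankTtest` orders features by ascending Welch two-sample t-test p-value;
#' `rankWilcoxon` by Wilcoxon rank-sum p-value (exact distribution when both
#' groups have <= 25 samples and no ties are present, otherwise the normal
#' approximation with tie correction and continuity correction).  Ties in
#' p-value are broken lexicographically by feature name.
#'
#' @param table a [FeatureTable-class] or numeric matrix (rows = eyes).
#' @param labels class labels, two classes, one per row.
#' @return a `RankedList` (method, ordered feature names, scores).
#' @export
rankTtest <- function(table, labels) {
  m <- if (is(table, "FeatureTable")) featureValues(table) else table
  f <- asLabelFactor(labels)
  if (min(table(f)) < 2L) stop("each class needs >= 2 rows")
  g1 <- m[f == levels(f)[1], , drop = FALSE]
  g2 <- m[f == levels(f)[2], , drop = FALSE]
  n1 <- colSums(is.finite(g1)); n2 <- colSums(is.finite(g2))
  m1 <- colMeans(g1, na.rm = TRUE); m2 <- colMeans(g2, na.rm = TRUE)
  v1 <- colSums(sweep(g1, 2, m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- colSums(sweep(g2, 2, m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1  # constant or empty columns carry no signal
  rankedList("ttest", colnames(m), p)
}

#' @rdname rankTtest
#' @export
rankWilcoxon <- function(table, labels) {
  m <- if (is(table, "FeatureTable")) featureValues(table) else table
  f <- asLabelFactor(labels)
  if (min(table(f)) < 2L) stop("each class needs >= 2 rows")
  idx1 <- which(f == levels(f)[1])
  n1 <- length(idx1); n2 <- nrow(m) - n1; n <- nrow(m)
  r <- cpp_colranks(m)
  w <- colSums(r[idx1, , drop = FALSE]) - n1 * (n1 + 1) / 2  # U statistic
  hasTies <- vapply(seq_len(ncol(m)), function(j)
    anyDuplicated(m[, j]) > 0L, logical(1))
  p <- numeric(ncol(m))
  exact <- !hasTies & n1 <= 25 & n2 <= 25
  if (any(exact)) {
    u <- w[exact]
    # two-sided exact p as in wilcox.test
    pe <- vapply(u, function(ui) {
      if (ui > n1 * n2 / 2)
        min(1, 2 * stats::pwilcox(ui - 1, n1, n2, lower.tail = FALSE))
      else min(1, 2 * stats::pwilcox(ui, n1, n2))
    }, numeric(1))
    p[exact] <- pe
  }
  if (any(!exact)) {
    j <- which(!exact)
    mu <- n1 * n2 / 2
    tieCorr <- vapply(j, function(k) {
      nt <- table(m[, k])
      sum(nt^3 - nt)
    }, numeric(1))
    sig <- sqrt(n1 * n2 / 12 * ((n + 1) - tieCorr / (n * (n - 1))))
    z <- w[j] - mu
    z <- z - sign(z) * 0.5  # continuity correction
    z <- ifelse(sig > 0, z / sig, 0)
    p[j] <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  p <- pmin(p, 1)
  rankedList("wilcoxon", colnames(m), p)
}

#' Rank features by minimum-redundancy maximum-relevance (mRmR)
#'
#' Features are discretized into tertiles of their values; greedy forward
#' selection maximizes the mutual information with the label minus the mean
#' mutual information with already-selected features (the MID difference
#' form).  Scores are reported as negative mRmR criteria so that, as in the
#' test rankings, smaller is better.
#'
#' @inheritParams rankTtest
#' @param k number of features to select.
#' @return a `RankedList` of the `k` selected features in selection order.
#' @export
rankMrmr <- function(table, labels, k = 15L) {
  m <- if (is(table, "FeatureTable")) featureValues(table) else table
  f <- asLabelFactor(labels)
  p <- ncol(m)
  if (k > p) stop("k (", k, ") exceeds feature count (", p, ")")
  bins <- apply(m, 2, discretizeTertiles)
  y <- as.integer(f)

  oneHot <- function(v, nl) {
    o <- matrix(0L, length(v), nl)
    o[cbind(seq_along(v), v)] <- 1L
    o
  }
  B <- lapply(1:3, function(b) bins == b)          # n x p logicals per bin
  Y <- oneHot(y, 2L)
  n <- nrow(m)

  # relevance I(feature; label) in bits
  rel <- numeric(p)
  for (b in 1:3) {
    cnt <- crossprod(Y, B[[b]])                    # 2 x p joint counts
    pb <- colSums(B[[b]]) / n
    for (c in 1:2) {
      pj <- cnt[c, ] / n
      pc <- sum(y == c) / n
      term <- ifelse(pj > 0, pj * log2(pj / (pc * pb)), 0)
      rel <- rel + term
    }
  }

  selected <- integer(0)
  redSum <- numeric(p)
  nms <- colnames(m)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0) rel else rel - redSum / length(selected)
    score[selected] <- -Inf
    best <- which(score == max(score))
    if (length(best) > 1) best <- best[order(nms[best])][1]
    selected <- c(selected, best)
    if (step == k) break
    # update redundancy with the newly selected feature
    bsel <- bins[, best]
    for (bs in 1:3) {
      sel <- bsel == bs
      ps <- mean(sel)
      if (ps == 0) next
      for (b in 1:3) {
        pj <- colSums(B[[b]] & sel) / n
        pb <- colSums(B[[b]]) / n
        term <- ifelse(pj > 0, pj * log2(pj / (ps * pb)), 0)
        redSum <- redSum + term
      }
    }
  }
  scoreOut <- seq_along(selected)  # selection order is the rank
  rankedList("mrmr", nms[selected], scoreOut)
}

discretizeTertiles <- function(v) {
  qs <- stats::quantile(v, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE,
                        type = 7)
  b <- findInterval(v, unique(qs), left.open = TRUE) + 1L
  b[is.na(b)] <- 1L
  b
}

#' Consensus selection of the two best features
#'
#' Intersects the three methods' top-`k` sets and selects the two members
#' with the lowest mean rank across the three rankings.  When the
#' intersection has fewer than two members the selection falls back to the
#' lowest mean rank over the union of the top-`k` sets (flagged in the
#' result).  Ties are broken lexicographically by name.
#'
#' @param rankings list of three `RankedList` objects over the same feature
#'   set (t-test, Wilcoxon, mRmR).
#' @param k list length per method (default 15).
#' @return object of class `ConsensusSelection`: `selected` (character(2)),
#'   `topk` (per-method lists), `intersection`, `fallback` (logical).
#' @export
consensusTop2 <- function(rankings, k = 15L) {
  topk <- lapply(rankings, function(r) utils::head(r$features, k))
  inter <- Reduce(intersect, topk)
  pool <- if (length(inter) >= 2L) inter else Reduce(union, topk)
  fallback <- length(inter) < 2L

  # mean rank across methods; features beyond a truncated list (mRmR
  # returns only k) get rank (length + 1)
  meanRank <- vapply(pool, function(fn) {
    mean(vapply(rankings, function(r) {
      i <- match(fn, r$features)
      if (is.na(i)) length(r$features) + 1 else i
    }, numeric(1)))
  }, numeric(1))
  ord <- order(meanRank, pool, method = "radix")
  sel <- pool[ord][1:2]
  structure(list(selected = sel, topk = topk, intersection = inter,
                 meanRank = meanRank[ord], fallback = fallback),
            class = "ConsensusSelection")
}

#' @export
print.ConsensusSelection <- function(x, ...) {
  cat(sprintf("ConsensusSelection: {%s}%s; |intersection| = %d\n",
              paste(x$selected, collapse = ", "),
              if (x$fallback) " [union fallback]" else "",
              length(x$intersection)))
  invisible(x)
}
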