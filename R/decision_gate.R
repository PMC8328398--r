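## Decision gate: the threshold table on classifier prediction scores and
## target-confidence threshold search.  Score orientation: higher score =
## rebounder; prediction rule is score >= threshold -> rebounder.

#' Per-threshold correct-classification percentages
#'
#' For each threshold, the percentage of rebounders with score >= threshold
#' and of non-rebounders with score < threshold, rounded to 2 decimals.  As
#' the threshold increases the rebounder percentage is non-increasing and
#' the non-rebounder percentage non-decreasing (the sensitivity/specificity
#' trade-off).
#'
#' @param scores prediction scores, one per eye.
#' @param labels `"rebounder"` / `"nonrebounder"` labels.
#' @param thresholds sorted numeric vector of thresholds; default is the
#'   midpoints of sorted unique scores plus the fixed grid 0.30-0.70 in
#'   steps of 0.02.
#' @return data.frame (threshold, pct_rebounders_correct,
#'   pct_nonrebounders_correct).
#' @export
thresholdTable <- function(scores, labels, thresholds = NULL) {
  reb <- labels == "rebounder"
  if (!any(reb) || all(reb)) stop("both classes must be present")
  if (is.null(thresholds))
    thresholds <- sort(unique(c(scoreMidpoints(scores),
                                seq(0.30, 0.70, by = 0.02))))
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  pr <- vapply(thresholds, function(t) 100 * mean(scores[reb] >= t),
               numeric(1))
  pn <- vapply(thresholds, function(t) 100 * mean(scores[!reb] < t),
               numeric(1))
  data.frame(threshold = thresholds,
             pct_rebounders_correct = round(pr, 2),
             pct_nonrebounders_correct = round(pn, 2))
}

scoreMidpoints <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) < 2L) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

#' Find a threshold achieving a target confidence for one group
#'
#' Scans the midpoints of sorted unique scores and returns the least
#' aggressive threshold at which the target group's correct-classification
#' percentage reaches `targetPct` — the smallest such midpoint when the
#' target group is the non-rebounders (whose correct percentage grows with
#' the threshold), the largest when it is the rebounders — together with
#' the other group's percentage there.  When no midpoint achieves the
#' target the result is marked unreachable.
#'
#' @inheritParams thresholdTable
#' @param targetGroup `"rebounder"` or `"nonrebounder"`.
#' @param targetPct target percentage in (0, 100].
#' @return list: `threshold`, `pct_rebounders_correct`,
#'   `pct_nonrebounders_correct`, `reachable`.
#' @export
findThreshold <- function(scores, labels, targetGroup = "nonrebounder",
                          targetPct = 90) {
  stopifnot(targetPct > 0, targetPct <= 100)
  targetGroup <- match.arg(targetGroup, c("rebounder", "nonrebounder"))
  grid <- scoreMidpoints(scores)
  tab <- thresholdTable(scores, labels, grid)
  achieved <- if (targetGroup == "rebounder")
    tab$pct_rebounders_correct >= targetPct
  else tab$pct_nonrebounders_correct >= targetPct
  if (!any(achieved))
    return(list(threshold = NA_real_, pct_rebounders_correct = NA_real_,
                pct_nonrebounders_correct = NA_real_, reachable = FALSE))
  i <- if (targetGroup == "rebounder") max(which(achieved))
       else which(achieved)[1]
  list(threshold = tab$threshold[i],
       pct_rebounders_correct = tab$pct_rebounders_correct[i],
       pct_nonrebounders_correct = tab$pct_nonrebounders_correct[i],
       reachable = TRUE)
}
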