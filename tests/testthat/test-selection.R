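plantedTable <- function(n = 30, p = 50, shift = 3, seed = 1) {
  set.seed(seed)
  labels <- rep(c("rebounder", "nonrebounder"), each = n / 2)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  m[labels == "rebounder", 1] <- m[labels == "rebounder", 1] + shift
  list(m = m, labels = labels)
}

test_that("a strongly planted column ranks first almost always", {
  for (fn in list(rankTtest, rankWilcoxon)) {
    hits <- vapply(1:100, function(s) {
      d <- plantedTable(seed = s)
      fn(d$m, d$labels)$features[1] == "f001"
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("under label permutation the planted column shows no rank bias", {
  d <- plantedTable(seed = 7)
  set.seed(99)
  ranks <- vapply(1:100, function(i) {
    perm <- sample(d$labels)
    match("f001", rankTtest(d$m, perm)$features)
  }, numeric(1))
  # uniform over 50 positions: chi-square on 5 equal bins
  bins <- table(cut(ranks, breaks = seq(0.5, 50.5, length.out = 6)))
  expect_gt(stats::chisq.test(bins)$p.value, 0.01)
})

test_that("duplicate columns take adjacent ranks with name tie-break", {
  d <- plantedTable(seed = 3, p = 10)
  m <- cbind(d$m, zdup = d$m[, "f001"])
  colnames(m)[1] <- "adup"
  r <- rankTtest(m, d$labels)
  i <- match(c("adup", "zdup"), r$features)
  expect_equal(diff(sort(i)), 1)
  expect_lt(i[1], i[2])  # lexicographic: adup before zdup
})

test_that("rank-sum ordering is invariant to monotone transforms", {
  d <- plantedTable(seed = 11)
  r1 <- rankWilcoxon(d$m, d$labels)
  r2 <- rankWilcoxon(d$m^3, d$labels)
  expect_identical(r1$features, r2$features)
})

test_that("small-sample rank-sum p-values match exhaustive enumeration", {
  set.seed(13)
  for (rep in 1:5) {
    x <- rnorm(3); y <- rnorm(3) + 1
    m <- matrix(c(x, y), 6, 1, dimnames = list(NULL, "f"))
    p <- rankWilcoxon(m, rep(c("rebounder", "nonrebounder"), each = 3))$scores
    expect_equal(unname(p), wilcoxExactEnum(x, y), tolerance = 1e-12)
  }
})

test_that("mRmR prefers complementary signal over duplicated signal", {
  # two identical informative columns and one independent informative column
  set.seed(21)
  n <- 60
  labels <- rep(c("rebounder", "nonrebounder"), each = n / 2)
  a <- rnorm(n) + 3 * (labels == "rebounder")   # duplicated, most relevant
  b <- rnorm(n) + 1.5 * (labels == "rebounder") # independent, weaker
  m <- cbind(dup1 = a, dup2 = a, indep = b)
  r <- rankMrmr(m, labels, k = 3)
  expect_true(r$features[1] %in% c("dup1", "dup2"))
  expect_equal(r$features[2], "indep")

  # single feature is trivially selected first
  r1 <- rankMrmr(m[, 1, drop = FALSE], labels, k = 1)
  expect_equal(r1$features, "dup1")
  expect_error(rankMrmr(m, labels, k = 5), "exceeds feature count")
})

test_that("label-independent features carry near-zero relevance", {
  rels <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 100
    labels <- rep(c("rebounder", "nonrebounder"), each = n / 2)
    m <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "noise"))
    bins <- octrad:::discretizeTertiles(m[, 1])
    # mutual information in bits from the 3 x 2 contingency table
    tab <- table(bins, labels) / n
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in 1:2) {
      pij <- tab[i, j]
      if (pij > 0)
        mi <- mi + pij * log2(pij / (sum(tab[i, ]) * sum(tab[, j])))
    }
    mi
  }, numeric(1))
  expect_lt(mean(rels), 0.05)
})

test_that("consensus selection intersects top lists and breaks ties by mean rank", {
  mk <- function(features) list(method = "x", features = features,
                                scores = seq_along(features))
  feats <- sprintf("g%02d", 1:20)
  same <- mk(feats)
  cs <- consensusTop2(list(same, same, same))
  expect_equal(cs$selected, c("g01", "g02"))
  expect_false(cs$fallback)

  # intersection {A,B,C} with mean ranks 2.0, 3.3, 7.7 -> {A,B}
  r1 <- mk(c("A", "B", "C", "D", "E"))
  r2 <- mk(c("A", "C", "B", "D", "E"))
  r3 <- mk(c("D", "E", "A", "B", "C"))
  # mean ranks: A (1+1+3)/3 = 1.67, B (2+3+4)/3 = 3, C (3+2+5)/3 = 3.33
  cs2 <- consensusTop2(list(r1, r2, r3), k = 5)
  expect_equal(cs2$selected, c("A", "B"))

  # empty intersection falls back to the union, flagged
  u1 <- mk(c("A", "B", "Z", "Y", "X"))
  u2 <- mk(c("C", "D", "Z", "Y", "X"))
  u3 <- mk(c("E", "F", "Z", "Y", "X"))
  cs3 <- consensusTop2(list(u1, u2, u3), k = 2)
  expect_true(cs3$fallback)
  expect_length(cs3$selected, 2L)
  expect_true(all(cs3$selected %in% c("A", "B", "C", "D", "E", "F")))
})
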