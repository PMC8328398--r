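test_that("PCA reduction exposes rank deficiency and preserves geometry", {
  set.seed(71)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  planar <- matrix(rnorm(40), 20, 2) %*% t(basis)  # exactly rank 2 in 10D
  red <- pcaReduce(planar, 9L)
  ev <- attr(red, "explainedVariance")
  expect_true(all(ev[3:9] < 1e-10))

  # all components = orthogonal transform: pairwise distances preserved
  full <- pcaReduce(planar, 10L)
  expect_equal(as.vector(dist(full)), as.vector(dist(planar)),
               tolerance = 1e-10)

  # isotropic cloud: roughly equal variance ratios on average
  ratios <- vapply(1:10, function(s) {
    set.seed(s)
    iso <- matrix(rnorm(500 * 5), 500, 5)
    evi <- attr(pcaReduce(iso, 5L), "explainedVariance")
    max(evi) / min(evi)
  }, numeric(1))
  expect_lt(mean(ratios), 1.5)
  iso <- matrix(rnorm(500 * 5), 500, 5)

  expect_error(pcaReduce(iso, 6L), "exceeds")
})

twoBlobs <- function(n = 20, sep = 10, seed = 81) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2) + sep, n, 2))
  labels <- rep(c("rebounder", "nonrebounder"), each = n)
  list(x = x, labels = labels)
}

test_that("well-separated blobs cluster purely with consistent bookkeeping", {
  d <- twoBlobs()
  rep <- hierarchicalCut(d$x, 2L, d$labels)
  expect_equal(sort(unname(diag(rep$composition[, c("rebounder", "nonrebounder")]))),
               c(100, 100))
  expect_equal(unname(rowSums(rep$composition)), c(100, 100))
  # class counts across clusters sum to cohort counts
  counts <- table(rep$assignments, d$labels)
  expect_equal(as.vector(colSums(counts)[levels(factor(d$labels))]),
               as.vector(table(factor(d$labels))))
  expect_equal(sum(counts), length(d$labels))

  # duplicates co-cluster
  dup <- rbind(d$x, d$x[1, , drop = FALSE])
  repD <- hierarchicalCut(dup, 2L, c(d$labels, d$labels[1]))
  expect_equal(repD$assignments[41], repD$assignments[1])

  # n = 2 -> one row per cluster
  rep2 <- hierarchicalCut(d$x[c(1, 40), ], 2L, d$labels[c(1, 40)])
  expect_equal(sort(rep2$assignments), c(1L, 2L))
})

test_that("the elbow criterion finds the planted number of blobs", {
  d2 <- twoBlobs(sep = 12, seed = 91)
  expect_equal(as.integer(elbowK(d2$x, 6L, seed = 1L)), 2L)

  set.seed(92)
  three <- rbind(matrix(rnorm(40), 20, 2),
                 cbind(rnorm(20) + 15, rnorm(20)),
                 cbind(rnorm(20), rnorm(20) + 15))
  expect_equal(as.integer(elbowK(three, 6L, seed = 1L)), 3L)

  # a single blob yields a valid k with a weak-elbow flag available
  set.seed(93)
  single <- matrix(rnorm(200), 100, 2)
  k <- elbowK(single, 6L, seed = 1L)
  expect_true(as.integer(k) >= 2L)
  expect_true(is.logical(attr(k, "weakElbow")))

  expect_warning(elbowK(d2$x[1:4, ], 6L, seed = 1L), "lowered")
})

test_that("K-means composition is order-invariant and respects planted structure", {
  d <- twoBlobs(sep = 8, seed = 95)
  rep <- kmeansComposition(d$x, 2L, d$labels, seed = 3L)
  expect_true(all(apply(rep$composition, 1, max) >= 80))

  perm <- sample(nrow(d$x))
  repP <- kmeansComposition(d$x[perm, ], 2L, d$labels[perm], seed = 3L)
  expect_equal(rep$composition, repP$composition)

  rep1 <- kmeansComposition(d$x, 1L, d$labels, seed = 3L)
  expect_equal(unname(rep1$classCapture["cluster1", ]), c(100, 100))
  expect_error(kmeansComposition(d$x[1:3, ], 5L, d$labels[1:3]), "exceeds")
})
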