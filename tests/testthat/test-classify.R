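test_that("AUC matches hand-counted concordant pairs", {
  lab <- c("rebounder", "rebounder", "nonrebounder", "nonrebounder")
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), lab), 1)
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2),
                   c("rebounder", "nonrebounder", "rebounder", "nonrebounder")),
               0.75)
  expect_equal(auc(rep(0.5, 6), rep(c("rebounder", "nonrebounder"), 3)), 0.5)
  expect_error(auc(1:3, rep("rebounder", 3)), "both classes")
})

test_that("AUC equals the exhaustive pair-count oracle on small inputs", {
  set.seed(19)
  for (n in 2:8) {
    for (rep in 1:10) {
      scores <- sample(seq(0.1, 0.9, by = 0.2), n, replace = TRUE)
      for (nPos in 1:(n - 1)) {
        lab <- rep("nonrebounder", n)
        lab[sample(n, nPos)] <- "rebounder"
        expect_equal(auc(scores, lab), aucPairs(scores, lab),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("confusion metrics follow the score >= threshold rule", {
  lab <- c("rebounder", "nonrebounder", "rebounder", "nonrebounder")
  sc <- c(0.9, 0.6, 0.4, 0.1)
  expect_equal(confusionMetrics(sc, lab, 0.5),
               c(ACC = 0.5, Sens = 0.5, Spec = 0.5))
  expect_equal(confusionMetrics(sc, lab, 0),
               c(ACC = 0.5, Sens = 1, Spec = 0))
  expect_equal(confusionMetrics(sc, lab, 1),
               c(ACC = 0.5, Sens = 0, Spec = 1))
})

test_that("the protocol recovers a clean two-feature signal and is reproducible", {
  set.seed(55)
  n <- 40
  labels <- rep(c("rebounder", "nonrebounder"), each = n / 2)
  m <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(sprintf("eye%02d", 1:n), sprintf("f%02d", 1:30)))
  m[labels == "rebounder", 1:2] <- m[labels == "rebounder", 1:2] + 3
  prot <- evalProtocol(nIterations = 10L, seed = 5L)
  res <- runProtocol(m, labels, prot)
  best <- res[[attr(res, "best")]]
  expect_gte(best@metrics["AUC", "mean"], 0.9)
  expect_true(all(cvSummary(res)$mean >= 0, cvSummary(res)$mean <= 1))
  expect_true(all(cvSummary(res)$sd >= 0))

  res2 <- runProtocol(m, labels, prot)
  expect_equal(cvSummary(res), cvSummary(res2), tolerance = 1e-12)

  aud <- attr(res, "selectionAudit")
  expect_equal(nrow(aud), 30L)  # 10 iterations x 3 folds
  expect_true(all(aud$selected1 %in% colnames(m)))
})

test_that("a feature informative only on the held-out rows is never exploited", {
  # no-leakage canary: selection and normalization see fold-train rows only,
  # so a column that encodes the label exclusively on the 20% held-out rows
  # must leave CV performance at chance
  set.seed(66)
  n <- 40
  labels <- rep(c("rebounder", "nonrebounder"), each = n / 2)
  m <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("eye%02d", 1:n), sprintf("f%02d", 1:20)))
  prot <- evalProtocol(nIterations = 10L, seed = 9L)
  f <- octrad:::asLabelFactor(labels)
  trainIdx <- octrad:::withRNG(prot@seed,
                               octrad:::stratifiedSplit(f, prot@trainFraction))
  testIdx <- setdiff(seq_len(n), trainIdx)
  m[, "f01"] <- rnorm(n)
  m[testIdx, "f01"] <- 10 * (labels[testIdx] == "rebounder")
  res <- runProtocol(m, labels, prot)
  for (r in res)
    expect_lt(r@metrics["AUC", "mean"], 0.72)
})

test_that("degenerate protocols are rejected", {
  labels <- rep(c("rebounder", "nonrebounder"), each = 3)
  m <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(paste0("e", 1:6), paste0("f", 1:4)))
  expect_error(runProtocol(m, labels, evalProtocol(nIterations = 2L)),
               "too few eyes per class")
})
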