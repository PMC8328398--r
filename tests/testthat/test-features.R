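test_that("aggregation statistics follow the stated definitions", {
  expect_equal(aggregateStats(1:5),
               c(Median = 3, Variance = 2, Skewness = 0, Kurtosis = 1.7))
  expect_equal(aggregateStats(rep(4, 10)),
               c(Median = 4, Variance = 0, Skewness = 0, Kurtosis = 0))
  one <- aggregateStats(7)
  expect_equal(one[["Median"]], 7)
  expect_true(all(is.nan(one[c("Variance", "Skewness", "Kurtosis")])))
  expect_true(all(is.nan(aggregateStats(numeric(0)))))
})

test_that("extraction emits exactly 962 named values per compartment", {
  spec <- tinySpec(nIrfPockets = c(1L, 1L), nSrfPockets = c(1L, 1L),
                   seed = 8L)
  eye <- generateCohort(spec)[[1]]
  cs <- deriveCompartments(eye@surfaces, eye@fluid, eyeId = eye@eyeId)
  fr <- suppressMessages(extractFeatures(eye, cs))
  expect_named(fr, c("IRF", "SRF", "RTC1", "RTC2"))
  for (nm in names(fr)) {
    expect_length(fr[[nm]], 962L)
    expect_true(all(startsWith(names(fr[[nm]]), paste0(nm, "/"))))
  }

  # determinism: identical eye -> bit-identical rows
  fr2 <- suppressMessages(extractFeatures(eye, cs))
  expect_identical(fr, fr2)
})

test_that("empty compartments yield missing rows, flagged but not dropped", {
  spec <- tinySpec(nIrfPockets = c(1L, 1L), nSrfPockets = c(0L, 0L),
                   seed = 8L)
  eye <- generateCohort(spec)[[1]]
  cs <- deriveCompartments(eye@surfaces, eye@fluid, eyeId = eye@eyeId)
  expect_message(fr <- extractFeatures(eye, cs), "SRF")
  expect_length(fr$SRF, 962L)
  expect_true(all(is.na(fr$SRF)))
  expect_false(anyNA(fr$RTC1))
})

test_that("aggregated features are invariant to joint translation of volume and mask", {
  set.seed(23)
  d <- c(14L, 20L, 20L)
  vol <- array(runif(prod(d), 0, 255), d)
  mask <- array(FALSE, d); mask[5:8, 8:11, 8:11] <- TRUE
  volT <- array(0, d); volT[3:14, , ] <- vol[1:12, , ]
  maskT <- array(FALSE, d); maskT[7:10, 8:11, 8:11] <- TRUE

  mf <- featureBankManifest()
  lw <- lawsMaps(vol, mf, maps = "E3S3S3")[[1]]@values
  lwT <- lawsMaps(volT, mf, maps = "E3S3S3")[[1]]@values
  expect_equal(aggregateStats(lw[mask]), aggregateStats(lwT[maskT]),
               tolerance = 1e-10)

  h <- octrad:::haralickStatMatrix(vol, mask, 5L, 32L)
  hT <- octrad:::haralickStatMatrix(volT, maskT, 5L, 32L)
  expect_equal(h, hT, tolerance = 1e-10)

  cg <- octrad:::collageStatMatrix(vol, mask, 5L, 16L)
  cgT <- octrad:::collageStatMatrix(volT, maskT, 5L, 16L)
  expect_equal(cg, cgT, tolerance = 1e-10)
})

test_that("fusion concatenates compartments with the documented column counts", {
  mkTab <- function(prefix, ids = paste0("eye", 1:3), p = 4) {
    m <- matrix(rnorm(length(ids) * p), length(ids), p,
                dimnames = list(ids, paste0(prefix, "/f", seq_len(p))))
    FeatureTable(m)
  }
  tabs <- list(IRF = mkTab("IRF"), SRF = mkTab("SRF"),
               RTC1 = mkTab("RTC1"), RTC2 = mkTab("RTC2"))
  expect_equal(ncol(fuseTables(tabs, "f")), 8L)
  expect_equal(ncol(fuseTables(tabs, "rtc")), 8L)
  expect_equal(ncol(fuseTables(tabs, "oct")), 16L)

  # per-compartment width 962 doubles and quadruples on fusion
  spec <- tinySpec(nIrfPockets = c(1L, 1L), nSrfPockets = c(1L, 1L), seed = 4L)
  eyes <- generateCohort(spec)[1:2]
  full <- suppressMessages(extractCohortFeatures(eyes))
  expect_equal(ncol(fuseTables(full, "f")), 1924L)
  expect_equal(ncol(fuseTables(full, "oct")), 3848L)

  # self-fusion under distinct prefixes doubles columns pairwise-equal
  self <- list(IRF = tabs$IRF, SRF = mkTab("SRF"),
               RTC1 = tabs$RTC1, RTC2 = tabs$RTC2)
  v <- featureValues(tabs$IRF)
  colnames(v) <- sub("IRF", "SRF", colnames(v))
  self$SRF <- FeatureTable(v)
  fused <- fuseTables(self, "f")
  expect_equal(ncol(fused), 8L)
  expect_equal(unname(featureValues(fused)[, 1:4]),
               unname(featureValues(fused)[, 5:8]))

  # eye mismatch errors list the symmetric difference
  bad <- tabs
  bad$SRF <- mkTab("SRF", ids = c("eye1", "eye2", "eyeX"))
  expect_error(fuseTables(bad, "f"), "eyeX")
})

test_that("z-normalization standardizes columns and flags constants", {
  m <- matrix(c(2, 4, 6, 5, 5, 5), 3, 2,
              dimnames = list(paste0("e", 1:3), c("a", "const")))
  zn <- znormalize(FeatureTable(m))
  v <- featureValues(zn)
  expect_equal(v[, "a"], c(e1 = -1, e2 = 0, e3 = 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_equal(unname(v[, "const"]), c(0, 0, 0))
  expect_equal(attr(zn, "constantColumns"), "const")

  # idempotence and the mean-0 / population-sd-1 invariant
  zn2 <- znormalize(zn)
  expect_equal(featureValues(zn2)[, "a"], v[, "a"], tolerance = 1e-12)
  expect_lt(abs(mean(v[, "a"])), 1e-9)
  expect_lt(abs(sqrt(mean((v[, "a"] - mean(v[, "a"]))^2)) - 1), 1e-9)
})
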