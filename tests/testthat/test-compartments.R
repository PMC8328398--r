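test_that("compartments tile the bands on a flat toy geometry", {
  surf <- flatSurfaces(1L, 4L, ilm = 2, ez = 5, rpe = 8)
  shape <- c(1L, 12L, 4L)
  cs <- deriveCompartments(surf, emptyFluid(shape), sliceWindow = c(1, 1))
  expect_equal(sum(compartmentMask(cs, "RTC1")), 12)  # 3 depths x 4 A-scans
  expect_equal(sum(compartmentMask(cs, "RTC2")), 12)
  expect_equal(sum(compartmentMask(cs, "IRF")), 0)

  # a 2-voxel IRF pocket is carved out of RTC1
  irf <- array(FALSE, shape); irf[1, 3:4, 2] <- TRUE
  cs2 <- deriveCompartments(surf, FluidMasks(irf, array(FALSE, shape)),
                            sliceWindow = c(1, 1))
  expect_equal(sum(compartmentMask(cs2, "RTC1")), 10)
  expect_equal(sum(compartmentMask(cs2, "IRF")), 2)
  expect_false(any(compartmentMask(cs2, "RTC1") & compartmentMask(cs2, "IRF")))
})

test_that("surface ordering violations cite the offending A-scan", {
  ilm <- matrix(5, 2, 3); ez <- matrix(8, 2, 3); rpe <- matrix(10, 2, 3)
  shape <- c(2L, 16L, 3L)
  good <- LayerSurfaces(ilm, ez, rpe)
  expect_s4_class(deriveCompartments(good, emptyFluid(shape)),
                  "CompartmentSet")
  ez[2, 3] <- 4  # EZ above ILM
  expect_error(LayerSurfaces(ilm, ez, rpe), "slice=2, ascan=3")
  bad <- good
  slot(bad, "ez", check = FALSE) <- ez  # bypass constructor validity
  expect_error(deriveCompartments(bad, emptyFluid(shape)),
               "slice=2, ascan=3")
})

test_that("slice window matches the 43-85-of-128 rule and scales proportionally", {
  expect_equal(selectSlices(128L, "tissue"), 43:85)
  expect_length(selectSlices(128L, "tissue"), 43L)
  expect_equal(selectSlices(64L, "tissue"), 22:43)
})

test_that("fluid mode drops empty slices and signals an all-empty window", {
  spec <- tinySpec(nIrfPockets = c(1L, 1L), nSrfPockets = c(0L, 0L),
                   seed = 2L)
  eyes <- generateCohort(spec)
  eye <- eyes[[1]]
  win <- selectSlices(dim(eye@volume@data)[1], "tissue")
  fl <- selectSlices(eye, "fluid")
  expect_true(all(fl %in% win))
  expect_true(all(vapply(fl, function(s)
    any(eye@fluid@irf[s, , ] | eye@fluid@srf[s, , ]), logical(1))))

  dry <- eye
  dry@fluid <- emptyFluid(dim(eye@volume@data))
  expect_error(selectSlices(dry, "fluid"), "no fluid voxels in window",
               class = "octradNoFluidError")
})

test_that("compartment partition property holds on random synthetic eyes", {
  spec <- cohortSpec(nRebounder = 50L, nNonrebounder = 50L,
                     volumeShape = c(6L, 20L, 10L), seed = 31L)
  eyes <- generateCohort(spec)
  for (eye in eyes) {
    cs <- deriveCompartments(eye@surfaces, eye@fluid, eyeId = eye@eyeId)
    w <- cs@sliceWindow
    bands <- octrad:::bandMasks(eye@surfaces, dim(eye@volume@data))
    inWin <- array(FALSE, dim(eye@volume@data))
    inWin[w[1]:w[2], , ] <- TRUE
    expect_identical(compartmentMask(cs, "RTC1") | compartmentMask(cs, "IRF"),
                     bands$inner & inWin)
    expect_identical(compartmentMask(cs, "RTC2") | compartmentMask(cs, "SRF"),
                     bands$outer & inWin)
    tot <- compartmentMask(cs, "IRF") + compartmentMask(cs, "SRF") +
           compartmentMask(cs, "RTC1") + compartmentMask(cs, "RTC2")
    expect_true(all(tot <= 1))
  }
})
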