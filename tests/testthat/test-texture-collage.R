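test_that("a pure intensity ramp yields a single constant orientation", {
  d <- c(6L, 12L, 12L)
  dep <- array(rep(seq_len(d[2]) - 1, each = d[1]), dim = d)
  mask <- array(FALSE, d); mask[2:5, 3:10, 3:10] <- TRUE
  expect_silent(maps <- collageMaps(dep * 2, mask))
  # single orientation bin -> zero co-occurrence entropy on both channels
  for (ch in c("Entropy_InPlane", "Entropy_ThroughPlane"))
    expect_true(all(abs(maps[[ch]]@values[mask]) < 1e-12))
  expect_true(all(abs(maps$Energy_InPlane@values[mask] - 1) < 1e-12))
})

test_that("dominant orientations equal the independent plane-fit oracle", {
  # exactly linear volume: the gradient is the plane normal everywhere
  d <- c(10L, 10L, 10L)
  co <- c(2.0, 0.7, -1.1)  # depth, ascan, slice coefficients
  dep <- array(rep(seq_len(d[2]) - 1, each = d[1]), dim = d)
  asc <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), dim = d)
  slc <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), dim = d)
  vol <- co[1] * dep + co[2] * asc + co[3] * slc
  mask <- array(TRUE, d)
  cd <- c(-0.5, 0, 0.5)
  g1 <- octrad:::cpp_sepconv3(vol, d, cd, 1, 1)
  g2 <- octrad:::cpp_sepconv3(vol, d, 1, cd, 1)
  g3 <- octrad:::cpp_sepconv3(vol, d, 1, 1, cd)
  ang <- octrad:::cpp_orientation_angles(g1, g2, g3, d, 5L, mask)

  # oracle: independent least-squares plane fit over each voxel's 5^3
  # neighbourhood, angles from the fitted normal
  for (vx in list(c(4, 4, 4), c(5, 6, 7), c(7, 5, 4))) {
    nb <- expand.grid(s = vx[1] + (-2:2), dd = vx[2] + (-2:2),
                      a = vx[3] + (-2:2))
    y <- vol[cbind(nb$s, nb$dd, nb$a)]
    fit <- stats::lm(y ~ nb$dd + nb$a + nb$s)
    v <- unname(stats::coef(fit)[2:4])  # (depth, ascan, slice) gradient
    v <- v / sqrt(sum(v^2))
    if (v[1] < 0) v <- -v
    thetaWant <- atan2(v[2], v[1]) %% pi
    phiWant <- atan2(v[3], sqrt(v[1]^2 + v[2]^2))
    expect_equal(ang$theta[vx[1], vx[2], vx[3]], thetaWant, tolerance = 1e-8)
    expect_equal(ang$phi[vx[1], vx[2], vx[3]], phiWant, tolerance = 1e-8)
  }
})

test_that("rotating a ramp within the B-scan plane shifts orientation a quarter turn", {
  d <- c(5L, 10L, 10L)
  dep <- array(rep(seq_len(d[2]) - 1, each = d[1]), dim = d)
  asc <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), dim = d)
  mask <- array(FALSE, d); mask[2:4, 3:8, 3:8] <- TRUE
  mDep <- collageMaps(3 * dep, mask)
  mAsc <- collageMaps(3 * asc, mask)
  # in-plane co-occurrence of a constant field: descriptors unchanged
  for (stat in c("Entropy_InPlane", "Energy_InPlane", "Contrast_InPlane"))
    expect_equal(mDep[[stat]]@values[mask], mAsc[[stat]]@values[mask],
                 tolerance = 1e-12)
  # ...but the orientation value itself moves by pi/2
  cd <- c(-0.5, 0, 0.5)
  angOf <- function(vol) {
    g1 <- octrad:::cpp_sepconv3(vol, d, cd, 1, 1)
    g2 <- octrad:::cpp_sepconv3(vol, d, 1, cd, 1)
    g3 <- octrad:::cpp_sepconv3(vol, d, 1, 1, cd)
    octrad:::cpp_orientation_angles(g1, g2, g3, d, 5L, mask)$theta[3, 5, 5]
  }
  expect_equal(abs(angOf(3 * asc) - angOf(3 * dep)), pi / 2,
               tolerance = 1e-8)
})

test_that("zero-gradient voxels are counted and assigned bin zero", {
  d <- c(5L, 8L, 8L)
  mask <- array(TRUE, d)
  expect_message(collageMaps(array(1, d), mask), "zero-gradient")
})
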