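## Synthetic OCT cohort generator: layered geometry, multiplicative gamma
## speckle, ellipsoidal IRF / lens-shaped SRF pockets, and a seeded
## class-dependent high-frequency texture effect inside IRF.

# smooth low-frequency random surface on an nS x nA grid, zero mean,
# approximately unit amplitude, from a small cosine/sine basis
smoothField <- function(nS, nA, nModes = 3L) {
  s <- (seq_len(nS) - 0.5) / nS
  a <- (seq_len(nA) - 0.5) / nA
  f <- matrix(0, nS, nA)
  for (ks in 0:nModes) for (ka in 0:nModes) {
    if (ks == 0 && ka == 0) next
    amp <- stats::rnorm(2) / (1 + ks + ka)
    f <- f + amp[1] * outer(cos(pi * ks * s), cos(pi * ka * a)) +
             amp[2] * outer(sin(pi * ks * s), sin(pi * ka * a))
  }
  f
}

#' Generate smooth retinal layer surfaces
#'
#' Produces three smooth depth fields (ILM, EZ, RPE) with a foveal
#' depression (local thinning of the inner retina) centred on the central
#' A-scan of the central slice.  Ordering ILM < EZ <= RPE is enforced
#' everywhere with at least one voxel between ILM and EZ.
#'
#' @param volumeShape integer(3): (n_slices, depth, n_ascans); depth >= 16.
#' @param seed integer seed.
#' @param surfaceSd amplitude (voxels) of the smooth random undulation.
#' @param pitDepth foveal depression depth as a fraction of the inner band
#'   thickness.  `surfaceSd = 0, pitDepth = 0` gives flat surfaces at the
#'   configured base depths.
#' @return A [LayerSurfaces-class] object.
#' @export
makeSurfaces <- function(volumeShape, seed = 1L, surfaceSd = 2,
                         pitDepth = 0.45) {
  volumeShape <- as.integer(volumeShape)
  if (length(volumeShape) != 3L || any(volumeShape < 1L))
    stop("volumeShape must be 3 positive integers")
  nS <- volumeShape[1]; D <- volumeShape[2]; nA <- volumeShape[3]
  if (D < 16L) stop("volumeShape: depth must be >= 16 so three layers fit")

  withRNG(seed, {
    ilm0 <- 0.22 * D; ez0 <- 0.55 * D; rpe0 <- 0.78 * D
    ilm <- ilm0 + surfaceSd * smoothField(nS, nA)
    ez  <- ez0  + surfaceSd * smoothField(nS, nA)
    rpe <- rpe0 + surfaceSd * smoothField(nS, nA)

    # foveal depression: ILM dips toward EZ near the volume centre
    s <- seq_len(nS); a <- seq_len(nA)
    pit <- outer(exp(-((s - (nS + 1) / 2)^2) / (2 * (nS / 8)^2)),
                 exp(-((a - (nA + 1) / 2)^2) / (2 * (nA / 8)^2)))
    ilm <- ilm + pitDepth * (ez0 - ilm0) * pit

    # enforce ordering with margins; clamp into the volume
    ilm <- pmin(pmax(ilm, 1), D - 8)
    ez <- pmax(ez, ilm + 2)
    rpe <- pmax(rpe, ez)
    ez <- pmin(ez, D - 4)
    rpe <- pmin(rpe, D - 2)
    ilm <- pmin(ilm, ez - 1)
    LayerSurfaces(ilm = ilm, ez = ez, rpe = rpe)
  })
}

#' Plant fluid pockets between the retinal layer surfaces
#'
#' IRF pockets are discrete ellipsoids clipped to the ILM->EZ band; SRF
#' pockets are lens-shaped caps hanging below the EZ surface, clipped to the
#' EZ->RPE band.  Pockets never escape their band, so IRF and SRF are
#' disjoint by construction.
#'
#' @param surfaces a [LayerSurfaces-class].
#' @param spec a [CohortSpec-class] (pocket count ranges, volume shape).
#' @param seed integer seed.
#' @return A [FluidMasks-class] object.
#' @export
plantFluid <- function(surfaces, spec, seed = 1L) {
  shape <- spec@volumeShape
  nS <- shape[1]; D <- shape[2]; nA <- shape[3]
  irf <- array(FALSE, dim = shape)
  srf <- array(FALSE, dim = shape)
  dep <- seq_len(D) - 1  # 0-based depth coordinate of voxel centres

  withRNG(seed, {
    nI <- sampleRange(spec@nIrfPockets)
    nSr <- sampleRange(spec@nSrfPockets)

    # pockets concentrate in the central macula (the cohort this emulates is
    # foveal-involving edema), within the central half of slices and A-scans
    centralS <- function() stats::runif(1, 0.25 * nS + 0.5, 0.75 * nS + 0.5)
    centralA <- function() stats::runif(1, 0.25 * nA + 0.5, 0.75 * nA + 0.5)

    for (k in seq_len(nI)) {
      cs <- centralS(); ca <- centralA()
      si <- pmin(pmax(round(cs), 1), nS); ai <- pmin(pmax(round(ca), 1), nA)
      band <- surfaces@ez[si, ai] - surfaces@ilm[si, ai]
      cd <- surfaces@ilm[si, ai] + stats::runif(1, 0.3, 0.7) * band
      rd <- stats::runif(1, 1.5, max(2, band / 2))
      rs <- stats::runif(1, 1.5, max(2, nS / 10))
      ra <- stats::runif(1, 1.5, max(2, nA / 10))
      irf <- irf | ellipsoidMask(shape, c(cs, cd, ca), c(rs, rd, ra))
    }
    for (k in seq_len(nSr)) {
      cs <- centralS(); ca <- centralA()
      rs <- stats::runif(1, 2, max(3, nS / 8))
      ra <- stats::runif(1, 2, max(3, nA / 8))
      h <- stats::runif(1, 2, 6)  # cap height in voxels
      # lens: depth in [ez, ez + h * (1 - radial^2)) below the EZ surface
      for (si in max(1, floor(cs - rs)):min(nS, ceiling(cs + rs)))
        for (ai in max(1, floor(ca - ra)):min(nA, ceiling(ca + ra))) {
          r2 <- ((si - cs) / rs)^2 + ((ai - ca) / ra)^2
          if (r2 >= 1) next
          ezv <- surfaces@ez[si, ai]
          top <- ezv + h * (1 - r2)
          sel <- dep >= ezv & dep < top
          srf[si, sel, ai] <- TRUE
        }
    }
    # clip to bands (half-open [ILM, EZ) and [EZ, RPE))
    bands <- bandMasks(surfaces, shape)
    FluidMasks(irf = irf & bands$inner, srf = srf & bands$outer)
  })
}

# discrete ellipsoid: voxel (s, d, a) included when the normalized squared
# distance of its centre from `centre` is < 1; centre/radii in (slice,
# depth, ascan) with slice/ascan 1-based and depth 0-based
ellipsoidMask <- function(shape, centre, radii) {
  nS <- shape[1]; D <- shape[2]; nA <- shape[3]
  m <- array(FALSE, dim = shape)
  for (si in max(1, floor(centre[1] - radii[1])):min(nS, ceiling(centre[1] + radii[1]))) {
    ds2 <- ((si - centre[1]) / radii[1])^2
    if (ds2 >= 1) next
    for (ai in max(1, floor(centre[3] - radii[3])):min(nA, ceiling(centre[3] + radii[3]))) {
      da2 <- ((ai - centre[3]) / radii[3])^2
      if (ds2 + da2 >= 1) next
      dep <- seq_len(D) - 1
      sel <- ds2 + da2 + ((dep - centre[2]) / radii[2])^2 < 1
      m[si, sel, ai] <- TRUE
    }
  }
  m
}

# logical band masks [ILM, EZ) ("inner") and [EZ, RPE) ("outer")
bandMasks <- function(surfaces, shape) {
  nS <- shape[1]; D <- shape[2]; nA <- shape[3]
  dep <- array(rep(seq_len(D) - 1, each = nS), dim = shape)
  ilmA <- aperm(array(surfaces@ilm, dim = c(nS, nA, D)), c(1, 3, 2))
  ezA  <- aperm(array(surfaces@ez,  dim = c(nS, nA, D)), c(1, 3, 2))
  rpeA <- aperm(array(surfaces@rpe, dim = c(nS, nA, D)), c(1, 3, 2))
  list(inner = dep >= ilmA & dep < ezA,
       outer = dep >= ezA & dep < rpeA)
}

#' Render one synthetic OCT eye
#'
#' Multiplicative gamma speckle (unit mean, shape `spec@speckleShape`) over
#' piecewise-constant band reflectivities: vitreous dark, ILM->EZ mid,
#' EZ->RPE bright, below-RPE dim.  Fluid voxels are attenuated
#' (hyporeflective).  For rebounder eyes a zero-mean spot-scale
#' high-frequency texture component with amplitude proportional to
#' `spec@effectSize` is added inside the IRF mask; the component is drawn for
#' every eye and scaled by zero for non-rebounders, so at `effectSize = 0`
#' the classes are exchangeable bit-for-bit.
#'
#' @param surfaces a [LayerSurfaces-class].
#' @param fluid a [FluidMasks-class].
#' @param label `"rebounder"` or `"nonrebounder"`.
#' @param spec a [CohortSpec-class].
#' @param seed integer seed.
#' @return An [OctVolume-class]; intensities on a nominal 8-bit [0, 255]
#'   scale (stored as doubles).
#' @export
renderEye <- function(surfaces, fluid, label, spec, seed = 1L) {
  shape <- spec@volumeShape
  bands <- bandMasks(surfaces, shape)
  base <- array(25, dim = shape)               # vitreous
  base[bands$inner] <- 110
  base[bands$outer] <- 180
  dep <- array(rep(seq_len(shape[2]) - 1, each = shape[1]), dim = shape)
  rpeA <- aperm(array(surfaces@rpe, dim = c(shape[1], shape[3], shape[2])),
                c(1, 3, 2))
  base[dep >= rpeA] <- 60                      # choroid
  base[fluid@irf | fluid@srf] <- base[fluid@irf | fluid@srf] * 0.35

  withRNG(seed, {
    k <- spec@speckleShape
    speckle <- array(stats::rgamma(prod(shape), shape = k, rate = k),
                     dim = shape)
    vol <- base * speckle

    # spot-scale class effect inside IRF (S3 x S3 x S3 filtered white
    # noise).  effectSize is calibrated in units of the speckle-driven
    # intensity sd inside fluid, so effectSize = 1 plants spot texture as
    # strong as the speckle background.
    w <- array(stats::rnorm(prod(shape)), dim = shape)
    s3 <- c(-1, 2, -1)
    hf <- cpp_sepconv3(w, dim(w), s3, s3, s3)
    hf <- hf / sqrt(sum(s3^2)^3)               # unit variance again
    fluidSd <- 110 * 0.35 / sqrt(k)            # speckle sd at fluid reflectivity
    amp <- if (identical(label, "rebounder")) spec@effectSize * fluidSd else 0
    vol[fluid@irf] <- vol[fluid@irf] + amp * hf[fluid@irf]

    vol <- pmin(pmax(vol, 0), 255)
    OctVolume(vol, spacing = spec@voxelSpacing)
  })
}

#' Generate a labeled synthetic OCT cohort
#'
#' Returns `nRebounder + nNonrebounder` eyes.  Per-eye seeds are derived
#' deterministically from `spec@seed`, so regeneration with the same spec is
#' bit-for-bit identical, eye by eye.
#'
#' @param spec a [CohortSpec-class].
#' @return list of [SyntheticEye-class] objects.
#' @examples
#' eyes <- generateCohort(cohortSpec(volumeShape = c(8, 24, 8),
#'                                   nRebounder = 1, nNonrebounder = 1))
#' table(vapply(eyes, eyeLabel, character(1)))
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nRebounder + spec@nNonrebounder
  labels <- c(rep("rebounder", spec@nRebounder),
              rep("nonrebounder", spec@nNonrebounder))
  eyeSeeds <- withRNG(spec@seed, sample.int(.Machine$integer.max - 3L, n))
  lapply(seq_len(n), function(i) {
    sd0 <- eyeSeeds[i]
    surfaces <- makeSurfaces(spec@volumeShape, seed = sd0)
    fluid <- plantFluid(surfaces, spec, seed = sd0 + 1L)
    volume <- renderEye(surfaces, fluid, labels[i], spec, seed = sd0 + 2L)
    new("SyntheticEye", volume = volume, surfaces = surfaces, fluid = fluid,
        label = labels[i], eyeId = sprintf("eye%03d", i), seed = sd0)
  })
}

# run expr under a temporary RNG state seeded with `seed`
withRNG <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

sampleRange <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
}
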