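## Per-voxel 3D texture maps: Laws energy, slice-wise Gabor magnitude,
## sliding-window GLCM Haralick statistics, and CoLlAGe dominant-gradient-
## orientation co-occurrence statistics.  Boundary policy: reflect padding
## for convolutions; per-voxel windows clipped to the mask for co-occurrence.

#' VoxelFeatureMap: one per-voxel texture response volume
#'
#' @slot values 3D numeric array of responses (NA outside the domain of
#'   validity for mask-restricted families).
#' @slot descriptor map name, e.g. `"E3S3S3"`.
#' @slot family descriptor family.
#' @export
setClass("VoxelFeatureMap",
  representation(values = "array", descriptor = "character",
                 family = "character"))

setMethod("show", "VoxelFeatureMap", function(object) {
  cat(sprintf("VoxelFeatureMap %s (%s), %s grid, %d finite voxels\n",
              object@descriptor, object@family,
              paste(dim(object@values), collapse = "x"),
              sum(is.finite(object@values))))
})

GLCM_OFFSETS <- local({
  # the 13 unique nearest-neighbour 3D direction classes
  m <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
             c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
             c(1, 1, 0), c(1, -1, 0),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
})

# ---- Laws energy -----------------------------------------------------------

#' Laws texture energy maps
#'
#' For each ordered kernel triplet `k1 k2 k3` the volume is convolved
#' separably with `k1` along depth, `k2` along A-scan and `k3` along slice
#' (reflect boundary), and the local energy is the windowed mean absolute
#' response.  Names follow the axis-order convention (e.g. `E3S3S3`).
#'
#' @param volume an [OctVolume-class] or 3D array.
#' @param manifest a [FeatureBankManifest-class]; its Laws triplet grid and
#'   energy window are used.
#' @param maps optional character vector of triplet names to compute
#'   (default: every triplet referenced by the manifest descriptors).
#' @param energy compute the windowed mean absolute response (default);
#'   `FALSE` returns the raw convolution response.
#' @return named list of [VoxelFeatureMap-class] objects.
#' @export
lawsMaps <- function(volume, manifest = featureBankManifest(), maps = NULL,
                     energy = TRUE) {
  arr <- if (is(volume, "OctVolume")) volume@data else volume
  if (any(dim(arr) < 3L)) stop("volume smaller than kernel support")
  if (is.null(maps))
    maps <- unique(manifest@descriptors$map[
      manifest@descriptors$family == "Laws"])
  w <- manifest@params$laws$energyWindow
  out <- lapply(maps, function(nm) {
    ks <- lawsTripletKernels(nm)
    r <- cpp_sepconv3(arr, dim(arr), ks[[1]], ks[[2]], ks[[3]])
    if (energy) r <- cpp_boxmean3(abs(r), dim(arr), w)
    new("VoxelFeatureMap", values = r, descriptor = nm, family = "Laws")
  })
  names(out) <- maps
  out
}

lawsTripletKernels <- function(name) {
  parts <- regmatches(name, gregexpr("[LESRW][35]", name))[[1]]
  if (length(parts) != 3L) stop("bad Laws triplet name: ", name)
  lapply(parts, function(p) LAWS_KERNELS[[p]])
}

# ---- Gabor -----------------------------------------------------------------

gaborKernel2d <- function(wavelength, orientationDeg, bandwidth,
                          maxHalf = Inf) {
  if (wavelength < 2) stop("Gabor wavelength must be >= 2 voxels (Nyquist)")
  sigma <- bandwidth * wavelength
  h <- max(3L, as.integer(ceiling(2.5 * sigma)))
  h <- min(h, as.integer(maxHalf))  # envelope truncated on small volumes
  if (h < 1L) stop("volume slices too small for the Gabor kernel support")
  x <- seq(-h, h)
  th <- orientationDeg * pi / 180
  X <- outer(x, rep(1, length(x)))   # rows: depth axis
  Y <- outer(rep(1, length(x)), x)   # cols: A-scan axis
  Xr <- X * cos(th) + Y * sin(th)
  Yr <- -X * sin(th) + Y * cos(th)
  env <- exp(-(Xr^2 + Yr^2) / (2 * sigma^2))
  g <- env * exp(2i * pi * Xr / wavelength)
  # DC correction: remove the envelope-projected mean so constants map to 0
  g - env * (sum(g) / sum(env))
}

#' Gabor magnitude maps
#'
#' A bank of 2D complex Gabor filters (DC-corrected, unit gamma) is applied
#' slice-wise within the B-scan (depth x A-scan) plane by FFT convolution
#' with reflect padding; the per-voxel response is the complex magnitude.
#' The bank covers the manifest's orientation x wavelength x bandwidth grid
#' (`sigma = bandwidth * wavelength`).
#'
#' @inheritParams lawsMaps
#' @return named list of [VoxelFeatureMap-class] objects.
#' @export
gaborMaps <- function(volume, manifest = featureBankManifest(), maps = NULL) {
  arr <- if (is(volume, "OctVolume")) volume@data else volume
  d <- dim(arr)
  grid <- manifest@params$gabor$grid
  gNames <- sprintf("o%03.0f_w%g_b%g", grid$orientation * 10, grid$wavelength,
                    grid$bandwidth)
  if (is.null(maps))
    maps <- unique(manifest@descriptors$map[
      manifest@descriptors$family == "Gabor"])
  sel <- match(maps, gNames)
  if (anyNA(sel)) stop("unknown Gabor map name(s): ",
                       paste(maps[is.na(sel)], collapse = ", "))

  maxHalf <- min(d[2], d[3]) - 1L
  kernels <- lapply(sel, function(i)
    gaborKernel2d(grid$wavelength[i], grid$orientation[i], grid$bandwidth[i],
                  maxHalf = maxHalf))
  hs <- vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1))
  h <- max(hs)
  P1 <- d[2] + 2L * h; P2 <- d[3] + 2L * h

  kpads <- lapply(kernels, function(k) {
    hk <- (nrow(k) - 1L) %/% 2L
    kp <- matrix(0 + 0i, P1, P2)
    kp[((seq(-hk, hk)) %% P1) + 1L, ((seq(-hk, hk)) %% P2) + 1L] <- k
    stats::fft(kp)
  })

  outs <- lapply(seq_along(maps), function(i)
    array(NA_real_, dim = d))
  ri <- c(rev(seq_len(h)), seq_len(d[2]), seq(d[2], d[2] - h + 1))
  ci <- c(rev(seq_len(h)), seq_len(d[3]), seq(d[3], d[3] - h + 1))
  for (s in seq_len(d[1])) {
    img <- arr[s, , , drop = TRUE]
    pad <- img[ri, ci, drop = FALSE]
    padF <- stats::fft(pad)
    for (i in seq_along(maps)) {
      resp <- stats::fft(padF * kpads[[i]], inverse = TRUE) / (P1 * P2)
      outs[[i]][s, , ] <- Mod(resp[h + seq_len(d[2]), h + seq_len(d[3])])
    }
  }
  out <- lapply(seq_along(maps), function(i)
    new("VoxelFeatureMap", values = outs[[i]], descriptor = maps[i],
        family = "Gabor"))
  names(out) <- maps
  out
}

# ---- Haralick --------------------------------------------------------------

quantizeLevels <- function(arr, mask, nLevels) {
  lev <- array(0L, dim = dim(arr))
  v <- arr[mask]
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    q <- floor((arr - lo) / (hi - lo) * nLevels)
    lev[] <- as.integer(pmin(pmax(q, 0), nLevels - 1L))
  }
  lev
}

#' Per-voxel Haralick statistic maps
#'
#' Gray levels are quantized (min-max within the mask, `nLevels` levels);
#' for every masked voxel a symmetric gray-level co-occurrence matrix is
#' accumulated over the sliding cubic window (clipped to the mask) across
#' the 13 unique 3D direction classes, and the 13 classical Haralick
#' statistics are computed from it.
#'
#' @param volume an [OctVolume-class] or 3D array.
#' @param mask logical 3D array; maps are NA outside it.
#' @param manifest a [FeatureBankManifest-class] (window size, levels).
#' @return named list of 13 [VoxelFeatureMap-class] objects.
#' @export
haralickMaps <- function(volume, mask, manifest = featureBankManifest()) {
  arr <- if (is(volume, "OctVolume")) volume@data else volume
  stats <- haralickStatMatrix(arr, mask,
                              manifest@params$haralick$windowSize,
                              manifest@params$haralick$nLevels)
  idx <- which(mask)
  out <- lapply(seq_along(HARALICK_STATS), function(j) {
    m <- array(NA_real_, dim = dim(arr))
    m[idx] <- stats[, j]
    new("VoxelFeatureMap", values = m, descriptor = HARALICK_STATS[j],
        family = "Haralick")
  })
  names(out) <- HARALICK_STATS
  out
}

# masked-voxel x 13 matrix of Haralick statistics (rows in which(mask) order)
haralickStatMatrix <- function(arr, mask, windowSize, nLevels) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  lev <- quantizeLevels(arr, mask, nLevels)
  m <- cpp_glcm_stats(lev, dim(arr), mask, idx - 1L, nLevels,
                      as.integer(windowSize), GLCM_OFFSETS)
  colnames(m) <- HARALICK_STATS
  m
}

# ---- CoLlAGe ---------------------------------------------------------------

#' CoLlAGe orientation co-occurrence maps
#'
#' Central-difference intensity gradients are pooled into a windowed
#' structure tensor per masked voxel; its dominant eigenvector yields an
#' in-plane angle (within the B-scan plane, range `[0, pi)`) and a
#' through-plane angle (range `[-pi/2, pi/2]`).  Angles are quantized into
#' `nBins` bins and the 13 Haralick statistics are computed on the per-voxel
#' angle co-occurrence matrix of each channel (13 x 2 = 26 maps).
#' Zero-gradient voxels have undefined orientation; they are assigned bin 0
#' and their count is reported in a message.
#'
#' @inheritParams haralickMaps
#' @return named list of 26 [VoxelFeatureMap-class] objects with names
#'   `"<Stat>_InPlane"` and `"<Stat>_ThroughPlane"`.
#' @export
collageMaps <- function(volume, mask, manifest = featureBankManifest()) {
  arr <- if (is(volume, "OctVolume")) volume@data else volume
  stats <- collageStatMatrix(arr, mask,
                             manifest@params$collage$windowSize,
                             manifest@params$collage$nBins)
  idx <- which(mask)
  out <- lapply(seq_len(ncol(stats)), function(j) {
    m <- array(NA_real_, dim = dim(arr))
    m[idx] <- stats[, j]
    new("VoxelFeatureMap", values = m, descriptor = colnames(stats)[j],
        family = "CoLlAGe")
  })
  names(out) <- colnames(stats)
  out
}

# masked-voxel x 26 matrix of CoLlAGe statistics
collageStatMatrix <- function(arr, mask, windowSize, nBins) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  d <- dim(arr)
  cd <- c(-0.5, 0, 0.5)
  g1 <- cpp_sepconv3(arr, d, cd, 1, 1)       # d/d depth
  g2 <- cpp_sepconv3(arr, d, 1, cd, 1)       # d/d A-scan
  g3 <- cpp_sepconv3(arr, d, 1, 1, cd)       # d/d slice
  ang <- cpp_orientation_angles(g1, g2, g3, d, as.integer(windowSize), mask)
  if (ang$zeroCount > 0)
    message("collageMaps: ", ang$zeroCount,
            " zero-gradient voxels assigned orientation bin 0")
  binTheta <- array(pmin(as.integer(floor(ang$theta / pi * nBins)),
                         nBins - 1L), dim = d)
  binPhi <- array(pmin(as.integer(floor((ang$phi + pi / 2) / pi * nBins)),
                       nBins - 1L), dim = d)
  inPlane <- cpp_glcm_stats(binTheta, d, mask, idx - 1L, nBins,
                            as.integer(windowSize), GLCM_OFFSETS)
  through <- cpp_glcm_stats(binPhi, d, mask, idx - 1L, nBins,
                            as.integer(windowSize), GLCM_OFFSETS)
  m <- cbind(inPlane, through)
  colnames(m) <- c(paste0(HARALICK_STATS, "_InPlane"),
                   paste0(HARALICK_STATS, "_ThroughPlane"))
  m
}
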