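#' @useDynLib octrad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Axis convention used throughout: axis 1 = B-scan slice, axis 2 = depth
## (increasing away from the vitreous), axis 3 = A-scan.  Depth intervals are
## 0-based half-open internally; user-facing slice indices are 1-based.

#' OctVolume: a 3D grayscale OCT cube
#'
#' A volumetric OCT scan stored as a 3D numeric array with per-axis voxel
#' spacing.  Array axes are (slice, depth, A-scan).
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), micrometers per voxel along (slice, depth, A-scan).
#' @export
setClass("OctVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("volume data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive finite numbers")
    TRUE
  })

#' OctVolume constructor
#'
#' @param data 3D numeric array (slice, depth, A-scan).
#' @param spacing numeric(3) voxel spacing in micrometers; defaults to 1.
#' @return An [OctVolume-class] object.
#' @export
OctVolume <- function(data, spacing = c(1, 1, 1)) {
  new("OctVolume", data = data, spacing = as.numeric(spacing))
}

#' LayerSurfaces: per-A-scan retinal layer boundary depths
#'
#' Depth (voxel index along axis 2, 0-based fractional allowed) of the inner
#' limiting membrane (ILM), ellipsoid zone (EZ) and retinal pigment
#' epithelium (RPE) at every (slice, A-scan) position.  The retina satisfies
#' ILM < EZ <= RPE everywhere.
#'
#' @slot ilm,ez,rpe numeric matrices (n_slices x n_ascans) of depths.
#' @export
setClass("LayerSurfaces",
  representation(ilm = "matrix", ez = "matrix", rpe = "matrix"),
  validity = function(object) {
    d <- dim(object@ilm)
    if (!identical(d, dim(object@ez)) || !identical(d, dim(object@rpe)))
      return("ilm, ez, rpe must share dimensions")
    bad <- which(!(object@ilm < object@ez & object@ez <= object@rpe),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L)
      return(sprintf(
        "layer ordering ILM < EZ <= RPE violated at (slice=%d, ascan=%d)",
        bad[1, 1], bad[1, 2]))
    TRUE
  })

#' LayerSurfaces constructor
#' @param ilm,ez,rpe numeric matrices (n_slices x n_ascans) of boundary depths.
#' @return A [LayerSurfaces-class] object.
#' @export
LayerSurfaces <- function(ilm, ez, rpe) {
  new("LayerSurfaces", ilm = ilm, ez = ez, rpe = rpe)
}

#' FluidMasks: binary IRF and SRF voxel masks
#'
#' Intraretinal fluid (IRF) lies strictly between ILM and EZ; subretinal
#' fluid (SRF) between EZ and RPE.  Masks are logical 3D arrays on the same
#' grid as the volume and are disjoint by construction.
#'
#' @slot irf,srf logical 3D arrays.
#' @export
setClass("FluidMasks",
  representation(irf = "array", srf = "array"),
  validity = function(object) {
    if (!identical(dim(object@irf), dim(object@srf)))
      return("irf and srf masks must share dimensions")
    if (!is.logical(object@irf) || !is.logical(object@srf))
      return("masks must be logical arrays")
    if (any(object@irf & object@srf))
      return("IRF and SRF masks must be disjoint")
    TRUE
  })

#' FluidMasks constructor
#' @param irf,srf logical 3D arrays (slice, depth, A-scan).
#' @return A [FluidMasks-class] object.
#' @export
FluidMasks <- function(irf, srf) new("FluidMasks", irf = irf, srf = srf)

#' CohortSpec: parameters of the synthetic OCT cohort generator
#'
#' Defaults emulate the study conditions of a 28-eye anti-VEGF durability
#' cohort (11 rebounders, 17 non-rebounders) at a desk-scale volume
#' geometry.  `effectSize` scales a high-frequency (spot-scale) texture
#' component added inside IRF pockets of rebounder eyes; at 0 the two
#' classes are exchangeable by construction.
#'
#' @slot nRebounder,nNonrebounder integer class sizes.
#' @slot volumeShape integer(3): (n_slices, depth, n_ascans).
#' @slot voxelSpacing numeric(3) micrometers per voxel.
#' @slot nIrfPockets,nSrfPockets integer(2) inclusive count ranges.
#' @slot effectSize non-negative multiplier on the rebounder IRF texture
#'   energy.
#' @slot speckleShape gamma shape of the multiplicative speckle (mean 1).
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
  representation(nRebounder = "integer", nNonrebounder = "integer",
                 volumeShape = "integer", voxelSpacing = "numeric",
                 nIrfPockets = "integer", nSrfPockets = "integer",
                 effectSize = "numeric", speckleShape = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nRebounder < 0L) return("nRebounder must be >= 0")
    if (object@nNonrebounder < 0L) return("nNonrebounder must be >= 0")
    if (object@nRebounder + object@nNonrebounder < 2L)
      return("nRebounder + nNonrebounder must be >= 2")
    if (length(object@volumeShape) != 3L || any(object@volumeShape < 1L))
      return("volumeShape must be 3 positive integers")
    if (object@volumeShape[2] < 16L)
      return("volumeShape depth must be >= 16 so three layers fit")
    for (fld in c("nIrfPockets", "nSrfPockets")) {
      r <- slot(object, fld)
      if (length(r) != 2L || any(r < 0L) || r[1] > r[2])
        return(sprintf("%s must be a non-decreasing pair of counts >= 0", fld))
    }
    if (object@effectSize < 0) return("effectSize must be >= 0")
    if (object@speckleShape <= 0) return("speckleShape must be > 0")
    TRUE
  })

#' CohortSpec constructor
#'
#' @param nRebounder,nNonrebounder class sizes (default 11 and 17).
#' @param volumeShape (n_slices, depth, n_ascans); default desk-scale
#'   `c(64, 96, 64)`.
#' @param voxelSpacing micrometers per voxel.
#' @param nIrfPockets,nSrfPockets inclusive ranges for the number of fluid
#'   pockets per eye.
#' @param effectSize class-effect multiplier (default 1).
#' @param speckleShape gamma speckle shape (default 4).
#' @param seed master seed.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nRebounder = 11L, nNonrebounder = 17L,
                       volumeShape = c(64L, 96L, 64L),
                       voxelSpacing = c(94, 21, 94),
                       nIrfPockets = c(1L, 3L), nSrfPockets = c(0L, 2L),
                       effectSize = 1, speckleShape = 4, seed = 1L) {
  new("CohortSpec",
      nRebounder = as.integer(nRebounder),
      nNonrebounder = as.integer(nNonrebounder),
      volumeShape = as.integer(volumeShape),
      voxelSpacing = as.numeric(voxelSpacing),
      nIrfPockets = as.integer(nIrfPockets),
      nSrfPockets = as.integer(nSrfPockets),
      effectSize = as.numeric(effectSize),
      speckleShape = as.numeric(speckleShape),
      seed = as.integer(seed))
}

#' SyntheticEye: one simulated OCT eye
#'
#' @slot volume an [OctVolume-class].
#' @slot surfaces a [LayerSurfaces-class].
#' @slot fluid a [FluidMasks-class].
#' @slot label `"rebounder"` or `"nonrebounder"`.
#' @slot eyeId character identifier.
#' @slot seed integer per-eye seed.
#' @export
setClass("SyntheticEye",
  representation(volume = "OctVolume", surfaces = "LayerSurfaces",
                 fluid = "FluidMasks", label = "character",
                 eyeId = "character", seed = "integer"),
  validity = function(object) {
    if (!object@label %in% c("rebounder", "nonrebounder"))
      return("label must be 'rebounder' or 'nonrebounder'")
    dv <- dim(object@volume@data)
    if (!identical(dv, dim(object@fluid@irf)))
      return("fluid masks and volume must share shape")
    if (!identical(dim(object@surfaces@ilm), c(dv[1], dv[3])))
      return("surfaces must be n_slices x n_ascans")
    TRUE
  })

#' CompartmentSet: the four analysis sub-volumes of one eye
#'
#' Binary masks for intraretinal fluid (IRF), subretinal fluid (SRF),
#' fluid-free inner tissue ILM->EZ (RTC1) and fluid-free outer tissue
#' EZ->RPE (RTC2), all restricted to an inclusive slice window.  The four
#' masks are pairwise disjoint; RTC1 | IRF tiles the ILM->EZ band and
#' RTC2 | SRF tiles the EZ->RPE band within the window.
#'
#' @slot masks named list of 4 logical arrays: IRF, SRF, RTC1, RTC2.
#' @slot sliceWindow integer(2) inclusive 1-based slice range.
#' @slot eyeId provenance identifier.
#' @export
setClass("CompartmentSet",
  representation(masks = "list", sliceWindow = "integer", eyeId = "character"),
  validity = function(object) {
    nm <- c("IRF", "SRF", "RTC1", "RTC2")
    if (!identical(names(object@masks), nm))
      return("masks must be named IRF, SRF, RTC1, RTC2")
    d <- dim(object@masks[[1]])
    for (m in object@masks)
      if (!identical(dim(m), d)) return("all masks must share dimensions")
    tot <- object@masks$IRF + object@masks$SRF +
           object@masks$RTC1 + object@masks$RTC2
    if (any(tot > 1L)) return("compartment masks must be pairwise disjoint")
    w <- object@sliceWindow
    if (length(w) != 2L || w[1] < 1L || w[2] > d[1] || w[1] > w[2])
      return("sliceWindow out of range")
    outside <- setdiff(seq_len(d[1]), seq(w[1], w[2]))
    if (length(outside) && any(tot[outside, , ] > 0))
      return("masks must be zero outside sliceWindow")
    TRUE
  })

#' FeatureTable: eyes x named texture descriptors
#'
#' Rows are eyes, columns are aggregated texture descriptors named
#' `"Compartment/Stat-Family_Param"` (e.g. `"IRF/Median-Laws_E3S3S3"`).
#'
#' @slot values numeric matrix with unique rownames (eye ids) and unique
#'   colnames (feature names).
#' @export
setClass("FeatureTable",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      return("rownames (eye ids) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      return("colnames (feature names) must be present and unique")
    if (!is.numeric(v)) return("values must be numeric")
    TRUE
  })

#' FeatureTable constructor
#' @param values numeric matrix, rownames = eye ids, colnames = features.
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(values) new("FeatureTable", values = values)

#' EvalProtocol: the repeated cross-validation evaluation protocol
#'
#' An 80:20 stratified train/test split followed by `nIterations` of
#' stratified `nFolds`-fold cross-validation within the training split, with
#' per-fold consensus feature selection and per-fold classifier fits.
#'
#' @slot trainFraction fraction of eyes in the training split (default 0.8).
#' @slot nIterations number of CV repetitions (study protocol: 1000).
#' @slot nFolds folds per repetition (study protocol: 3).
#' @slot classifiers subset of `c("LDA","QDA","RF","SVM")`.
#' @slot seed integer seed.
#' @slot positiveClass the positive label (`"rebounder"`).
#' @export
setClass("EvalProtocol",
  representation(trainFraction = "numeric", nIterations = "integer",
                 nFolds = "integer", classifiers = "character",
                 seed = "integer", positiveClass = "character"),
  validity = function(object) {
    if (object@trainFraction <= 0 || object@trainFraction > 1)
      return("trainFraction must be in (0, 1]")
    if (object@nFolds < 2L) return("nFolds must be >= 2")
    if (object@nIterations < 1L) return("nIterations must be >= 1")
    if (!all(object@classifiers %in% c("LDA", "QDA", "RF", "SVM")))
      return("classifiers must be a subset of LDA, QDA, RF, SVM")
    TRUE
  })

#' EvalProtocol constructor
#' @param trainFraction training split fraction (default 0.8).
#' @param nIterations CV repetitions (default 1000).
#' @param nFolds folds (default 3).
#' @param classifiers classifier names.
#' @param seed integer seed.
#' @param positiveClass positive label.
#' @return An [EvalProtocol-class] object.
#' @export
evalProtocol <- function(trainFraction = 0.8, nIterations = 1000L,
                         nFolds = 3L,
                         classifiers = c("LDA", "QDA", "RF", "SVM"),
                         seed = 1L, positiveClass = "rebounder") {
  new("EvalProtocol", trainFraction = trainFraction,
      nIterations = as.integer(nIterations), nFolds = as.integer(nFolds),
      classifiers = classifiers, seed = as.integer(seed),
      positiveClass = positiveClass)
}
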