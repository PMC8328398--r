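#' Accessors for octrad data classes
#'
#' `volumeData()` returns the raw 3D intensity array; `voxelSpacing()` the
#' per-axis spacing; `featureValues()` the eyes x features matrix;
#' `featureNames()` and `eyeIds()` its dimnames; `compartmentMask()` one of
#' the four compartment masks; `eyeLabel()` the class label of a synthetic
#' eye.
#'
#' @param x an octrad object.
#' @param name for `compartmentMask`, one of `"IRF"`, `"SRF"`, `"RTC1"`,
#'   `"RTC2"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("eyeIds", function(x) standardGeneric("eyeIds"))
#' @rdname accessors
#' @export
setGeneric("compartmentMask", function(x, name) standardGeneric("compartmentMask"))
#' @rdname accessors
#' @export
setGeneric("eyeLabel", function(x) standardGeneric("eyeLabel"))

#' @rdname accessors
#' @export
setMethod("volumeData", "OctVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volumeData", "SyntheticEye", function(x) x@volume@data)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "OctVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("eyeIds", "FeatureTable", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("compartmentMask", "CompartmentSet", function(x, name) {
  name <- match.arg(name, c("IRF", "SRF", "RTC1", "RTC2"))
  x@masks[[name]]
})
#' @rdname accessors
#' @export
setMethod("eyeLabel", "SyntheticEye", function(x) x@label)

#' @export
setMethod("dim", "OctVolume", function(x) dim(x@data))
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

setMethod("show", "OctVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("OctVolume: %d slices x %d depth x %d A-scans, spacing (%s) um\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = ", ")))
})

setMethod("show", "LayerSurfaces", function(object) {
  d <- dim(object@ilm)
  cat(sprintf("LayerSurfaces: %d slices x %d A-scans (ILM < EZ <= RPE)\n",
              d[1], d[2]))
})

setMethod("show", "FluidMasks", function(object) {
  cat(sprintf("FluidMasks: %d IRF voxels, %d SRF voxels on %s grid\n",
              sum(object@irf), sum(object@srf),
              paste(dim(object@irf), collapse = "x")))
})

setMethod("show", "SyntheticEye", function(object) {
  cat(sprintf("SyntheticEye '%s' (%s), seed %d\n",
              object@eyeId, object@label, object@seed))
  show(object@volume)
  show(object@fluid)
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d rebounders + %d non-rebounders, volume %s, effectSize %.2f, seed %d\n",
    object@nRebounder, object@nNonrebounder,
    paste(object@volumeShape, collapse = "x"),
    object@effectSize, object@seed))
})

setMethod("show", "CompartmentSet", function(object) {
  counts <- vapply(object@masks, sum, numeric(1))
  cat(sprintf("CompartmentSet '%s', slices %d..%d\n", object@eyeId,
              object@sliceWindow[1], object@sliceWindow[2]))
  cat("  voxels:", paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureTable: %d eyes x %d features\n", d[1], d[2]))
  if (d[2] > 0)
    cat("  e.g.", paste(utils::head(colnames(object@values), 3),
                        collapse = ", "), "...\n")
})

setMethod("show", "EvalProtocol", function(object) {
  cat(sprintf(
    "EvalProtocol: %.0f:%.0f split, %d x %d-fold CV, classifiers %s, seed %d\n",
    100 * object@trainFraction, 100 * (1 - object@trainFraction),
    object@nIterations, object@nFolds,
    paste(object@classifiers, collapse = "/"), object@seed))
})
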