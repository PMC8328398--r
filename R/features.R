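## Aggregation of per-voxel maps into the 962-descriptor feature table,
## fusion of compartment tables, and z-normalization.

#' First-order aggregation statistics over masked voxels
#'
#' Median, variance (denominator n), skewness and kurtosis (standardized
#' 3rd/4th central moments; kurtosis non-excess) of the values.  With fewer
#' than 2 values the variance, skewness and kurtosis are NaN; with zero
#' variance skewness and kurtosis are 0 by convention.
#'
#' @param values numeric vector of masked per-voxel responses.
#' @return named numeric(4): Median, Variance, Skewness, Kurtosis.
#' @examples
#' aggregateStats(1:5)  # median 3, variance 2, skewness 0, kurtosis 1.7
#' @export
aggregateStats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L)
    return(c(Median = NaN, Variance = NaN, Skewness = NaN, Kurtosis = NaN))
  med <- stats::median(values)
  if (n < 2L)
    return(c(Median = med, Variance = NaN, Skewness = NaN, Kurtosis = NaN))
  mu <- mean(values)
  v <- mean((values - mu)^2)
  if (v <= 0)
    return(c(Median = med, Variance = 0, Skewness = 0, Kurtosis = 0))
  s <- sqrt(v)
  c(Median = med, Variance = v,
    Skewness = mean((values - mu)^3) / s^3,
    Kurtosis = mean((values - mu)^4) / v^2)
}

#' Aggregate a per-voxel map over a compartment mask
#'
#' @param map a [VoxelFeatureMap-class] or 3D array.
#' @param mask logical 3D array.
#' @return named numeric(4) as in [aggregateStats()].
#' @export
aggregateMap <- function(map, mask) {
  vals <- if (is(map, "VoxelFeatureMap")) map@values else map
  aggregateStats(vals[mask])
}

#' Extract the 962-descriptor feature vector for each compartment of an eye
#'
#' Per-voxel maps for the four descriptor families are computed and
#' aggregated over each compartment mask.  Every non-empty compartment
#' yields exactly the manifest's 962 named values; an empty compartment
#' yields 962 missing values (reported via a message, never dropped).
#'
#' @param eye a [SyntheticEye-class].
#' @param compartments a [CompartmentSet-class] for the eye.
#' @param manifest a [FeatureBankManifest-class].
#' @return named list of numeric vectors (`IRF`, `SRF`, `RTC1`, `RTC2`),
#'   each of length `nrow(manifest@descriptors)`, names prefixed with the
#'   compartment (e.g. `"IRF/Median-Laws_E3S3S3"`).
#' @export
extractFeatures <- function(eye, compartments,
                            manifest = featureBankManifest()) {
  arr <- eye@volume@data
  desc <- manifest@descriptors
  comps <- names(compartments@masks)
  nonEmpty <- vapply(compartments@masks, function(m) any(m), logical(1))
  if (any(!nonEmpty))
    message("extractFeatures [", eye@eyeId, "]: empty compartment(s) ",
            paste(comps[!nonEmpty], collapse = ", "),
            " -> missing feature rows")

  # per-family aggregated values, indexed [map, aggstat, compartment]
  store <- list()
  lawsNames <- unique(desc$map[desc$family == "Laws"])
  gaborNames <- unique(desc$map[desc$family == "Gabor"])

  aggOver <- function(vals) {
    out <- array(NA_real_, dim = c(4, length(comps)),
                 dimnames = list(AGG_STATS, comps))
    for (ci in seq_along(comps))
      if (nonEmpty[ci]) out[, ci] <- aggregateStats(vals[compartments@masks[[ci]]])
    out
  }

  # Laws: stream map by map to bound memory
  w <- manifest@params$laws$energyWindow
  store$Laws <- array(NA_real_, dim = c(length(lawsNames), 4, length(comps)),
                      dimnames = list(lawsNames, AGG_STATS, comps))
  for (nm in lawsNames) {
    ks <- lawsTripletKernels(nm)
    r <- cpp_sepconv3(arr, dim(arr), ks[[1]], ks[[2]], ks[[3]])
    r <- cpp_boxmean3(abs(r), dim(arr), w)
    store$Laws[nm, , ] <- aggOver(r)
  }

  # Gabor: shared slice FFTs across the bank
  gm <- gaborMaps(eye@volume, manifest, maps = gaborNames)
  store$Gabor <- array(NA_real_, dim = c(length(gaborNames), 4, length(comps)),
                       dimnames = list(gaborNames, AGG_STATS, comps))
  for (nm in gaborNames) store$Gabor[nm, , ] <- aggOver(gm[[nm]]@values)
  rm(gm)

  # Haralick and CoLlAGe: mask-dependent, computed per compartment
  store$Haralick <- array(NA_real_,
                          dim = c(length(HARALICK_STATS), 4, length(comps)),
                          dimnames = list(HARALICK_STATS, AGG_STATS, comps))
  collNames <- unique(desc$map[desc$family == "CoLlAGe"])
  store$CoLlAGe <- array(NA_real_, dim = c(length(collNames), 4, length(comps)),
                         dimnames = list(collNames, AGG_STATS, comps))
  for (ci in seq_along(comps)) {
    if (!nonEmpty[ci]) next
    msk <- compartments@masks[[ci]]
    hm <- haralickStatMatrix(arr, msk, manifest@params$haralick$windowSize,
                             manifest@params$haralick$nLevels)
    for (j in seq_along(HARALICK_STATS))
      store$Haralick[j, , ci] <- aggregateStats(hm[, j])
    cm <- collageStatMatrix(arr, msk, manifest@params$collage$windowSize,
                            manifest@params$collage$nBins)
    for (j in seq_len(ncol(cm)))
      store$CoLlAGe[colnames(cm)[j], , ci] <- aggregateStats(cm[, j])
  }

  out <- lapply(seq_along(comps), function(ci) {
    vals <- vapply(seq_len(nrow(desc)), function(k)
      store[[desc$family[k]]][desc$map[k], desc$stat[k], ci], numeric(1))
    names(vals) <- paste0(comps[ci], "/", desc$name)
    vals
  })
  names(out) <- comps
  out
}

#' Extract per-compartment feature tables for a cohort
#'
#' @param eyes list of [SyntheticEye-class] objects.
#' @param manifest a [FeatureBankManifest-class].
#' @param sliceWindow optional integer(2); default proportional mid-macular
#'   window.
#' @param verbose print per-eye progress.
#' @return named list of four [FeatureTable-class] objects (IRF, SRF, RTC1,
#'   RTC2), rows = eyes.
#' @export
extractCohortFeatures <- function(eyes, manifest = featureBankManifest(),
                                  sliceWindow = NULL, verbose = FALSE) {
  rows <- lapply(eyes, function(eye) {
    if (verbose) message("extracting ", eye@eyeId)
    cs <- deriveCompartments(eye@surfaces, eye@fluid,
                             sliceWindow = sliceWindow, eyeId = eye@eyeId)
    suppressMessages(extractFeatures(eye, cs, manifest))
  })
  ids <- vapply(eyes, function(e) e@eyeId, character(1))
  comps <- c("IRF", "SRF", "RTC1", "RTC2")
  out <- lapply(comps, function(cn) {
    m <- do.call(rbind, lapply(rows, `[[`, cn))
    rownames(m) <- ids
    FeatureTable(m)
  })
  names(out) <- comps
  out
}

#' Fuse compartment feature tables
#'
#' `which = "f"` column-concatenates IRF + SRF (the combined fluid table
#' F_f); `"rtc"` concatenates RTC1 + RTC2 (F_RTC); `"oct"` concatenates all
#' four (F_OCT = F_f + F_RTC).  Compartment prefixes keep names unique.
#'
#' @param tables named list with elements `IRF`, `SRF`, `RTC1`, `RTC2`
#'   ([FeatureTable-class] objects sharing eye ids).
#' @param which `"f"`, `"rtc"` or `"oct"`.
#' @return A [FeatureTable-class].
#' @export
fuseTables <- function(tables, which = c("f", "rtc", "oct")) {
  which <- match.arg(which)
  pick <- switch(which, f = c("IRF", "SRF"), rtc = c("RTC1", "RTC2"),
                 oct = c("IRF", "SRF", "RTC1", "RTC2"))
  ids <- lapply(tables[pick], eyeIds)
  for (i in seq_along(ids)[-1]) {
    if (!setequal(ids[[1]], ids[[i]])) {
      dif <- union(setdiff(ids[[1]], ids[[i]]), setdiff(ids[[i]], ids[[1]]))
      stop("eye_id mismatch between tables: ", paste(dif, collapse = ", "))
    }
  }
  mats <- lapply(tables[pick], function(t) featureValues(t)[ids[[1]], , drop = FALSE])
  FeatureTable(do.call(cbind, mats))
}

#' Z-normalize a feature table
#'
#' Per-column standardization to mean 0 and (population) standard deviation
#' 1 over non-missing entries.  Zero-variance columns are set to 0 and
#' flagged in the `"constantColumns"` attribute.
#'
#' @param table a [FeatureTable-class] or numeric matrix.
#' @return object of the same type; normalized.
#' @export
znormalize <- function(table) {
  m <- if (is(table, "FeatureTable")) featureValues(table) else table
  zn <- znormalizeMatrix(m)
  if (is(table, "FeatureTable")) {
    out <- FeatureTable(zn$m)
    attr(out, "constantColumns") <- zn$constant
    out
  } else {
    attr(zn$m, "constantColumns") <- zn$constant
    zn$m
  }
}

# internal: returns list(m, constant, center, scale); population sd
znormalizeMatrix <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(m, na.rm = TRUE)
    scale <- sqrt(colMeans(sweep(m, 2, center)^2, na.rm = TRUE))
  }
  constant <- which(!is.finite(scale) | scale < 1e-15)
  scale2 <- ifelse(is.finite(scale) & scale >= 1e-15, scale, 1)
  zm <- sweep(sweep(m, 2, center), 2, scale2, "/")
  zm[, constant] <- 0
  list(m = zm, constant = colnames(m)[constant], center = center,
       scale = scale2)
}
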