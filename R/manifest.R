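## The feature-bank manifest: the single versioned source of truth for the
## 962-descriptor bank (52 Haralick + 501 Laws + 383 Gabor + 26 CoLlAGe).
## Family grids are enumerated in a fixed canonical order and truncated to
## the published per-family counts; the manifest, not the grids, defines the
## bank.

LAWS_KERNELS <- list(
  L3 = c(1, 2, 1),    E3 = c(-1, 0, 1),   S3 = c(-1, 2, -1),
  L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1), S5 = c(-1, 0, 2, 0, -1),
  R5 = c(1, -4, 6, -4, 1), W5 = c(-1, 2, 0, -2, 1))

HARALICK_STATS <- c("Energy", "Contrast", "Correlation", "Variance",
                    "Homogeneity", "SumAverage", "SumVariance", "SumEntropy",
                    "Entropy", "DifferenceVariance", "DifferenceEntropy",
                    "IMC1", "IMC2")

AGG_STATS <- c("Median", "Variance", "Skewness", "Kurtosis")

#' FeatureBankManifest: the versioned 962-descriptor bank definition
#'
#' @slot version manifest version string.
#' @slot descriptors data.frame with columns `family`, `map`, `stat`,
#'   `name`; exactly one row per descriptor.
#' @slot params named list of family parameter grids (window sizes, kernel
#'   triplets, Gabor orientations/wavelengths/bandwidths, CoLlAGe bins).
#' @export
setClass("FeatureBankManifest",
  representation(version = "character", descriptors = "data.frame",
                 params = "list"),
  validity = function(object) {
    d <- object@descriptors
    if (!all(c("family", "map", "stat", "name") %in% names(d)))
      return("descriptors must have family, map, stat, name columns")
    if (anyDuplicated(d$name)) return("descriptor names must be unique")
    counts <- table(factor(d$family,
                           levels = c("Haralick", "Laws", "Gabor", "CoLlAGe")))
    want <- c(Haralick = 52L, Laws = 501L, Gabor = 383L, CoLlAGe = 26L)
    if (!identical(as.integer(counts), unname(want)))
      return(sprintf("family counts must be 52/501/383/26, got %s",
                     paste(counts, collapse = "/")))
    TRUE
  })

lawsTriplets <- function() {
  tri3 <- expand.grid(k3 = c("L3", "E3", "S3"), k2 = c("L3", "E3", "S3"),
                      k1 = c("L3", "E3", "S3"),
                      stringsAsFactors = FALSE)[, 3:1]
  n5 <- c("L5", "E5", "S5", "R5", "W5")
  tri5 <- expand.grid(k3 = n5, k2 = n5, k1 = n5,
                      stringsAsFactors = FALSE)[, 3:1]
  rbind(tri3, tri5)
}

gaborGrid <- function() {
  expand.grid(bandwidth = c(0.4, 0.6, 0.8),
              wavelength = c(3, 4, 6, 8),
              orientation = seq(0, 157.5, by = 22.5))[, 3:1]
}

#' Build the default feature-bank manifest
#'
#' Enumerates, in canonical order, 13 Haralick statistics (x 4 aggregation
#' statistics = 52 descriptors); Laws energy maps over all 27 three-point
#' and 125 five-point separable kernel triplets (x 4, truncated to 501);
#' a 2D slice-wise Gabor bank over 8 orientations x 4 wavelengths x 3
#' bandwidths (x 4, truncated to 383); and 13 CoLlAGe co-occurrence
#' statistics x 2 angle channels aggregated by median (26).  Total 962.
#'
#' @param version manifest version string.
#' @return A [FeatureBankManifest-class].
#' @export
featureBankManifest <- function(version = "1.0") {
  rows <- list()

  # Haralick: 13 GLCM statistics x 4 aggregation statistics = 52
  h <- expand.grid(stat = AGG_STATS, map = HARALICK_STATS,
                   stringsAsFactors = FALSE)[, 2:1]
  rows$Haralick <- data.frame(family = "Haralick", map = h$map, stat = h$stat)

  # Laws: 152 triplets x 4 = 608, truncated to 501
  tri <- lawsTriplets()
  mapNames <- vapply(seq_len(nrow(tri)), function(i)
    paste0(tri$k1[i], tri$k2[i], tri$k3[i]), character(1))
  l <- expand.grid(stat = AGG_STATS, map = mapNames,
                   stringsAsFactors = FALSE)[, 2:1]
  rows$Laws <- data.frame(family = "Laws", map = l$map, stat = l$stat)[1:501, ]

  # Gabor: 96 filters x 4 = 384, truncated to 383
  g <- gaborGrid()
  gNames <- sprintf("o%03.0f_w%g_b%g", g$orientation * 10, g$wavelength,
                    g$bandwidth)
  gg <- expand.grid(stat = AGG_STATS, map = gNames,
                    stringsAsFactors = FALSE)[, 2:1]
  rows$Gabor <- data.frame(family = "Gabor", map = gg$map,
                           stat = gg$stat)[1:383, ]

  # CoLlAGe: 13 statistics x 2 angle channels, median-aggregated = 26
  cm <- expand.grid(channel = c("InPlane", "ThroughPlane"),
                    stat0 = HARALICK_STATS, stringsAsFactors = FALSE)[, 2:1]
  rows$CoLlAGe <- data.frame(family = "CoLlAGe",
                             map = paste0(cm$stat0, "_", cm$channel),
                             stat = "Median")

  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d$name <- paste0(d$stat, "-", d$family, "_", d$map)
  new("FeatureBankManifest", version = version, descriptors = d,
      params = list(
        haralick = list(windowSize = 5L, nLevels = 32L),
        laws = list(triplets = tri, energyWindow = 5L),
        gabor = list(grid = gaborGrid()),
        collage = list(windowSize = 5L, nBins = 16L)))
}

#' Descriptor count per family
#' @param manifest a [FeatureBankManifest-class].
#' @return named integer vector of per-family descriptor counts.
#' @export
familyCounts <- function(manifest) {
  tab <- table(factor(manifest@descriptors$family,
                      levels = c("Haralick", "Laws", "Gabor", "CoLlAGe")))
  stats::setNames(as.integer(tab), names(tab))
}

setMethod("show", "FeatureBankManifest", function(object) {
  fc <- familyCounts(object)
  cat(sprintf("FeatureBankManifest v%s: %d descriptors (%s)\n",
              object@version, nrow(object@descriptors),
              paste(sprintf("%s=%d", names(fc), fc), collapse = ", ")))
})

#' Serialize / load a feature-bank manifest as JSON
#'
#' @param manifest a [FeatureBankManifest-class].
#' @param path JSON file path.
#' @return `readManifest` returns a [FeatureBankManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(
    list(version = manifest@version,
         descriptors = manifest@descriptors,
         params = list(
           haralick = manifest@params$haralick,
           laws = list(triplets = manifest@params$laws$triplets,
                       energyWindow = manifest@params$laws$energyWindow),
           gabor = manifest@params$gabor,
           collage = manifest@params$collage)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FeatureBankManifest", version = m$version,
      descriptors = as.data.frame(m$descriptors),
      params = list(
        haralick = m$params$haralick,
        laws = list(triplets = as.data.frame(m$params$laws$triplets),
                    energyWindow = m$params$laws$energyWindow),
        gabor = list(grid = as.data.frame(m$params$gabor$grid)),
        collage = m$params$collage))
}
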