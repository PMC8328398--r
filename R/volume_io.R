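## I/O: NIfTI / multi-page TIFF volumes and masks, surface and label CSVs,
## cohort manifests (JSON), feature-table CSVs.

volumeFormat <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  stop("unsupported volume format (need .nii/.nii.gz or .tif/.tiff): ", path)
}

#' Read a volumetric OCT cube or mask
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and multi-page TIFF.  TIFF pages are
#' treated as slices (axis 1); NIfTI axes are taken as stored.  Integer
#' intensities round-trip losslessly; spacing defaults to 1 micrometer per
#' axis when the file carries none.
#'
#' @param path file path.
#' @return An [OctVolume-class].
#' @export
readVolume <- function(path) {
  fmt <- volumeFormat(path)
  if (!file.exists(path)) stop("no such volume file: ", path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    a <- unclass(img)
    attributes(a) <- list(dim = dim(img))
    if (length(dim(a)) != 3L)
      stop("not a 3D volume (", paste(dim(a), collapse = "x"), "): ", path)
    pd <- attr(img, "pixdim")
    spacing <- if (!is.null(pd) && length(pd) >= 3 && all(pd[1:3] > 0))
      pd[1:3] else c(1, 1, 1)
    OctVolume(array(as.numeric(a), dim = dim(a)), spacing = spacing)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L && length(dim(pages[[1]])) == 2L && length(pages) == 1L)
      stop("not a 3D volume (single-page TIFF): ", path)
    d2 <- dim(pages[[1]])
    if (length(d2) != 2L) stop("TIFF pages must be single-channel 2D: ", path)
    arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    OctVolume(arr, spacing = c(1, 1, 1))
  }
}

#' Write a volumetric OCT cube or mask
#'
#' @param volume an [OctVolume-class] or 3D array.
#' @param path destination (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  if (is(volume, "OctVolume")) {
    arr <- volume@data; spacing <- volume@spacing
  } else {
    arr <- volume; spacing <- c(1, 1, 1)
  }
  if (length(dim(arr)) != 3L) stop("volume must be 3D")
  fmt <- volumeFormat(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else {
    ## 16-bit unsigned storage; integer values in [0, 65535] are lossless
    if (any(arr < 0 | arr > 65535))
      stop("TIFF output supports intensities in [0, 65535]")
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(i) arr[i, , , drop = TRUE] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' An eye's on-disk record within a cohort
#'
#' @slot eyeId identifier.
#' @slot volumePath,surfacesPath file paths.
#' @slot maskPaths named character(2): IRF and SRF mask paths.
#' @slot label `"rebounder"`, `"nonrebounder"`, or `NA` (prediction-only).
#' @export
setClass("EyeRecord",
  representation(eyeId = "character", volumePath = "character",
                 maskPaths = "character", surfacesPath = "character",
                 label = "character"))

#' Write a synthetic cohort to disk
#'
#' Writes per-eye volumes and 0/1 masks (NIfTI by default), a long-format
#' surfaces CSV (eye_id, slice, ascan, ilm_depth, ez_depth, rpe_depth), a
#' label CSV (eye_id, label), and a JSON manifest holding the full
#' [CohortSpec-class] and per-eye seeds.
#'
#' @param eyes list of [SyntheticEye-class] objects.
#' @param dir output directory (created if needed).
#' @param spec the generating [CohortSpec-class] (stored in the manifest).
#' @param format `"nifti"` or `"tiff"`.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(eyes, dir, spec, format = c("nifti", "tiff")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".tif"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  surfRows <- list(); labRows <- list(); entries <- list()
  for (eye in eyes) {
    id <- eye@eyeId
    vp <- file.path(dir, paste0(id, "_volume", ext))
    ip <- file.path(dir, paste0(id, "_irf", ext))
    sp <- file.path(dir, paste0(id, "_srf", ext))
    writeVolume(eye@volume, vp)
    writeVolume(array(as.numeric(eye@fluid@irf), dim = dim(eye@fluid@irf)), ip)
    writeVolume(array(as.numeric(eye@fluid@srf), dim = dim(eye@fluid@srf)), sp)
    d <- dim(eye@surfaces@ilm)
    surfRows[[id]] <- data.frame(
      eye_id = id,
      slice = rep(seq_len(d[1]), times = d[2]),
      ascan = rep(seq_len(d[2]), each = d[1]),
      ilm_depth = as.vector(eye@surfaces@ilm),
      ez_depth = as.vector(eye@surfaces@ez),
      rpe_depth = as.vector(eye@surfaces@rpe))
    labRows[[id]] <- data.frame(eye_id = id, label = eye@label)
    entries[[id]] <- list(
      eye_id = id, volume = basename(vp),
      masks = list(IRF = basename(ip), SRF = basename(sp)),
      surfaces = "surfaces.csv", label = eye@label, seed = eye@seed)
  }
  data.table::fwrite(data.table::rbindlist(surfRows),
                     file.path(dir, "surfaces.csv"))
  data.table::fwrite(data.table::rbindlist(labRows),
                     file.path(dir, "labels.csv"))
  manifest <- list(
    format = format,
    spec = specToList(spec),
    eyes = unname(entries))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

specToList <- function(spec) {
  list(nRebounder = spec@nRebounder, nNonrebounder = spec@nNonrebounder,
       volumeShape = spec@volumeShape, voxelSpacing = spec@voxelSpacing,
       nIrfPockets = spec@nIrfPockets, nSrfPockets = spec@nSrfPockets,
       effectSize = spec@effectSize, speckleShape = spec@speckleShape,
       seed = spec@seed)
}

specFromList <- function(lst) {
  do.call(cohortSpec, lst)
}

#' Read a cohort manifest
#'
#' Loads the JSON manifest written by [writeCohort()] (or a user-authored
#' equivalent), validates that each eye's masks share the volume's shape,
#' and returns one [EyeRecord-class] per eye.  Missing labels are allowed
#' (prediction-only cohorts).
#'
#' @param manifestPath path to `manifest.json`.
#' @return list of [EyeRecord-class] objects.
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath)) stop("no such manifest: ", manifestPath)
  m <- jsonlite::read_json(manifestPath)
  dir <- dirname(manifestPath)
  recs <- lapply(m$eyes, function(e) {
    vp <- file.path(dir, e$volume)
    mp <- c(IRF = file.path(dir, e$masks$IRF),
            SRF = file.path(dir, e$masks$SRF))
    for (p in c(vp, mp)) if (!file.exists(p))
      stop("missing file for eye ", e$eye_id, ": ", p)
    vol <- readVolume(vp)
    for (nm in names(mp)) {
      msk <- readVolume(mp[[nm]])
      if (!identical(dim(msk@data), dim(vol@data)))
        stop("shape mismatch between volume and ", nm, " mask for eye ",
             e$eye_id)
    }
    new("EyeRecord", eyeId = e$eye_id, volumePath = vp, maskPaths = mp,
        surfacesPath = file.path(dir, e$surfaces),
        label = if (is.null(e$label)) NA_character_ else e$label)
  })
  recs
}

#' Load one eye from its on-disk record
#'
#' @param record an [EyeRecord-class].
#' @return A [SyntheticEye-class] (label `"nonrebounder"` place-holder when
#'   the record carries none; check the record for truth).
#' @export
loadEye <- function(record) {
  vol <- readVolume(record@volumePath)
  irf <- readVolume(record@maskPaths[["IRF"]])@data > 0.5
  srf <- readVolume(record@maskPaths[["SRF"]])@data > 0.5
  surf <- data.table::fread(record@surfacesPath)
  surf <- surf[surf$eye_id == record@eyeId, ]
  d <- dim(vol@data)
  toM <- function(col) {
    m <- matrix(NA_real_, d[1], d[3])
    m[cbind(surf$slice, surf$ascan)] <- col
    m
  }
  surfaces <- LayerSurfaces(toM(surf$ilm_depth), toM(surf$ez_depth),
                            toM(surf$rpe_depth))
  lbl <- if (is.na(record@label)) "nonrebounder" else record@label
  new("SyntheticEye", volume = vol, surfaces = surfaces,
      fluid = FluidMasks(irf, srf), label = lbl, eyeId = record@eyeId,
      seed = NA_integer_)
}

#' Write / read a feature table as CSV
#'
#' CSV layout: an `eye_id` key column followed by one column per feature.
#' Numeric values round-trip within 1e-12 relative tolerance; NaN entries
#' (undefined statistics on degenerate compartments) are preserved and
#' their count reported in a message.
#'
#' @param table a [FeatureTable-class].
#' @param path CSV destination / source.
#' @return `readFeatureTable` returns a [FeatureTable-class];
#'   `writeFeatureTable` returns `path` invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  v <- featureValues(table)
  nNa <- sum(!is.finite(v))
  if (nNa > 0)
    message("writeFeatureTable: ", nNa,
            " non-finite values (empty-compartment statistics) preserved")
  df <- data.frame(eye_id = rownames(v), v, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- data.table::fread(path, check.names = FALSE)
  if (!"eye_id" %in% names(df)) stop("feature table CSV needs an eye_id column")
  ids <- as.character(df$eye_id)
  m <- as.matrix(df[, setdiff(names(df), "eye_id"), with = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate feature names in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  FeatureTable(m)
}
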