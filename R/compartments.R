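## Compartment derivation: the four analysis sub-volumes (IRF, SRF, RTC1 =
## fluid-free ILM->EZ tissue, RTC2 = fluid-free EZ->RPE tissue), with the
## mid-macular slice window and the empty-slice exclusion for fluid.

#' Select the analysis slice window
#'
#' The study protocol uses the mid central subfield slices 43..85 (1-based,
#' inclusive) of a 128-slice macular cube for retinal tissue, and the same
#' window with empty-fluid slices removed for the fluid compartments.  For
#' other slice counts the window is scaled proportionally: slice centre
#' positions are mapped through `x' = (x - 0.5) * n / 128 + 0.5` and the
#' endpoints rounded half away from the volume centre.
#'
#' @param eye a [SyntheticEye-class], or an integer slice count (tissue mode
#'   only).
#' @param mode `"tissue"` (full window) or `"fluid"` (window minus slices
#'   whose IRF and SRF masks are both empty; errors with a classed
#'   `octradNoFluidError` condition when nothing remains).
#' @return integer vector of 1-based slice indices.
#' @export
selectSlices <- function(eye, mode = c("tissue", "fluid")) {
  mode <- match.arg(mode)
  if (is.numeric(eye)) {
    nSlices <- as.integer(eye)
    if (mode == "fluid") stop("fluid mode needs an eye with fluid masks")
    fluidAny <- NULL
  } else {
    nSlices <- dim(eye@volume@data)[1]
    fluidAny <- eye@fluid@irf | eye@fluid@srf
  }
  w <- scaleWindow(nSlices)
  slices <- seq(w[1], w[2])
  if (mode == "fluid") {
    keep <- vapply(slices, function(s) any(fluidAny[s, , ]), logical(1))
    slices <- slices[keep]
    if (length(slices) == 0L)
      stop(structure(class = c("octradNoFluidError", "error", "condition"),
                     list(message = "no fluid voxels in window",
                          call = sys.call(-1))))
  }
  slices
}

# proportional rescaling of the canonical 43..85-of-128 window
scaleWindow <- function(nSlices, lo = 43L, hi = 85L, ref = 128L) {
  centre <- (nSlices + 1) / 2
  map <- function(x) (x - 0.5) * nSlices / ref + 0.5
  roundAway <- function(v) {
    f <- v - floor(v)
    if (abs(f - 0.5) < 1e-9) {
      if (v < centre) floor(v) else ceiling(v)
    } else round(v)
  }
  c(max(1L, as.integer(roundAway(map(lo)))),
    min(nSlices, as.integer(roundAway(map(hi)))))
}

#' Derive the four analysis compartments of an eye
#'
#' RTC1 is the set of voxels with ILM <= depth < EZ minus IRF; RTC2 the set
#' with EZ <= depth < RPE minus SRF; the fluid masks are passed through.
#' All four masks are restricted to the slice window (zeroed outside).
#'
#' @param surfaces a [LayerSurfaces-class] (ordering is re-validated; a
#'   violation raises a geometry error citing the slice and A-scan).
#' @param fluid a [FluidMasks-class] whose masks lie within their bands.
#' @param sliceWindow integer(2) inclusive 1-based slice range; default is
#'   the proportional 43..85-of-128 window for the mask's slice count.
#' @param eyeId provenance string.
#' @return A [CompartmentSet-class].
#' @examples
#' ilm <- matrix(2, 1, 4); ez <- matrix(5, 1, 4); rpe <- matrix(8, 1, 4)
#' surf <- LayerSurfaces(ilm, ez, rpe)
#' fl <- FluidMasks(array(FALSE, c(1, 10, 4)), array(FALSE, c(1, 10, 4)))
#' cs <- deriveCompartments(surf, fl, sliceWindow = c(1, 1))
#' sum(compartmentMask(cs, "RTC1"))  # 3 depths x 4 A-scans = 12
#' @export
deriveCompartments <- function(surfaces, fluid, sliceWindow = NULL,
                               eyeId = "eye") {
  shape <- dim(fluid@irf)
  if (!identical(dim(surfaces@ilm), c(shape[1], shape[3])))
    stop("surfaces (", paste(dim(surfaces@ilm), collapse = "x"),
         ") do not match mask grid (", paste(shape, collapse = "x"), ")")
  bad <- which(!(surfaces@ilm < surfaces@ez & surfaces@ez <= surfaces@rpe),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("surface ordering violated at (slice=%d, ascan=%d)",
                 bad[1, 1], bad[1, 2]))
  if (is.null(sliceWindow)) sliceWindow <- scaleWindow(shape[1])
  sliceWindow <- as.integer(sliceWindow)

  bands <- bandMasks(surfaces, shape)
  inWindow <- array(FALSE, dim = shape)
  inWindow[seq(sliceWindow[1], sliceWindow[2]), , ] <- TRUE

  irf <- fluid@irf & inWindow
  srf <- fluid@srf & inWindow
  rtc1 <- bands$inner & inWindow & !irf
  rtc2 <- bands$outer & inWindow & !srf
  new("CompartmentSet",
      masks = list(IRF = irf, SRF = srf, RTC1 = rtc1, RTC2 = rtc2),
      sliceWindow = sliceWindow, eyeId = eyeId)
}

#' Per-eye compartment voxel-count summary
#'
#' @param compartments a [CompartmentSet-class].
#' @return one-row data.frame of voxel counts per compartment.
#' @export
compartmentCounts <- function(compartments) {
  counts <- vapply(compartments@masks, sum, numeric(1))
  data.frame(eye_id = compartments@eyeId, t(counts))
}
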