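#' Separate junctional (membrane) and cytoplasmic/nuclear Arm pools
#'
#' Within a rectangular ROI confined to one signaling regime, the
#' background-adjusted total intensity is decomposed exactly into the
#' membrane pool (pixels under the membrane mask) and the remaining
#' cytoplasmic/nuclear pool, and areas are tracked so per-area means can be
#' compared across pools: `membraneIntensity + cytoplasmicIntensity ==
#' totalIntensity` and `membraneArea + cytoplasmicArea == roiArea`, both
#' exact.
#'
#' @param armProjection numeric `(y, x)` matrix (unmasked Arm projection).
#' @param mask a [MembraneMask-class] or logical matrix aligned to the
#'   projection.
#' @param roi rectangle `c(x, y, w, h)`. The study's ROI was 160 x 20 px
#'   drawn with the anterior rotated to the top, i.e. long axis along DV; in
#'   canonical (anterior-left) orientation this is a 20-wide by 160-high
#'   rectangle. See [placePoolRoi()].
#' @param background scalar background subtracted per pixel.
#' @return a [PoolResult-class].
#' @examples
#' out <- renderEmbryo(embryoSpec(), noise = FALSE)
#' arm <- sumProjection(out$image, role = "arm")
#' roi <- placePoolRoi(out$truth, regime = "off")
#' poolSeparation(arm, out$truth@membraneTruth, roi, background = 5 * 8)
#' @export
poolSeparation <- function(armProjection, mask, roi, background = 0) {
    m <- if (is(mask, "MembraneMask")) mask@mask else mask
    if (!all(dim(armProjection) == dim(m)))
        stop("projection and mask shapes differ")
    rectCheck(roi, dim(armProjection), "pool roi")
    sub <- rectCrop(armProjection, roi) - background
    msub <- rectCrop(m, roi)
    roiArea <- length(sub)
    memArea <- sum(msub)
    cytArea <- roiArea - memArea
    if (cytArea == 0)
        stop("membrane mask covers the whole ROI: cytoplasmic mean undefined")
    total <- sum(sub)
    memI <- sum(sub[msub])
    cytI <- total - memI
    new("PoolResult", totalIntensity = total, membraneIntensity = memI,
        cytoplasmicIntensity = cytI, roiArea = roiArea,
        membraneArea = memArea, cytoplasmicArea = cytArea,
        totalMean = total / roiArea,
        membraneMean = if (memArea > 0) memI / memArea else 0,
        cytoplasmicMean = cytI / cytArea, roi = roi)
}

#' Place a pool-separation ROI confined to one signaling regime
#'
#' Centres the ROI on a Wg stripe (`regime = "on"`) or on an interstripe
#' (`regime = "off"`) using the generator's ground truth, spanning the cell
#' rows vertically. The ROI is one segment-aligned cell period wide so its
#' membrane/cytoplasm area ratio matches the lattice.
#'
#' @param truth a [GroundTruth-class].
#' @param regime `"off"` (interstripe) or `"on"` (Wg stripe).
#' @param widthPx ROI width along AP; defaults to one cell diameter.
#' @return rectangle `c(x, y, w, h)`.
#' @export
placePoolRoi <- function(truth, regime = c("off", "on"), widthPx = NULL) {
    regime <- match.arg(regime)
    spec <- truth@spec
    geo <- latticeGeometry(spec)
    if (is.null(widthPx)) widthPx <- spec@cellDiameterPx
    cx <- if (regime == "on") geo$stripeX[1]
          else geo$stripeX[1] + segmentPeriodPx(spec) / 2
    y0 <- spec@marginPx + 1
    h <- spec@cellRows * spec@cellDiameterPx + spec@membraneWidthPx
    c(round(cx - widthPx / 2), y0, as.integer(widthPx), h)
}
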