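#' Arm intensity profile across segments
#'
#' Column means of a membrane-subtracted Arm projection along the AP axis
#' within a rectangular ROI, resampled to a fixed number of points (the
#' embryo-length adjustment) and shifted so the profile minimum is zero
#' (valleys to zero). The default of 100 points per segment resamples a
#' three-segment ROI to 300 points.
#'
#' @param armMasked numeric `(y, x)` matrix, membrane-subtracted.
#' @param roi rectangle `c(x, y, w, h)` spanning the segments of interest.
#' @param nSegments segments covered by the ROI.
#' @param pointsPerSegment resampled profile resolution.
#' @param smoothSigmaPx optional Gaussian smoothing of the column means, in
#'   pixels, to suppress single-cell-scale ripple (masked membrane lines)
#'   when segment-scale structure is of interest; 0 disables.
#' @return a [SegmentProfile-class].
#' @examples
#' out <- renderEmbryo(embryoSpec(), noise = FALSE)
#' arm <- sumProjection(out$image, role = "arm")
#' armc <- subtractMask(arm, out$truth@membraneTruth)
#' sp <- out$truth@spec
#' roi <- c(sp@marginPx + 1, sp@marginPx + 1, 3 * segmentPeriodPx(sp), 60)
#' prof <- profileAcrossSegments(armc, roi, nSegments = 3L)
#' length(prof@intensity)
#' @export
profileAcrossSegments <- function(armMasked, roi, nSegments = 3L,
                                  pointsPerSegment = 100L,
                                  smoothSigmaPx = 0) {
    rectCheck(roi, dim(armMasked), "profile roi")
    sub <- rectCrop(armMasked, roi)
    colMean <- colMeans(sub)
    if (smoothSigmaPx > 0) {
        r <- ceiling(3 * smoothSigmaPx)
        kern <- exp(-(seq(-r, r))^2 / (2 * smoothSigmaPx^2))
        kern <- kern / sum(kern)
        padded <- c(rev(colMean[seq_len(r)]), colMean,
                    rev(colMean[length(colMean) - seq_len(r) + 1L]))
        colMean <- as.numeric(stats::filter(padded, kern,
                                            sides = 2))[r + seq_along(colMean)]
    }
    nOut <- as.integer(pointsPerSegment) * as.integer(nSegments)
    pos <- seq(0, nSegments, length.out = nOut)
    res <- approx(x = seq(0, nSegments, length.out = length(colMean)),
                  y = colMean, xout = pos)$y
    res <- res - min(res)
    new("SegmentProfile", position = pos, intensity = res, roi = roi,
        nSegments = as.integer(nSegments))
}

#' Count peaks in a segment profile
#'
#' Convenience peak detector for recovery tests: local maxima separated by at
#' least half a segment and rising above `minRel` of the profile maximum.
#'
#' @param profile a [SegmentProfile-class].
#' @param minRel minimum peak height as a fraction of the profile maximum.
#' @return integer number of peaks.
#' @export
countProfilePeaks <- function(profile, minRel = 0.5) {
    v <- profile@intensity
    if (max(v) == 0) return(0L)
    sep <- length(v) / profile@nSegments / 2
    length(findPeaks1d(v, minSep = sep, minHeight = minRel * max(v)))
}

#' Place stripe and interstripe measurement boxes from the Wg channel
#'
#' Detects Wg stripe AP positions as peaks of the column-summed Wg
#' projection and centres measurement boxes on the first `nStripes` stripes;
#' interstripe boxes are centred midway between adjacent stripes. This
#' automates the study's manually drawn boxes spanning the Wg-expressing
#' cells.
#'
#' @param wgProjection numeric `(y, x)` matrix of the Wg channel projection.
#' @param boxShape `c(w, h)` of each box, default 100 x 30 px.
#' @param nStripes stripes to use (default 3, the parasegment-2-to-4
#'   analogue).
#' @param yCenter vertical centre of the boxes; defaults to the foreground
#'   row centroid.
#' @param minSep minimum stripe separation in px; defaults to half the
#'   dominant stripe spacing estimate (a quarter of the image width divided
#'   by `nStripes`).
#' @return list with `stripeBoxes` and `interstripeBoxes`, each a list of
#'   rectangles, plus `stripeX` (detected stripe centres).
#' @export
placeStripeBoxes <- function(wgProjection, boxShape = c(100L, 30L),
                             nStripes = 3L, yCenter = NULL, minSep = NULL) {
    prof <- colSums(wgProjection)
    prof <- prof - min(prof)      # remove the flat background baseline
    if (max(prof) == 0)
        stop("no Wg signal detected: cannot place stripe boxes")
    if (is.null(minSep)) minSep <- ncol(wgProjection) / (2 * (nStripes + 1))
    peaks <- findPeaks1d(prof, minSep = minSep,
                         minHeight = 0.3 * max(prof))
    if (length(peaks) < nStripes)
        stop("detected only ", length(peaks), " Wg stripes; ", nStripes,
             " required")
    ## refine each peak to the centroid of its half-maximum region (peaks
    ## sit on plateaus spanning the stripe cells)
    stripeX <- vapply(peaks[seq_len(nStripes)], function(p) {
        half <- prof[p] / 2
        lo <- p; while (lo > 1L && prof[lo - 1L] >= half) lo <- lo - 1L
        hi <- p; while (hi < length(prof) && prof[hi + 1L] >= half)
            hi <- hi + 1L
        win <- lo:hi
        sum(win * prof[win]) / sum(prof[win])
    }, 0)
    if (is.null(yCenter)) {
        rows <- rowSums(wgProjection)
        yCenter <- if (sum(rows) > 0) sum(seq_along(rows) * rows) / sum(rows)
                   else nrow(wgProjection) / 2
    }
    mkBox <- function(cx) c(round(cx - boxShape[1] / 2),
                            round(yCenter - boxShape[2] / 2),
                            boxShape[1], boxShape[2])
    interX <- if (nStripes > 1L) (stripeX[-1] + stripeX[-nStripes]) / 2
              else stripeX + diff(range(prof > 0)) / 2
    list(stripeBoxes = lapply(stripeX, mkBox),
         interstripeBoxes = lapply(interX, mkBox), stripeX = stripeX)
}

#' Wg-stripe versus interstripe Arm levels
#'
#' Mean gray value of each box, averaged over the stripe boxes and over the
#' interstripe boxes, each minus the background; `difference` is stripe minus
#' interstripe (the background cancels).
#'
#' @param armProjection numeric `(y, x)` matrix (masked or unmasked Arm; both
#'   usages are supported).
#' @param boxes a list as returned by [placeStripeBoxes()].
#' @param background scalar background intensity (see
#'   [estimateBackground()]).
#' @return a [StripeInterstripeResult-class].
#' @export
stripeInterstripe <- function(armProjection, boxes, background = 0) {
    boxMean <- function(b) {
        rectCheck(b, dim(armProjection), "measurement box")
        mean(rectCrop(armProjection, b))
    }
    sMeans <- vapply(boxes$stripeBoxes, boxMean, 0)
    iMeans <- vapply(boxes$interstripeBoxes, boxMean, 0)
    sM <- mean(sMeans) - background
    iM <- mean(iMeans) - background
    new("StripeInterstripeResult", stripeMean = sM, interstripeMean = iM,
        difference = sM - iM, background = background,
        stripeBoxes = boxes$stripeBoxes,
        interstripeBoxes = boxes$interstripeBoxes)
}
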