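#' Threshold an Engrailed max projection
#'
#' Otsu threshold by default (manual override via `threshold`), followed by
#' removal of objects smaller than `minCellArea` -- highlighting
#' En-expressing cells and eliminating background noise.
#'
#' @param maxProjection numeric `(y, x)` matrix.
#' @param threshold manual intensity threshold; pixels strictly above it are
#'   kept (`0` keeps all nonzero pixels). `NULL` uses Otsu.
#' @param minCellArea objects smaller than this many pixels are removed.
#' @return logical `(y, x)` matrix.
#' @export
thresholdEn <- function(maxProjection, threshold = NULL, minCellArea = 9L) {
    if (max(maxProjection) == 0)
        return(matrix(FALSE, nrow(maxProjection), ncol(maxProjection)))
    if (is.null(threshold)) {
        sc <- maxProjection / max(maxProjection)
        threshold <- EBImage::otsu(EBImage::Image(sc)) * max(maxProjection)
    }
    bw <- maxProjection > threshold
    if (minCellArea > 1L && any(bw)) {
        lab <- as.matrix(EBImage::bwlabel(bw))
        sizes <- tabulate(lab[lab > 0])
        bw <- lab > 0 & sizes[pmax(lab, 1L)] >= minCellArea
    }
    bw
}

#' Count rows of En-expressing cells per segment
#'
#' Along each of three lines parallel to the AP axis, the cells crossed in
#' each intersected En band are counted as connected foreground runs
#' separated by membrane gaps; the result is the grand mean over lines and
#' bands (bands 2--5 by default, two lines lateral and one near the
#' midline).
#'
#' @param binary logical `(y, x)` matrix from [thresholdEn()].
#' @param midlineY y coordinate of the midline; defaults to the foreground
#'   row centroid.
#' @param bands En band indices (anterior to posterior) to count.
#' @param nLines number of AP-parallel sampling lines.
#' @param lateralOffsetPx offsets of the lateral lines from the midline
#'   line; defaults to a third of the foreground height. Each line is
#'   snapped to the nearby row with the most foreground so it runs through
#'   cell interiors rather than along a membrane gap.
#' @param gapMin minimum background gap separating two cells on a line, px.
#' @param bandGapTol gaps up to this many px are bridged when grouping
#'   foreground columns into bands (membrane gaps within a band).
#' @return an [EnRowResult-class].
#' @examples
#' en <- renderEnChannel(embryoSpec(nSegments = 6L), noise = FALSE)
#' res <- countEnRows(thresholdEn(en$image, threshold = 0))
#' res@meanRowsPerSegment
#' @export
countEnRows <- function(binary, midlineY = NULL, bands = 2:5, nLines = 3L,
                        lateralOffsetPx = NULL, gapMin = 2L,
                        bandGapTol = NULL) {
    occ <- colSums(binary)
    if (!any(occ > 0)) stop("no En stripes detected in the binary image")
    if (is.null(bandGapTol)) {
        ## bridge intra-band membrane gaps: use the typical cell width scale
        runs <- runIntervals(occ > 0)
        bandGapTol <- max(3L, as.integer(
            round(median(runs[, 2] - runs[, 1] + 1) / 2)))
    }
    iv <- runIntervals(occ > 0, gapTol = bandGapTol)
    if (nrow(iv) < max(bands))
        stop("detected ", nrow(iv), " En bands; bands up to ", max(bands),
             " requested")
    rows <- rowSums(binary)
    if (is.null(midlineY))
        midlineY <- sum(seq_along(rows) * rows) / sum(rows)
    if (is.null(lateralOffsetPx)) {
        fgRows <- range(which(rows > 0))
        lateralOffsetPx <- max(1L, round(diff(fgRows) / 3))
    }
    targets <- round(midlineY + c(-lateralOffsetPx, 0, lateralOffsetPx))
    targets <- targets[seq_len(min(nLines, length(targets)))]
    ## snap each line to the densest nearby row (manual placement picked
    ## lines through cells, not along membrane gaps)
    snap <- vapply(targets, function(t) {
        win <- max(1L, t - 4L):min(nrow(binary), t + 4L)
        win[which.max(rows[win])]
    }, 0L)
    counts <- matrix(0L, length(snap), length(bands),
                     dimnames = list(paste0("line", seq_along(snap)),
                                     paste0("band", bands)))
    for (li in seq_along(snap)) {
        line <- binary[snap[li], ]
        for (bi in seq_along(bands)) {
            b <- iv[bands[bi], ]
            seg <- line[max(1L, b[1] - 1L):min(length(line), b[2] + 1L)]
            r <- runIntervals(seg)
            if (nrow(r) > 1L) {
                gaps <- r[-1, 1] - r[-nrow(r), 2] - 1L
                counts[li, bi] <- 1L + sum(gaps >= gapMin)
            } else counts[li, bi] <- nrow(r)
        }
    }
    new("EnRowResult", perLineCounts = counts,
        meanRowsPerSegment = mean(counts),
        thresholdUsed = NA_real_, linePositions = as.numeric(snap),
        bands = as.integer(bands))
}
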