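#' Classify puncta by compartment and Wg signaling region
#'
#' A punctum is `membrane` when its centroid lies within `dMem` pixels of a
#' membrane-mask pixel, `cytoplasmic` otherwise; its region (`Wg-ON` /
#' `Wg-OFF`) is read from a region map at the centroid.
#'
#' @param puncta data.frame from [detectPuncta()].
#' @param mask a [MembraneMask-class] or logical matrix.
#' @param wgRegionMap logical `(y, x)` matrix, `TRUE` in Wg-ON territory
#'   (see [wgRegionMap()]).
#' @param dMem membrane-proximity threshold, pixels (default 3).
#' @return the table with `compartment` and `region` columns filled.
#' @export
classifyPuncta <- function(puncta, mask, wgRegionMap = NULL, dMem = 3) {
    m <- if (is(mask, "MembraneMask")) mask@mask else mask
    n <- nrow(puncta)
    if (n == 0L) {
        puncta$compartment <- character()
        puncta$region <- character()
        return(puncta)
    }
    if (any(m)) {
        dist <- as.matrix(EBImage::distmap(1 - m))
        near <- dist[cbind(puncta$y, puncta$x)] <= dMem
    } else near <- rep(FALSE, n)
    puncta$compartment <- ifelse(near, "membrane", "cytoplasmic")
    puncta$region <- if (is.null(wgRegionMap)) "unknown" else
        ifelse(wgRegionMap[cbind(puncta$y, puncta$x)], "Wg-ON", "Wg-OFF")
    puncta
}

#' Wg-ON region map from simulator ground truth
#'
#' Marks the pixels of Wg-ON cells, dilated slightly so membrane pixels
#' between two ON cells are covered.
#'
#' @param truth a [GroundTruth-class].
#' @param dilatePx dilation of the ON territory, pixels.
#' @return logical `(y, x)` matrix.
#' @export
wgRegionMap <- function(truth, dilatePx = NULL) {
    if (is.null(dilatePx)) dilatePx <- truth@spec@membraneWidthPx + 1L
    on <- matrix(truth@cellMap > 0 &
                     truth@wgState[pmax(truth@cellMap, 1L)] == 1L,
                 nrow(truth@cellMap), ncol(truth@cellMap))
    as.matrix(EBImage::dilate(
        on + 0, EBImage::makeBrush(2L * dilatePx + 1L, "box"))) > 0
}

#' Structure-class label map from simulator ground truth
#'
#' Builds a `(y, x)` character matrix labelling the structures relevant to
#' brightness ranking: discs of radius `radiusPx` around Wg-OFF cytoplasmic
#' puncta (`"puncta-WgOFF"`) and Wg-ON membrane puncta (`"puncta-WgON"`),
#' remaining Wg-ON cytoplasm (`"cytoplasm-WgON"`) and Wg-OFF cytoplasm
#' (`"cytoplasm-WgOFF"`).
#'
#' @param truth a [GroundTruth-class].
#' @param radiusPx punctum footprint radius, pixels.
#' @return character matrix with `NA` outside the labelled classes.
#' @export
structureClassMap <- function(truth, radiusPx = 2) {
    cm <- truth@cellMap
    on <- matrix(cm > 0 & truth@wgState[pmax(cm, 1L)] == 1L, nrow(cm),
                 ncol(cm))
    off <- matrix(cm > 0 & truth@wgState[pmax(cm, 1L)] == 0L, nrow(cm),
                  ncol(cm))
    lab <- matrix(NA_character_, nrow(cm), ncol(cm))
    lab[on] <- "cytoplasm-WgON"
    lab[off] <- "cytoplasm-WgOFF"
    p <- truth@puncta
    r <- ceiling(radiusPx)
    for (i in seq_len(nrow(p))) {
        yy <- max(1, round(p$y[i]) - r):min(nrow(cm), round(p$y[i]) + r)
        xx <- max(1, round(p$x[i]) - r):min(ncol(cm), round(p$x[i]) + r)
        d2 <- outer((yy - p$y[i])^2, (xx - p$x[i])^2, "+")
        cls <- if (p$region[i] == "Wg-OFF") "puncta-WgOFF" else "puncta-WgON"
        lab[yy, xx][d2 <= radiusPx^2] <- cls
    }
    lab
}

#' Percentile-threshold brightness ranking
#'
#' For each fraction f, the threshold is the (1 - f) intensity quantile over
#' foreground pixels, so the mask holds the brightest f of in-embryo pixels;
#' masks are nested (a larger fraction contains every smaller one). When a
#' class map is supplied, the fraction of each structure class's pixels above
#' each threshold is reported, ranking structure classes by brightness (the
#' brightest 0.1\% of pixels fall in cytoplasmic Wg-OFF puncta, membrane
#' puncta appear by 1\%, the elevated Wg-ON cytoplasm only by 15\%).
#'
#' @param image numeric `(y, x)` matrix (e.g. a GFP max projection).
#' @param foreground logical `(y, x)` matrix of in-embryo pixels.
#' @param fractions strictly increasing fractions in (0, 1]; default
#'   `c(0.001, 0.003, 0.01, 0.15)`.
#' @param classMap optional character matrix from [structureClassMap()].
#' @return list with `thresholds` (named by fraction), `masks` (list of
#'   logical matrices) and `coverage` (data.frame `fraction, class,
#'   coverage`; `NULL` without a class map).
#' @export
percentileThresholdRanking <- function(image, foreground,
                                       fractions = c(0.001, 0.003, 0.01,
                                                     0.15),
                                       classMap = NULL) {
    if (any(diff(fractions) <= 0) || any(fractions <= 0) ||
        any(fractions > 1))
        stop("fractions must be strictly increasing and lie in (0, 1]")
    vals <- image[foreground]
    if (!length(vals)) stop("empty foreground")
    thr <- quantile(vals, probs = 1 - fractions, names = FALSE, type = 7)
    thr[fractions == 1] <- -Inf
    masks <- lapply(thr, function(t) image > t & foreground)
    names(masks) <- names(thr) <- as.character(fractions)
    cov <- NULL
    if (!is.null(classMap)) {
        classes <- sort(unique(classMap[!is.na(classMap)]))
        cov <- do.call(rbind, lapply(seq_along(fractions), function(i) {
            data.frame(fraction = fractions[i], class = classes,
                       coverage = vapply(classes, function(cl) {
                           px <- !is.na(classMap) & classMap == cl &
                               foreground
                           if (!sum(px)) return(NA_real_)
                           sum(masks[[i]] & px) / sum(px)
                       }, 0, USE.NAMES = FALSE))
        }))
        rownames(cov) <- NULL
    }
    list(thresholds = thr, masks = masks, coverage = cov)
}
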