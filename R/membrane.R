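## Membrane segmentation and mask arithmetic.  The study segmented junctions
## with a trained pixel classifier on anti-phosphotyrosine staining; here a
## deterministic pipeline -- Gaussian smoothing, a Hessian-eigenvalue ridge
## filter, hysteresis thresholding and morphological closing -- produces a
## reproducible binary membrane mask from the junction-marker channel.

hessianRidge <- function(img) {
    ny <- nrow(img); nx <- ncol(img)
    pad <- function(m, dy, dx) {
        yy <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
        xx <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
        m[yy, xx]
    }
    Ixx <- pad(img, 0, 1) - 2 * img + pad(img, 0, -1)
    Iyy <- pad(img, 1, 0) - 2 * img + pad(img, -1, 0)
    Ixy <- (pad(img, 1, 1) - pad(img, 1, -1) -
            pad(img, -1, 1) + pad(img, -1, -1)) / 4
    lmin <- ((Ixx + Iyy) - sqrt((Ixx - Iyy)^2 + 4 * Ixy^2)) / 2
    resp <- -lmin
    resp[resp < 0] <- 0
    resp
}

#' Segment the junctional membrane from a junction-marker projection
#'
#' Deterministic replacement for a trained pixel classifier: Gaussian smooth,
#' bright-ridge (Hessian minor eigenvalue) filter, hysteresis threshold,
#' morphological closing and optional dilation. Identical parameters give an
#' identical mask.
#'
#' @param projection numeric `(y, x)` matrix (e.g. the 8-um sum projection of
#'   the junction channel).
#' @param smoothSigma Gaussian pre-smoothing sigma, pixels.
#' @param hi,lo hysteresis thresholds as fractions of the maximum ridge
#'   response; weak components are kept only when they touch a strong pixel.
#' @param closeSize edge length of the box brush used for closing.
#' @param dilatePx extra dilation of the final mask, pixels (0 disables).
#' @return a [MembraneMask-class]. A blank input yields an empty mask with a
#'   warning.
#' @examples
#' out <- renderEmbryo(embryoSpec(), noise = FALSE)
#' jp <- sumProjection(out$image, role = "junction")
#' mask <- segmentMembrane(jp)
#' mask
#' @export
segmentMembrane <- function(projection, smoothSigma = 1, hi = 0.2,
                            lo = 0.05, closeSize = 3L, dilatePx = 0L) {
    params <- list(smoothSigma = smoothSigma, hi = hi, lo = lo,
                   closeSize = closeSize, dilatePx = dilatePx)
    if (all(projection == 0) || max(projection) == min(projection)) {
        if (all(projection == 0))
            warning("blank junction projection: returning an empty mask")
        resp <- matrix(0, nrow(projection), ncol(projection))
    } else {
        sm <- EBImage::gblur(projection / max(projection), sigma = smoothSigma)
        resp <- hessianRidge(as.matrix(sm))
    }
    m <- max(resp)
    if (m == 0)
        return(new("MembraneMask",
                   mask = matrix(FALSE, nrow(projection), ncol(projection)),
                   sourceChannel = "junction", params = params))
    strong <- resp >= hi * m
    weak <- resp >= lo * m
    lab <- as.matrix(EBImage::bwlabel(weak))
    keep <- unique(lab[strong & lab > 0])
    mask <- matrix(lab %in% keep & lab > 0, nrow(lab), ncol(lab))
    if (closeSize > 1L)
        mask <- as.matrix(EBImage::closing(
            mask + 0, EBImage::makeBrush(closeSize, "box"))) > 0
    if (dilatePx > 0L)
        mask <- as.matrix(EBImage::dilate(
            mask + 0, EBImage::makeBrush(2L * dilatePx + 1L, "box"))) > 0
    new("MembraneMask", mask = mask, sourceChannel = "junction",
        params = params)
}

#' Subtract a membrane mask from an image
#'
#' Sets masked pixels to zero, leaving the rest untouched; the identity
#' `sum(output) + sum(input[mask]) == sum(input)` holds exactly.
#'
#' @param image numeric `(y, x)` matrix.
#' @param mask a [MembraneMask-class] or logical matrix of the same shape.
#' @return the masked image.
#' @export
subtractMask <- function(image, mask) {
    m <- if (is(mask, "MembraneMask")) mask@mask else mask
    if (!all(dim(image) == dim(m)))
        stop("image (", paste(dim(image), collapse = "x"),
             ") and mask (", paste(dim(m), collapse = "x"),
             ") shapes differ")
    image[m] <- 0
    image
}

#' Estimate background intensity from a region outside the embryo
#'
#' Mean intensity over a rectangular ROI, used as "the background value from
#' a region outside the embryo". Supplying the foreground mask flags ROIs
#' that overlap the embryo.
#'
#' @param image numeric `(y, x)` matrix.
#' @param roi rectangle `c(x, y, w, h)`; default from [backgroundRoi()].
#' @param foreground optional logical foreground mask used to warn when the
#'   ROI touches the embryo.
#' @return scalar mean intensity.
#' @export
estimateBackground <- function(image, roi = NULL, foreground = NULL) {
    if (is.null(roi)) roi <- backgroundRoi(image, foreground = foreground)
    rectCheck(roi, dim(image), "background roi")
    if (roi[3] * roi[4] < 1) stop("background roi has zero area")
    if (!is.null(foreground) && any(rectCrop(foreground, roi)))
        warning("background roi overlaps the foreground")
    mean(rectCrop(image, roi))
}

#' Default background ROI: a box at the image corner farthest from the
#' foreground
#'
#' @param image numeric `(y, x)` matrix (used for its shape).
#' @param size `c(w, h)` of the box, default 30 x 30 px.
#' @param foreground optional logical mask; its centroid decides which corner
#'   is farthest (image centre assumed when absent).
#' @return rectangle `c(x, y, w, h)`.
#' @export
backgroundRoi <- function(image, size = c(30L, 30L), foreground = NULL) {
    ny <- nrow(image); nx <- ncol(image)
    size <- c(min(size[1], nx), min(size[2], ny))
    cen <- if (!is.null(foreground) && any(foreground)) {
        idx <- which(foreground, arr.ind = TRUE)
        c(mean(idx[, 2]), mean(idx[, 1]))
    } else c((nx + 1) / 2, (ny + 1) / 2)
    corners <- rbind(c(1, 1), c(nx - size[1] + 1, 1),
                     c(1, ny - size[2] + 1),
                     c(nx - size[1] + 1, ny - size[2] + 1))
    mid <- cbind(corners[, 1] + size[1] / 2, corners[, 2] + size[2] / 2)
    far <- which.max((mid[, 1] - cen[1])^2 + (mid[, 2] - cen[2])^2)
    c(corners[far, 1], corners[far, 2], size[1], size[2])
}

#' Foreground (in-embryo) mask
#'
#' Thresholds a smoothed sum of all channels above the off-specimen
#' background, estimated from the image border frame (the specimen is
#' assumed not to touch the border): threshold = border median + `k` robust
#' sds of the smoothed border. Small gaps are closed, the largest connected
#' component kept and its holes filled, so the result is a single connected
#' region restricted to in-embryo pixels.
#'
#' @param image an [EmbryoImage-class] (all channels are summed over z) or a
#'   numeric `(y, x)` matrix.
#' @param smoothSigma Gaussian smoothing sigma, pixels.
#' @param borderPx width of the border frame used for the background
#'   estimate.
#' @param k threshold multiplier on the robust background sd.
#' @param closeSize box-brush size bridging small gaps before the
#'   largest-component step.
#' @return logical `(y, x)` matrix.
#' @export
foregroundMask <- function(image, smoothSigma = 2, borderPx = 8L, k = 6,
                           closeSize = 5L) {
    proj <- if (is(image, "EmbryoImage")) {
        apply(image@data, c(3, 4), sum)
    } else image
    if (max(proj) == 0)
        return(matrix(FALSE, nrow(proj), ncol(proj)))
    sm <- as.matrix(EBImage::gblur(proj / max(proj), sigma = smoothSigma)) *
        max(proj)
    ny <- nrow(sm); nx <- ncol(sm)
    b <- min(borderPx, floor(min(ny, nx) / 4))
    border <- c(sm[seq_len(b), ], sm[(ny - b + 1):ny, ],
                sm[, seq_len(b)], sm[, (nx - b + 1):nx])
    thr <- median(border) + k * max(mad(border), 1e-8)
    bw <- sm > thr
    if (!any(bw)) return(matrix(FALSE, ny, nx))
    if (closeSize > 1L)
        bw <- as.matrix(EBImage::closing(
            bw + 0, EBImage::makeBrush(as.integer(closeSize), "box"))) > 0
    lab <- as.matrix(EBImage::bwlabel(bw))
    big <- which.max(tabulate(lab[lab > 0]))
    mask <- lab == big
    as.matrix(EBImage::fillHull(mask + 0)) > 0
}
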