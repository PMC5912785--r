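#' Sum and maximum intensity projections over a physical depth
#'
#' Projects `ceiling(depthUm / zStepUm)` consecutive slices starting at
#' `zOrigin`, matching the study's 8-um-deep projections into the embryo.
#'
#' @param stack numeric `(z, y, x)` array, or an [EmbryoImage-class] together
#'   with `role`.
#' @param depthUm projection depth in micrometres (> 0).
#' @param zOrigin first slice of the projection (1-based).
#' @param zStepUm z spacing in micrometres (taken from the image when an
#'   [EmbryoImage-class] is given).
#' @param role channel role when projecting an [EmbryoImage-class].
#' @return numeric `(y, x)` matrix.
#' @examples
#' out <- renderEmbryo(embryoSpec(), noise = FALSE)
#' arm <- sumProjection(out$image, depthUm = 8, role = "arm")
#' dim(arm)
#' @export
sumProjection <- function(stack, depthUm = 8, zOrigin = NULL, zStepUm = 1,
                          role = "arm") {
    projectStack(stack, depthUm, zOrigin, zStepUm, role, fun = "sum")
}

#' @rdname sumProjection
#' @export
maxProjection <- function(stack, depthUm = 8, zOrigin = NULL, zStepUm = 1,
                          role = "arm") {
    projectStack(stack, depthUm, zOrigin, zStepUm, role, fun = "max")
}

projectStack <- function(stack, depthUm, zOrigin, zStepUm, role, fun) {
    if (is(stack, "EmbryoImage")) {
        img <- stack
        zStepUm <- img@zStepUm
        if (is.null(zOrigin))
            zOrigin <- if (!is.null(img@meta$signalSlices))
                img@meta$signalSlices[1] else 1L
        stack <- channelData(img, role)
    } else if (is.null(zOrigin)) zOrigin <- 1L
    stopifnot(length(dim(stack)) == 3L)
    if (depthUm <= 0) stop("depthUm must be > 0")
    n <- ceiling(depthUm / zStepUm)
    nz <- dim(stack)[1]
    if (zOrigin < 1L || zOrigin > nz)
        stop("zOrigin outside the stack (1..", nz, ")")
    if (zOrigin + n - 1L > nz)
        stop(sprintf(
            "projection depth %g um (%d slices) exceeds the %g um available below slice %d",
            depthUm, n, (nz - zOrigin + 1) * zStepUm, zOrigin))
    sl <- stack[zOrigin:(zOrigin + n - 1L), , , drop = FALSE]
    if (fun == "sum") colSums(sl) else apply(sl, c(2, 3), max)
}

#' Rotate an embryo image to canonical orientation
#'
#' Canonical orientation places the anterior at low x with the midline
#' centred. Only axis flips are applied (no interpolation), so a double flip
#' is the identity.
#'
#' @param image an [EmbryoImage-class].
#' @param flipAP mirror the AP (x) axis.
#' @param flipDV mirror the DV (y) axis.
#' @return the flipped [EmbryoImage-class] with `orientation = "canonical"`.
#' @export
rotateToCanonical <- function(image, flipAP = FALSE, flipDV = FALSE) {
    stopifnot(is(image, "EmbryoImage"))
    d <- dim(image@data)
    data <- image@data
    if (flipAP) data <- data[, , , d[4]:1, drop = FALSE]
    if (flipDV) data <- data[, , d[3]:1, , drop = FALSE]
    initialize(image, data = data, orientation = "canonical")
}
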