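## Synthetic embryo rendering.  The cell field is a rectangular lattice of
## cells separated by thin junctional membrane lines; one cell column per
## segment expresses Wg.  All projected signal levels are defined on the
## sum projection over the embryo's signal slices, so analysis of the
## canonical 8-um projection recovers the configured parameters directly.

## Lattice geometry: cell label map, membrane truth and per-cell table.
latticeGeometry <- function(spec) {
    d <- spec@cellDiameterPx
    w <- spec@membraneWidthPx
    m <- spec@marginPx
    ncol <- spec@nSegments * spec@cellsPerSegment
    nrow <- spec@cellRows
    ny <- spec@imageShape[2]
    nx <- spec@imageShape[3]
    x0 <- m
    y0 <- m
    ## lattice spans x0+1 .. x0+ncol*d+w (closing membrane line on the far
    ## side), similarly in y
    xs <- seq_len(nx)
    ys <- seq_len(ny)
    inX <- xs > x0 & xs <= x0 + ncol * d + w
    inY <- ys > y0 & ys <= y0 + nrow * d + w
    memX <- inX & (((xs - x0 - 1L) %% d) < w | xs > x0 + ncol * d)
    memY <- inY & (((ys - y0 - 1L) %% d) < w | ys > y0 + nrow * d)
    membrane <- outer(memY & inY, inX) | outer(inY, memX & inX)
    foreground <- outer(inY, inX)
    ## cell ids: column-major over (row, col); 0 on membrane/background
    colIdx <- ifelse(inX & !memX, pmin((xs - x0 - 1L) %/% d + 1L, ncol), 0L)
    rowIdx <- ifelse(inY & !memY, pmin((ys - y0 - 1L) %/% d + 1L, nrow), 0L)
    cellMap <- outer(rowIdx, colIdx, function(r, c)
        ifelse(r > 0L & c > 0L, (c - 1L) * nrow + r, 0L))
    ## Wg stripe: centre column of each segment, plus halo
    sc <- (spec@cellsPerSegment + 1L) %/% 2L
    segOfCol <- (seq_len(ncol) - 1L) %/% spec@cellsPerSegment + 1L
    posInSeg <- (seq_len(ncol) - 1L) %% spec@cellsPerSegment + 1L
    half <- (spec@wgStripeWidthCells - 1L) %/% 2L
    isStripeCol <- abs(posInSeg - sc) <= half
    isOnCol <- abs(posInSeg - sc) <= half + spec@wgOnHaloCells
    cells <- data.frame(
        id = seq_len(ncol * nrow),
        col = rep(seq_len(ncol), each = nrow),
        row = rep(seq_len(nrow), times = ncol))
    cells$segment <- segOfCol[cells$col]
    cells$wgStripe <- isStripeCol[cells$col]
    cells$wgOn <- isOnCol[cells$col]
    cells$cx <- x0 + (cells$col - 0.5) * d + w / 2
    cells$cy <- y0 + (cells$row - 0.5) * d + w / 2
    stripeX <- x0 + ((seq_len(spec@nSegments) - 1L) * spec@cellsPerSegment +
                         sc - 0.5) * d + w / 2
    list(cellMap = cellMap, membrane = membrane, foreground = foreground,
         cells = cells, stripeX = stripeX, x0 = x0, y0 = y0,
         interiorX = inX & !memX, interiorY = inY & !memY)
}

## Smooth periodic AP bump profile peaking at Wg stripe centres.
apBump <- function(xs, stripeX, sigma) {
    b <- numeric(length(xs))
    for (s in stripeX) b <- b + exp(-((xs - s)^2) / (2 * sigma^2))
    b
}

## Effective cytoplasmic stripe increment: armStripeAmplitude is defined as
## the expected stripe-minus-interstripe difference of box means of the
## membrane-subtracted projection, measured with the default geometry
## (100 x 30 px boxes centred on stripe and interstripe positions).  The
## per-pixel gain is obtained by measuring a unit-amplitude bump rendered on
## the cytoplasmic pixels with exactly that geometry.
amplitudeCalibration <- function(spec, geo) {
    d <- spec@cellDiameterPx
    ny <- spec@imageShape[2]; nx <- spec@imageShape[3]
    xs <- seq_len(nx)
    bump <- apBump(xs, geo$stripeX, sigma = d)
    unit <- matrix(bump, ny, nx, byrow = TRUE)
    unit[!(geo$foreground & !geo$membrane)] <- 0
    halfW <- (5L * d) %/% 2L
    yc <- spec@marginPx +
        (spec@cellRows * d + spec@membraneWidthPx) / 2
    yy <- max(1, round(yc) - 15L):min(ny, round(yc) + 14L)
    boxMean <- function(cx) {
        sel <- max(1, round(cx) - halfW):min(nx, round(cx) + halfW - 1L)
        mean(unit[yy, sel])
    }
    interX <- geo$stripeX[-length(geo$stripeX)] + segmentPeriodPx(spec) / 2
    if (!length(interX)) interX <- geo$stripeX + segmentPeriodPx(spec) / 2
    unitDiff <- mean(vapply(geo$stripeX, boxMean, 0)) -
        mean(vapply(interX, boxMean, 0))
    list(bump = bump, gain = 1 / unitDiff)
}

#' Render a synthetic multi-channel embryo stack with ground truth
#'
#' Produces a 4-channel Z stack (junction marker, Arm, Wg, GFP) of a
#' segmented epithelium in canonical orientation (anterior at low x). The Arm
#' channel splits total Arm between the junctional lattice
#' (`junctionalFraction` of the total) and a cytoplasmic pool whose
#' anteroposterior profile peaks at the Wg stripes. The GFP channel contains
#' destruction-complex puncta -- 3-D Gaussian spots whose integrated photon
#' count is `molecules * brightnessPerMolecule` -- placed in the cytoplasm of
#' Wg-OFF cells and adjacent to the membrane in Wg-ON cells, over a diffuse
#' cytoplasmic level that is elevated in Wg-ON cells. Noise is Poisson shot
#' noise plus Gaussian read noise, hard-clipped at the camera ceiling.
#' Identical spec and seed give identical output.
#'
#' @param spec an [EmbryoSpec-class].
#' @param noise apply the camera noise model (`FALSE` renders the noiseless
#'   expectation plus the constant background offset).
#' @param seed random seed; defaults to `spec@seed`.
#' @return list with `image` (an [EmbryoImage-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' out <- renderEmbryo(embryoSpec(), noise = FALSE)
#' out$image
#' f <- sum(out$truth@armJunctional) /
#'     sum(out$truth@armJunctional + out$truth@armCytoplasmic)
#' round(f, 3)   # the configured junctional fraction
#' @export
renderEmbryo <- function(spec, noise = TRUE, seed = spec@seed) {
    validObject(spec)
    set.seed(mixSeed(seed, 1L))
    geo <- latticeGeometry(spec)
    dimZYX <- spec@imageShape
    nz <- dimZYX[1]; ny <- dimZYX[2]; nx <- dimZYX[3]
    zSig <- spec@signalSlices[1]:spec@signalSlices[2]
    nSig <- length(zSig)

    cal <- amplitudeCalibration(spec, geo)
    profile <- spec@armBaseLevel +
        spec@armStripeAmplitude * cal$gain * cal$bump
    cytoPx <- geo$foreground & !geo$membrane
    profImg <- matrix(profile, ny, nx, byrow = TRUE)

    ## junctional pool normalised per lattice period (one cell column plus
    ## its left membrane line) so that junctional / total Arm equals the
    ## configured fraction exactly within every period, hence within any
    ## period-aligned ROI and globally
    f <- spec@junctionalFraction
    armCyto <- ifelse(cytoPx, profImg, 0)
    armJunc <- ifelse(geo$membrane, profImg, 0)
    if (f == 0 || sum(armJunc) == 0) {
        armJunc[] <- 0
    } else if (f == 1) {
        armCyto[] <- 0
    } else {
        d <- spec@cellDiameterPx
        ncolCell <- spec@nSegments * spec@cellsPerSegment
        xsIdx <- seq_len(nx)
        pIdx <- pmin(pmax((xsIdx - geo$x0 - 1L) %/% d + 1L, 1L), ncolCell)
        pIdx[xsIdx <= geo$x0 | !apply(geo$membrane | cytoPx, 2, any)] <- NA
        for (p in seq_len(ncolCell)) {
            cols <- which(!is.na(pIdx) & pIdx == p)
            cp <- sum(armCyto[, cols])
            jp <- sum(armJunc[, cols])
            if (jp > 0)
                armJunc[, cols] <- armJunc[, cols] * (f / (1 - f)) * cp / jp
        }
    }

    ## Wg channel: stripe-cell cytoplasm; junction channel: membrane lattice
    stripeCells <- geo$cells$id[geo$cells$wgStripe]
    onCells <- geo$cells$id[geo$cells$wgOn]
    wgImg <- ifelse(matrix(geo$cellMap %in% stripeCells, ny, nx), spec@wgLevel,
                    0)
    juncImg <- ifelse(geo$membrane, spec@junctionLevel, 0)

    ## diffuse GFP
    onPx <- matrix(geo$cellMap %in% onCells, ny, nx)
    gfpDiffuse <- ifelse(cytoPx, ifelse(onPx, spec@gfpDiffuseOn,
                                        spec@gfpDiffuseOff), 0)

    ## puncta: one per cell; counts log-normal, clipped to the configured
    ## range; Wg-OFF in cytoplasm, Wg-ON within 2 px of the membrane
    cells <- geo$cells
    ncell <- nrow(cells)
    meanOf <- ifelse(cells$wgOn, spec@punctaWgonCountMean,
                     spec@punctaWgoffCountMean)
    disp <- spec@punctaCountDispersion
    mol <- rlnorm(ncell, meanlog = log(meanOf) - disp^2 / 2, sdlog = disp)
    mol <- pmin(pmax(mol, spec@punctaCountRange[1]), spec@punctaCountRange[2])
    d <- spec@cellDiameterPx; w <- spec@membraneWidthPx
    halfIn <- (d - w) / 2
    zChoices <- zSig[zSig > min(zSig) & zSig < max(zSig)]
    pz <- sample(zChoices, ncell, replace = TRUE)
    px <- py <- numeric(ncell)
    inset <- 4                        # cytoplasmic clearance from membrane
    minSepPx <- 11                    # puncta closer than this are not
                                      # resolvable as separate structures
    draw <- function(i) {
        if (cells$wgOn[i]) {
            ## membrane-proximal: just inside a randomly chosen cell edge
            side <- sample(4L, 1L)
            off <- halfIn - w / 2 - 1      # ~2 px from the membrane line
            u <- runif(1, -halfIn + inset, halfIn - inset)
            c(cells$cx[i] + switch(side, off, -off, u, u),
              cells$cy[i] + switch(side, u, u, off, -off))
        } else {
            c(cells$cx[i] + runif(1, -halfIn + inset, halfIn - inset),
              cells$cy[i] + runif(1, -halfIn + inset, halfIn - inset))
        }
    }
    for (i in seq_len(ncell)) {
        for (try in 1:60) {
            p <- draw(i)
            prev <- seq_len(i - 1L)
            if (i == 1L ||
                all((px[prev] - p[1])^2 + (py[prev] - p[2])^2 >=
                        minSepPx^2)) break
        }
        px[i] <- p[1]; py[i] <- p[2]
    }
    gfpStack <- array(0, dim = c(nz, ny, nx))
    for (z in seq_along(zSig))
        gfpStack[zSig[z], , ] <- gfpDiffuse / nSig
    for (i in seq_len(ncell))
        gfpStack <- addSpot(gfpStack, pz[i], py[i], px[i],
                            mol[i] * spec@brightnessPerMolecule,
                            spec@psfSigmaPx, spec@psfSigmaZ)

    ## assemble channels; projected 2-D signals spread evenly over zSig
    data <- array(0, dim = c(4L, nz, ny, nx))
    for (z in seq_along(zSig)) {
        data[1L, zSig[z], , ] <- juncImg / nSig
        data[2L, zSig[z], , ] <- (armJunc + armCyto) / nSig
        data[3L, zSig[z], , ] <- wgImg / nSig
    }
    data[4L, , , ] <- gfpStack

    if (spec@attenuationPerUm > 0) {
        depth <- (seq_len(nz) - 1) * spec@zStepUm
        att <- exp(-spec@attenuationPerUm * depth)
        for (z in seq_len(nz)) data[, z, , ] <- data[, z, , ] * att[z]
    }

    for (ch in 1:4)
        data[ch, , , ] <- applyCamera(array(data[ch, , , ], c(nz, ny, nx)),
                                      spec@backgroundOffset, spec@readNoiseSd,
                                      spec@saturationLevel, noise = noise)

    image <- new("EmbryoImage", data = data,
                 channelRoles = c(junction = 1L, arm = 2L, wg = 3L,
                                  gfp = 4L),
                 pixelSizeUm = spec@pixelSizeUm, zStepUm = spec@zStepUm,
                 orientation = "canonical",
                 meta = list(signalSlices = spec@signalSlices,
                             opticsId = opticsId(spec)))
    puncta <- data.frame(
        id = cells$id, z = pz, y = py, x = px,
        compartment = ifelse(cells$wgOn, "membrane", "cytoplasmic"),
        region = ifelse(cells$wgOn, "Wg-ON", "Wg-OFF"),
        molecules = mol)
    truth <- new("GroundTruth", cellMap = geo$cellMap,
                 wgState = as.integer(cells$wgOn[order(cells$id)]),
                 membraneTruth = geo$membrane, armJunctional = armJunc,
                 armCytoplasmic = armCyto, puncta = puncta,
                 enRows = spec@enRowsPerSegment, spec = spec)
    list(image = image, truth = truth)
}

#' Imaging-settings identifier of a spec
#'
#' Standards can only calibrate puncta acquired under the same settings
#' ("same settings on the same day"); this id captures the optical and camera
#' parameters that must match.
#'
#' @param spec an [EmbryoSpec-class] or [StandardSpec-class].
#' @return character id.
#' @export
opticsId <- function(spec) {
    paste0("b", spec@brightnessPerMolecule, "_s", spec@psfSigmaPx, "x",
           spec@psfSigmaZ, "_r", spec@readNoiseSd, "_o",
           spec@backgroundOffset, "_c", spec@saturationLevel)
}

#' Ground-truth Wg stripe centres (x positions)
#' @param truth a [GroundTruth-class].
#' @return numeric x coordinates of the stripe centres.
#' @export
trueStripeCenters <- function(truth) {
    latticeGeometry(truth@spec)$stripeX
}
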