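#' Construct an EmbryoSpec
#'
#' Builds a validated [EmbryoSpec-class]. Defaults describe a stage-9-like
#' wild-type embryo: three segments of six 20-px (5 um) cell columns, eight
#' cell rows, a single Wg-expressing column per segment, 70\% of total Arm on
#' the junctional lattice, per-punctum molecule counts log-normal around 260
#' (Wg-OFF) / 130 (Wg-ON) molecules clipped to 46--931, and Poisson + Gaussian
#' camera noise under a 16-bit saturation ceiling.
#'
#' @param nSegments,cellsPerSegment,cellRows,cellDiameterPx,membraneWidthPx,marginPx
#'   lattice geometry (see [EmbryoSpec-class]).
#' @param imageShape integer `(z, y, x)`; `NULL` derives the smallest shape
#'   holding the lattice plus margins.
#' @param signalSlices z range occupied by the embryo; `NULL` centres an
#'   8-slice band.
#' @param pixelSizeUm,zStepUm voxel calibration.
#' @param junctionalFraction fraction of Arm on the junctions (default 0.70).
#' @param armBaseLevel,armStripeAmplitude cytoplasmic Arm levels (projected
#'   counts): interstripe base and stripe-peak increment.
#' @param wgStripeWidthCells,wgOnHaloCells Wg stripe width and signaling halo.
#' @param punctaWgoffCountMean,punctaWgonCountMean,punctaCountRange,punctaCountDispersion
#'   per-punctum molecule-count distribution.
#' @param brightnessPerMolecule,psfSigmaPx,psfSigmaZ optical model.
#' @param gfpDiffuseOff,gfpDiffuseOn,junctionLevel,wgLevel channel levels.
#' @param readNoiseSd,backgroundOffset,saturationLevel,attenuationPerUm
#'   noise/camera model.
#' @param enRowsPerSegment En-positive cell columns per segment (default 2).
#' @param seed base random seed.
#' @return an [EmbryoSpec-class] object.
#' @examples
#' spec <- embryoSpec()
#' segmentPeriodPx(spec)
#' @export
embryoSpec <- function(nSegments = 3L, cellsPerSegment = 6L, cellRows = 8L,
                       cellDiameterPx = 20L, membraneWidthPx = 2L,
                       marginPx = 32L, imageShape = NULL, signalSlices = NULL,
                       pixelSizeUm = 0.25, zStepUm = 1,
                       junctionalFraction = 0.70, armBaseLevel = 20,
                       armStripeAmplitude = 60, wgStripeWidthCells = 1L,
                       wgOnHaloCells = 1L, punctaWgoffCountMean = 260,
                       punctaWgonCountMean = 130,
                       punctaCountRange = c(46, 931),
                       punctaCountDispersion = 0.5,
                       brightnessPerMolecule = 80, psfSigmaPx = 1.5,
                       psfSigmaZ = 1, gfpDiffuseOff = 10, gfpDiffuseOn = 30,
                       junctionLevel = 150, wgLevel = 100, readNoiseSd = 2,
                       backgroundOffset = 5, saturationLevel = 65535,
                       attenuationPerUm = 0, enRowsPerSegment = 2L,
                       seed = 1L) {
    period <- as.integer(cellsPerSegment) * as.integer(cellDiameterPx)
    if (is.null(imageShape)) {
        imageShape <- c(12L,
                        as.integer(cellRows) * as.integer(cellDiameterPx) +
                            2L * as.integer(marginPx),
                        as.integer(nSegments) * period +
                            2L * as.integer(marginPx))
    }
    imageShape <- as.integer(imageShape)
    if (is.null(signalSlices)) {
        nz <- imageShape[1]
        n <- min(8L, nz)
        lo <- max(1L, (nz - n) %/% 2L + 1L)
        signalSlices <- c(lo, lo + n - 1L)
    }
    new("EmbryoSpec", nSegments = as.integer(nSegments),
        cellsPerSegment = as.integer(cellsPerSegment),
        cellRows = as.integer(cellRows),
        cellDiameterPx = as.integer(cellDiameterPx),
        membraneWidthPx = as.integer(membraneWidthPx),
        marginPx = as.integer(marginPx), imageShape = imageShape,
        signalSlices = as.integer(signalSlices),
        pixelSizeUm = pixelSizeUm, zStepUm = zStepUm,
        junctionalFraction = junctionalFraction,
        armBaseLevel = armBaseLevel,
        armStripeAmplitude = armStripeAmplitude,
        wgStripeWidthCells = as.integer(wgStripeWidthCells),
        wgOnHaloCells = as.integer(wgOnHaloCells),
        punctaWgoffCountMean = punctaWgoffCountMean,
        punctaWgonCountMean = punctaWgonCountMean,
        punctaCountRange = as.numeric(punctaCountRange),
        punctaCountDispersion = punctaCountDispersion,
        brightnessPerMolecule = brightnessPerMolecule,
        psfSigmaPx = psfSigmaPx, psfSigmaZ = psfSigmaZ,
        gfpDiffuseOff = gfpDiffuseOff, gfpDiffuseOn = gfpDiffuseOn,
        junctionLevel = junctionLevel, wgLevel = wgLevel,
        readNoiseSd = readNoiseSd, backgroundOffset = backgroundOffset,
        saturationLevel = saturationLevel,
        attenuationPerUm = attenuationPerUm,
        enRowsPerSegment = as.integer(enRowsPerSegment),
        seed = as.integer(seed))
}

#' Construct a StandardSpec
#'
#' Defaults follow the yeast kinetochore-cluster standards used for GFP
#' molecule counting: Ndc80 clusters carry 306 GFP molecules, Mif2 clusters
#' 58. Optical and noise parameters default to the [embryoSpec()] values so
#' standards and embryos share one imaging configuration.
#'
#' @param name label; `"Ndc80"` and `"Mif2"` select their known molecule
#'   numbers automatically.
#' @param moleculesPerStructure known molecules per structure; default from
#'   `name` (306 for Ndc80, 58 for Mif2).
#' @param nStructures spots to render (default 40).
#' @param gridSpacingPx spacing of the jittered placement grid (default 30).
#' @param nSlices stack depth (default 9).
#' @param brightnessPerMolecule,psfSigmaPx,psfSigmaZ,readNoiseSd,backgroundOffset,saturationLevel
#'   optical/noise model, matching [embryoSpec()] defaults.
#' @param seed random seed.
#' @return a [StandardSpec-class] object.
#' @examples
#' standardSpec("Ndc80")@moleculesPerStructure
#' @export
standardSpec <- function(name = "Ndc80", moleculesPerStructure = NULL,
                         nStructures = 40L, gridSpacingPx = 30L,
                         nSlices = 9L, brightnessPerMolecule = 80,
                         psfSigmaPx = 1.5, psfSigmaZ = 1, readNoiseSd = 2,
                         backgroundOffset = 5, saturationLevel = 65535,
                         seed = 1L) {
    if (is.null(moleculesPerStructure)) {
        known <- c(Ndc80 = 306, Mif2 = 58)
        if (!name %in% names(known))
            stop("moleculesPerStructure must be given for standard '", name,
                 "' (known standards: ", paste(names(known), collapse = ", "),
                 ")")
        moleculesPerStructure <- known[[name]]
    }
    new("StandardSpec", name = name,
        moleculesPerStructure = moleculesPerStructure,
        nStructures = as.integer(nStructures),
        gridSpacingPx = as.integer(gridSpacingPx),
        nSlices = as.integer(nSlices),
        brightnessPerMolecule = brightnessPerMolecule,
        psfSigmaPx = psfSigmaPx, psfSigmaZ = psfSigmaZ,
        readNoiseSd = readNoiseSd, backgroundOffset = backgroundOffset,
        saturationLevel = saturationLevel, seed = as.integer(seed))
}

#' Segment period of an EmbryoSpec, in pixels
#' @param spec an [EmbryoSpec-class].
#' @return integer pixels per segment along the AP axis.
#' @export
segmentPeriodPx <- function(spec) {
    spec@cellsPerSegment * spec@cellDiameterPx
}

#' @describeIn embryoSpec compact display
#' @param object an `EmbryoSpec`.
#' @export
setMethod("show", "EmbryoSpec", function(object) {
    cat("EmbryoSpec:", object@nSegments, "segments x",
        object@cellsPerSegment, "cells (period",
        segmentPeriodPx(object), "px), stack",
        paste(object@imageShape, collapse = " x "),
        "(z y x)\n  junctional fraction", object@junctionalFraction,
        "| puncta means", object@punctaWgoffCountMean, "/",
        object@punctaWgonCountMean, "molecules | seed", object@seed, "\n")
})

#' @describeIn standardSpec compact display
#' @param object a `StandardSpec`.
#' @export
setMethod("show", "StandardSpec", function(object) {
    cat("StandardSpec", object@name, "-", object@moleculesPerStructure,
        "molecules/structure,", object@nStructures, "structures\n")
})

setMethod("show", "EmbryoImage", function(object) {
    d <- dim(object@data)
    cat("EmbryoImage:", d[1], "channels,", d[2], "slices,", d[3], "x", d[4],
        "px (", object@orientation, ")\n  roles:",
        paste(names(object@channelRoles), object@channelRoles, sep = "=",
              collapse = ", "), "\n")
})

setMethod("show", "MembraneMask", function(object) {
    cat("MembraneMask from", object@sourceChannel, "channel:",
        sum(object@mask), "of", length(object@mask), "pixels (",
        round(100 * mean(object@mask), 1), "% )\n")
})

setMethod("show", "PoolResult", function(object) {
    cat("PoolResult over", object@roiArea, "px ROI\n",
        " membrane:", signif(object@membraneIntensity, 6), "(",
        round(100 * object@membraneIntensity / object@totalIntensity, 1),
        "% of total ),", object@membraneArea, "px\n",
        " cytoplasmic/nuclear:", signif(object@cytoplasmicIntensity, 6),
        ",", object@cytoplasmicArea, "px\n")
})

setMethod("show", "StripeInterstripeResult", function(object) {
    cat("Stripe/interstripe Arm levels:\n  stripe",
        signif(object@stripeMean, 6), "| interstripe",
        signif(object@interstripeMean, 6), "| difference",
        signif(object@difference, 6), "\n")
})

setMethod("show", "EnRowResult", function(object) {
    cat("En rows per segment:", round(object@meanRowsPerSegment, 2),
        "( lines at y =", paste(object@linePositions, collapse = ", "),
        "; bands", paste(range(object@bands), collapse = "-"), ")\n")
})

setMethod("show", "CalibrationStandard", function(object) {
    cat("CalibrationStandard", object@name, ":", object@molecules,
        "molecules,", object@nStructures, "structures, per-structure",
        signif(object@perStructureIntensity, 6), "+/-",
        signif(object@intensitySd, 4), "counts\n")
})

setMethod("show", "FoldMeasure", function(object) {
    cat(sprintf("FoldMeasure %s : %s = %.2f +/- %.2f (n = %d blots)\n",
                object@numerator, object@denominator, object@fold,
                object@sd, object@nBlots))
})

#' Extract one channel of an EmbryoImage as a (z, y, x) stack
#'
#' @param image an [EmbryoImage-class].
#' @param role channel role (`"junction"`, `"arm"`, `"wg"`, `"gfp"`) or a
#'   channel index.
#' @return numeric 3-D array `(z, y, x)`.
#' @examples
#' img <- renderEmbryo(embryoSpec(), noise = FALSE)$image
#' dim(channelData(img, "arm"))
#' @export
channelData <- function(image, role) {
    stopifnot(is(image, "EmbryoImage"))
    idx <- if (is.character(role)) {
        if (!role %in% names(image@channelRoles))
            stop("channel role '", role, "' not present (have: ",
                 paste(names(image@channelRoles), collapse = ", "), ")")
        image@channelRoles[[role]]
    } else as.integer(role)
    d <- dim(image@data)
    array(image@data[idx, , , ], dim = d[2:4])
}

#' @rdname MembraneMask-class
#' @param mask a [MembraneMask-class].
#' @return `maskData()`: the logical matrix.
#' @export
maskData <- function(mask) {
    stopifnot(is(mask, "MembraneMask"))
    mask@mask
}
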