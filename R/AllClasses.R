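## Central S4 containers. Geometry convention: arrays are indexed
## (channel, z, y, x); 2-D images are (y, x) matrices; coordinates are 1-based
## with the AP axis along x (anterior at low x in canonical orientation).
## Rectangles are length-4 numeric vectors c(x, y, w, h), 1-based top-left.

#' EmbryoSpec: parameters of the synthetic segmented-embryo generator
#'
#' Describes the geometry, signal levels and noise model of a synthetic
#' multi-channel embryo stack. Cells sit on a rectangular lattice separated by
#' thin junctional membrane lines; each segment is `cellsPerSegment` cell
#' columns wide with one Wg-expressing column per segment. A configurable
#' fraction of total Arm (default 70\%) is placed on the junctional lattice,
#' the remainder in cytoplasm with a smooth periodic anteroposterior profile
#' peaking at the Wg stripes. Destruction-complex puncta carry log-normal
#' molecule counts (clipped to `punctaCountRange`): bright cytoplasmic puncta
#' in Wg-OFF cells, dimmer membrane-proximal puncta in Wg-ON cells.
#'
#' @slot nSegments number of segments along the AP axis.
#' @slot cellsPerSegment cell columns per segment (segment period =
#'   `cellsPerSegment * cellDiameterPx` pixels).
#' @slot cellRows cell rows along the DV axis.
#' @slot cellDiameterPx cell pitch in pixels (membrane line included).
#' @slot membraneWidthPx width of junctional membrane lines, pixels.
#' @slot marginPx cell-free border around the lattice (background region).
#' @slot imageShape integer `(z, y, x)` stack shape.
#' @slot signalSlices integer range of z slices occupied by the embryo.
#' @slot pixelSizeUm,zStepUm pixel size and z spacing, micrometres.
#' @slot junctionalFraction fraction of total Arm on the junctional lattice.
#' @slot armBaseLevel,armStripeAmplitude cytoplasmic Arm level in interstripes
#'   and added level at stripe centres, in counts on the 8-um sum projection.
#' @slot wgStripeWidthCells width of the Wg-expressing stripe, cells.
#' @slot wgOnHaloCells cell columns on each side of the stripe that still
#'   receive Wg signal (Wg-ON region = stripe + halo).
#' @slot punctaWgoffCountMean,punctaWgonCountMean mean molecules per punctum
#'   in Wg-OFF (cytoplasmic) and Wg-ON (membrane) cells.
#' @slot punctaCountRange `(min, max)` clip range for molecules per punctum.
#' @slot punctaCountDispersion log-space sd of per-punctum molecule counts.
#' @slot brightnessPerMolecule integrated counts contributed per GFP molecule.
#' @slot psfSigmaPx,psfSigmaZ Gaussian PSF sigma laterally (pixels) and
#'   axially (slices).
#' @slot gfpDiffuseOff,gfpDiffuseOn diffuse cytoplasmic GFP level (projected
#'   counts) in Wg-OFF and Wg-ON cells.
#' @slot junctionLevel,wgLevel projected counts of the junction-marker lattice
#'   and the Wg stripe cytoplasm.
#' @slot readNoiseSd sd of additive Gaussian read noise, counts.
#' @slot backgroundOffset constant camera/media background, counts.
#' @slot saturationLevel hard intensity ceiling (camera saturation).
#' @slot attenuationPerUm optional depth attenuation coefficient (1/um).
#' @slot enRowsPerSegment En-positive cell columns per segment.
#' @slot seed base random seed for rendering.
#' @seealso [embryoSpec()], [renderEmbryo()]
#' @export
setClass("EmbryoSpec", representation(
    nSegments = "integer", cellsPerSegment = "integer", cellRows = "integer",
    cellDiameterPx = "integer", membraneWidthPx = "integer",
    marginPx = "integer", imageShape = "integer", signalSlices = "integer",
    pixelSizeUm = "numeric", zStepUm = "numeric",
    junctionalFraction = "numeric", armBaseLevel = "numeric",
    armStripeAmplitude = "numeric", wgStripeWidthCells = "integer",
    wgOnHaloCells = "integer", punctaWgoffCountMean = "numeric",
    punctaWgonCountMean = "numeric", punctaCountRange = "numeric",
    punctaCountDispersion = "numeric", brightnessPerMolecule = "numeric",
    psfSigmaPx = "numeric", psfSigmaZ = "numeric", gfpDiffuseOff = "numeric",
    gfpDiffuseOn = "numeric", junctionLevel = "numeric", wgLevel = "numeric",
    readNoiseSd = "numeric", backgroundOffset = "numeric",
    saturationLevel = "numeric", attenuationPerUm = "numeric",
    enRowsPerSegment = "integer", seed = "integer"))

setValidity("EmbryoSpec", function(object) {
    msg <- character()
    pos <- c(cellDiameterPx = object@cellDiameterPx,
             pixelSizeUm = object@pixelSizeUm, zStepUm = object@zStepUm,
             armBaseLevel = object@armBaseLevel,
             brightnessPerMolecule = object@brightnessPerMolecule,
             psfSigmaPx = object@psfSigmaPx, psfSigmaZ = object@psfSigmaZ,
             saturationLevel = object@saturationLevel)
    if (any(pos <= 0))
        msg <- c(msg, paste0("must be > 0: ",
                 paste(names(pos)[pos <= 0], collapse = ", ")))
    if (object@junctionalFraction < 0 || object@junctionalFraction > 1)
        msg <- c(msg, "junctionalFraction must lie in [0, 1]")
    if (object@armStripeAmplitude < 0)
        msg <- c(msg, "armStripeAmplitude must be >= 0")
    if (length(object@punctaCountRange) != 2L ||
        object@punctaCountRange[1] < 1 ||
        diff(object@punctaCountRange) < 0)
        msg <- c(msg, "punctaCountRange must be (min, max) with min >= 1")
    if (object@enRowsPerSegment < 0L)
        msg <- c(msg, "enRowsPerSegment must be >= 0")
    if (object@enRowsPerSegment > object@cellsPerSegment)
        msg <- c(msg, "enRowsPerSegment cannot exceed cellsPerSegment")
    if (object@membraneWidthPx >= object@cellDiameterPx)
        msg <- c(msg, "membraneWidthPx must be smaller than cellDiameterPx")
    period <- object@cellsPerSegment * object@cellDiameterPx
    needX <- object@nSegments * period + 2L * object@marginPx
    needY <- object@cellRows * object@cellDiameterPx + 2L * object@marginPx
    if (length(object@imageShape) != 3L)
        msg <- c(msg, "imageShape must be (z, y, x)")
    else if (object@imageShape[3] < needX || object@imageShape[2] < needY)
        msg <- c(msg, sprintf(
            "imageShape (y >= %d, x >= %d required) too small to hold %d segments of period %d px",
            needY, needX, object@nSegments, period))
    if (length(object@signalSlices) != 2L ||
        object@signalSlices[1] < 1L ||
        object@signalSlices[2] > object@imageShape[1])
        msg <- c(msg, "signalSlices must lie within the stack")
    if (length(msg)) msg else TRUE
})

#' StandardSpec: parameters of a synthetic fluorescence calibration standard
#'
#' Describes a field of diffraction-limited spots each carrying a fixed,
#' known number of GFP molecules, emulating yeast strains whose
#' kinetochore clusters have calibrated stoichiometry (Ndc80, 306 molecules;
#' Mif2, 58 molecules). The noise model and PSF match [renderEmbryo()] so the
#' standards can calibrate embryo puncta imaged under the same optics.
#'
#' @slot name standard label (e.g. `"Ndc80"`).
#' @slot moleculesPerStructure known GFP molecules per structure.
#' @slot nStructures number of spots rendered.
#' @slot gridSpacingPx spot-to-spot spacing of the jittered placement grid.
#' @slot nSlices z slices in the stack.
#' @slot brightnessPerMolecule,psfSigmaPx,psfSigmaZ,readNoiseSd,backgroundOffset,saturationLevel
#'   as in [EmbryoSpec-class].
#' @slot seed random seed.
#' @seealso [standardSpec()], [renderStandard()]
#' @export
setClass("StandardSpec", representation(
    name = "character", moleculesPerStructure = "numeric",
    nStructures = "integer", gridSpacingPx = "integer", nSlices = "integer",
    brightnessPerMolecule = "numeric", psfSigmaPx = "numeric",
    psfSigmaZ = "numeric", readNoiseSd = "numeric",
    backgroundOffset = "numeric", saturationLevel = "numeric",
    seed = "integer"))

setValidity("StandardSpec", function(object) {
    msg <- character()
    if (object@moleculesPerStructure < 1)
        msg <- c(msg, "moleculesPerStructure must be >= 1")
    if (object@nStructures < 1L)
        msg <- c(msg, "nStructures must be >= 1")
    if (object@brightnessPerMolecule <= 0 || object@psfSigmaPx <= 0 ||
        object@psfSigmaZ <= 0 || object@saturationLevel <= 0)
        msg <- c(msg, "brightness, PSF sigmas and saturation must be > 0")
    if (length(msg)) msg else TRUE
})

#' EmbryoImage: a multi-channel confocal stack with imaging metadata
#'
#' @slot data numeric 4-D array `(channel, z, y, x)`, intensities >= 0.
#' @slot channelRoles named integer vector mapping roles (`junction`, `arm`,
#'   `wg`, `gfp`) to channel indices; a subset of roles is allowed.
#' @slot pixelSizeUm,zStepUm pixel size and z spacing, micrometres.
#' @slot orientation `"canonical"` (anterior at low x, midline centred) or
#'   `"unknown"`.
#' @slot meta free-form list (e.g. `signalSlices`, `opticsId`).
#' @seealso [channelData()], [rotateToCanonical()], [sumProjection()]
#' @export
setClass("EmbryoImage", representation(
    data = "array", channelRoles = "integer", pixelSizeUm = "numeric",
    zStepUm = "numeric", orientation = "character", meta = "list"))

setValidity("EmbryoImage", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
        msg <- c(msg, "data must be a 4-D (channel, z, y, x) array")
    if (any(object@data < 0, na.rm = TRUE))
        msg <- c(msg, "intensities must be >= 0")
    if (is.null(names(object@channelRoles)) ||
        any(object@channelRoles < 1L) ||
        any(object@channelRoles > dim(object@data)[1]))
        msg <- c(msg, "channelRoles must name valid channel indices")
    if (!object@orientation %in% c("canonical", "unknown"))
        msg <- c(msg, "orientation must be 'canonical' or 'unknown'")
    if (length(msg)) msg else TRUE
})

#' GroundTruth: simulator ground truth for recovery testing
#'
#' @slot cellMap integer label matrix `(y, x)`; 0 outside cells (membrane and
#'   background), cell id elsewhere.
#' @slot wgState integer vector indexed by cell id; 1 = Wg-ON, 0 = Wg-OFF.
#' @slot membraneTruth logical matrix of junctional membrane pixels.
#' @slot armJunctional,armCytoplasmic noiseless projected Arm intensity for
#'   each pool; their sum is the total Arm truth.
#' @slot puncta data.frame with columns `id, z, y, x, compartment, region,
#'   molecules` (one row per rendered punctum).
#' @slot enRows En-positive cell columns per segment.
#' @slot spec the generating [EmbryoSpec-class].
#' @export
setClass("GroundTruth", representation(
    cellMap = "matrix", wgState = "integer", membraneTruth = "matrix",
    armJunctional = "matrix", armCytoplasmic = "matrix",
    puncta = "data.frame", enRows = "integer", spec = "EmbryoSpec"))

#' MembraneMask: binary junctional-membrane mask
#'
#' @slot mask logical matrix aligned to the projection it was derived from.
#' @slot sourceChannel role of the channel segmented (normally `"junction"`).
#' @slot params segmentation parameters used (for provenance/idempotence).
#' @seealso [segmentMembrane()], [subtractMask()]
#' @export
setClass("MembraneMask", representation(
    mask = "matrix", sourceChannel = "character", params = "list"))

setValidity("MembraneMask", function(object) {
    if (!is.logical(object@mask)) "mask must be a logical matrix" else TRUE
})

#' CalibrationStandard: a measured fluorescence standard
#'
#' Summarises the per-structure integrated intensity of a standard with known
#' molecules per structure; the ratio `perStructureIntensity / molecules` is
#' the intensity of a single GFP molecule under the imaging settings used.
#'
#' @slot name standard label.
#' @slot molecules known molecules per structure.
#' @slot perStructureIntensity mean background-subtracted integrated
#'   intensity per structure.
#' @slot intensitySd sd over structures.
#' @slot nStructures number of structures measured.
#' @slot opticsId identifier of the imaging-settings session; puncta may only
#'   be calibrated against standards carrying the same id.
#' @seealso [measureStandard()], [countMolecules()]
#' @export
setClass("CalibrationStandard", representation(
    name = "character", molecules = "numeric",
    perStructureIntensity = "numeric", intensitySd = "numeric",
    nStructures = "integer", opticsId = "character"))

setValidity("CalibrationStandard", function(object) {
    msg <- character()
    if (object@molecules <= 0) msg <- c(msg, "molecules must be > 0")
    if (object@perStructureIntensity <= 0)
        msg <- c(msg, "perStructureIntensity must be > 0")
    if (length(msg)) msg else TRUE
})

#' SegmentProfile: valley-zeroed Arm intensity profile across segments
#'
#' @slot position normalised AP coordinate in `[0, nSegments]`.
#' @slot intensity column-mean intensity, resampled to a fixed length and
#'   shifted so the profile minimum is zero.
#' @slot roi rectangle `c(x, y, w, h)` profiled.
#' @slot nSegments segments spanned by the ROI.
#' @export
setClass("SegmentProfile", representation(
    position = "numeric", intensity = "numeric", roi = "numeric",
    nSegments = "integer"))

#' StripeInterstripeResult: Wg-stripe versus interstripe Arm levels
#'
#' @slot stripeMean,interstripeMean background-subtracted mean gray values
#'   averaged over the stripe / interstripe boxes.
#' @slot difference `stripeMean - interstripeMean` (background cancels).
#' @slot background scalar background subtracted.
#' @slot stripeBoxes,interstripeBoxes lists of rectangles measured.
#' @export
setClass("StripeInterstripeResult", representation(
    stripeMean = "numeric", interstripeMean = "numeric",
    difference = "numeric", background = "numeric", stripeBoxes = "list",
    interstripeBoxes = "list"))

#' PoolResult: junctional versus cytoplasmic/nuclear Arm pools in an ROI
#'
#' Exact decomposition: `membraneIntensity + cytoplasmicIntensity ==
#' totalIntensity` and `membraneArea + cytoplasmicArea == roiArea`.
#'
#' @slot totalIntensity,membraneIntensity,cytoplasmicIntensity
#'   background-adjusted summed intensities.
#' @slot roiArea,membraneArea,cytoplasmicArea pixel counts.
#' @slot totalMean,membraneMean,cytoplasmicMean per-area means.
#' @slot roi rectangle measured.
#' @export
setClass("PoolResult", representation(
    totalIntensity = "numeric", membraneIntensity = "numeric",
    cytoplasmicIntensity = "numeric", roiArea = "numeric",
    membraneArea = "numeric", cytoplasmicArea = "numeric",
    totalMean = "numeric", membraneMean = "numeric",
    cytoplasmicMean = "numeric", roi = "numeric"))

#' EnRowResult: rows of En-expressing cells per segment
#'
#' @slot perLineCounts integer matrix (sampling line x En band) of cells
#'   crossed.
#' @slot meanRowsPerSegment grand mean of `perLineCounts`.
#' @slot thresholdUsed intensity threshold applied to the max projection.
#' @slot linePositions y coordinates of the three AP-parallel lines.
#' @slot bands En band indices counted (anterior to posterior).
#' @export
setClass("EnRowResult", representation(
    perLineCounts = "matrix", meanRowsPerSegment = "numeric",
    thresholdUsed = "numeric", linePositions = "numeric", bands = "integer"))

#' FoldMeasure: a fold ratio between two species with uncertainty
#'
#' @slot numerator,denominator labels of the compared species.
#' @slot fold ratio (> 0).
#' @slot sd standard deviation of the fold.
#' @slot nBlots number of blots averaged.
#' @slot dilutionVerified whether a > 5-fold (or < 0.2) value was verified by
#'   serial dilution; unverified extreme folds trigger a warning.
#' @seealso [foldMeasure()], [chainFolds()]
#' @export
setClass("FoldMeasure", representation(
    numerator = "character", denominator = "character", fold = "numeric",
    sd = "numeric", nBlots = "integer", dilutionVerified = "logical"))

setValidity("FoldMeasure", function(object) {
    msg <- character()
    if (object@fold <= 0) msg <- c(msg, "fold must be > 0")
    if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
    if (length(msg)) msg else TRUE
})
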