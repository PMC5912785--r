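#' Render a synthetic yeast fluorescence-standard stack
#'
#' Renders `nStructures` diffraction-limited spots, each with integrated
#' photon count `moleculesPerStructure * brightnessPerMolecule` before noise,
#' on a jittered grid over a dark field. Spots are axially centred on the
#' middle slice (a coverslip monolayer); the camera/noise model matches
#' [renderEmbryo()] so standards calibrate puncta imaged under the same
#' settings.
#'
#' @param spec a [StandardSpec-class].
#' @param noise apply the camera noise model.
#' @param seed random seed; defaults to `spec@seed`.
#' @return list with `stack` (numeric `(z, y, x)` array) and `positions`
#'   (data.frame `id, z, y, x, molecules`).
#' @examples
#' std <- renderStandard(standardSpec("Mif2", nStructures = 12L),
#'                       noise = FALSE)
#' nrow(std$positions)
#' @export
renderStandard <- function(spec, noise = TRUE, seed = spec@seed) {
    validObject(spec)
    set.seed(mixSeed(seed, 2L))
    n <- spec@nStructures
    sp <- spec@gridSpacingPx
    nc <- ceiling(sqrt(n))
    nr <- ceiling(n / nc)
    pad <- sp           # room for the 21x21 outer ROI at the border
    ny <- nr * sp + 2L * pad
    nx <- nc * sp + 2L * pad
    nz <- spec@nSlices
    cz <- (nz + 1L) %/% 2L
    idx <- seq_len(n) - 1L
    jit <- sp / 4
    cx <- pad + (idx %% nc) * sp + sp / 2 + runif(n, -jit, jit)
    cy <- pad + (idx %/% nc) * sp + sp / 2 + runif(n, -jit, jit)
    stack <- array(0, dim = c(nz, ny, nx))
    photons <- spec@moleculesPerStructure * spec@brightnessPerMolecule
    for (i in seq_len(n))
        stack <- addSpot(stack, cz, cy[i], cx[i], photons,
                         spec@psfSigmaPx, spec@psfSigmaZ)
    stack <- applyCamera(stack, spec@backgroundOffset, spec@readNoiseSd,
                         spec@saturationLevel, noise = noise)
    list(stack = stack,
         positions = data.frame(id = seq_len(n), z = cz, y = cy, x = cx,
                                molecules = spec@moleculesPerStructure),
         opticsId = opticsId(spec))
}

#' Render a synthetic Engrailed channel
#'
#' Per segment, the `enRowsPerSegment` most posterior cell columns express
#' En; cells are rendered as distinct bright blobs separated by dark membrane
#' gaps so that a line drawn parallel to the AP axis crosses countable cells.
#' The image is returned as a single (already projected) 2-D frame.
#'
#' @param spec an [EmbryoSpec-class]; `nSegments` should be at least the
#'   largest En band to be counted (bands 2--5 need 5 segments or more).
#' @param enLevel projected intensity of En-positive cell interiors.
#' @param noise apply the camera noise model.
#' @param seed random seed; defaults to `spec@seed`.
#' @return list with `image` (numeric `(y, x)` matrix) and `truth`
#'   (a [GroundTruth-class]; `enRows` holds the configured row count).
#' @examples
#' en <- renderEnChannel(embryoSpec(nSegments = 6L), noise = FALSE)
#' en$truth@enRows
#' @export
renderEnChannel <- function(spec, enLevel = 100, noise = TRUE,
                            seed = spec@seed) {
    validObject(spec)
    set.seed(mixSeed(seed, 3L))
    geo <- latticeGeometry(spec)
    cells <- geo$cells
    k <- spec@enRowsPerSegment
    posInSeg <- (cells$col - 1L) %% spec@cellsPerSegment + 1L
    enCells <- cells$id[posInSeg > spec@cellsPerSegment - k]
    img <- ifelse(matrix(geo$cellMap %in% enCells, nrow(geo$cellMap),
                         ncol(geo$cellMap)), enLevel, 0)
    img <- applyCamera(img, spec@backgroundOffset, spec@readNoiseSd,
                       spec@saturationLevel, noise = noise)
    truth <- new("GroundTruth", cellMap = geo$cellMap,
                 wgState = as.integer(cells$wgOn),
                 membraneTruth = geo$membrane,
                 armJunctional = matrix(0, 1, 1),
                 armCytoplasmic = matrix(0, 1, 1),
                 puncta = data.frame(), enRows = k, spec = spec)
    list(image = img, truth = truth)
}
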