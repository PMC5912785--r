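#' Measure a fluorescence calibration standard
#'
#' Detects the standard's structures, integrates each with the same
#' nested-ROI procedure used for embryo puncta, and summarises the mean and
#' sd per-structure intensity. At least ten structures are required.
#'
#' @param stacks a `(z, y, x)` array or a list of such arrays (multiple
#'   fields of the same standard).
#' @param knownMolecules molecules per structure (306 for Ndc80, 58 for
#'   Mif2).
#' @param name standard label.
#' @param opticsId imaging-settings identifier (see [opticsId()]); puncta can
#'   only be calibrated against standards with a matching id.
#' @param ... passed to [detectPuncta()].
#' @return a [CalibrationStandard-class].
#' @examples
#' std <- renderStandard(standardSpec("Mif2"))
#' measureStandard(std$stack, 58, "Mif2", std$opticsId)
#' @export
measureStandard <- function(stacks, knownMolecules, name = "standard",
                            opticsId = "unspecified", ...) {
    if (!is.list(stacks)) stacks <- list(stacks)
    ints <- numeric()
    for (stack in stacks) {
        det <- detectPuncta(stack, ...)
        det <- det[!det$edge, , drop = FALSE]
        det <- integratePuncta(det, stack)
        ints <- c(ints, det$intensity)
    }
    ints <- ints[!is.na(ints)]
    if (length(ints) < 10L)
        stop("only ", length(ints),
             " structures detected; >= 10 required to measure a standard")
    new("CalibrationStandard", name = name, molecules = knownMolecules,
        perStructureIntensity = mean(ints), intensitySd = sd(ints),
        nStructures = length(ints), opticsId = opticsId)
}

#' Count GFP molecules in puncta by dual-standard calibration
#'
#' Each punctum's integrated intensity is converted to molecules against two
#' standards of known stoichiometry: `count = intensity * depthFactor /
#' (perStructureIntensity / molecules)`. A punctum is accepted when the two
#' estimates agree within `toleranceMolecules` (the +/- 15 molecule
#' consistency rule); the accepted count is the mean of the two estimates.
#' Standards and puncta must share the same imaging-settings id (standards
#' are only comparable when imaged with the same settings in the same
#' session).
#'
#' @param puncta data.frame with an `intensity` column (see
#'   [integratePuncta()]); saturated puncta should have been removed with
#'   [saturationFilter()] first.
#' @param standardA,standardB [CalibrationStandard-class] objects.
#' @param toleranceMolecules consistency tolerance, molecules (default 15),
#'   applied as an absolute tolerance at all count scales.
#' @param punctaOpticsId imaging-settings id of the puncta acquisition;
#'   mismatch with either standard is an error. `NULL` skips the check.
#' @param attenuationPerUm optional distance-from-coverslip correction
#'   coefficient; the correction factor is
#'   `exp(attenuationPerUm * (z - 1) * zStepUm)` (default 0, no correction).
#' @param zStepUm z spacing used for the depth correction.
#' @return the table with columns `countA`, `countB` (named
#'   `count_<standard>`), `accepted` and `acceptedCount` (`NA` when
#'   rejected) added.
#' @export
countMolecules <- function(puncta, standardA, standardB,
                           toleranceMolecules = 15, punctaOpticsId = NULL,
                           attenuationPerUm = 0, zStepUm = 1) {
    stopifnot(is(standardA, "CalibrationStandard"),
              is(standardB, "CalibrationStandard"))
    if (!is.null(punctaOpticsId)) {
        for (s in list(standardA, standardB))
            if (!identical(s@opticsId, punctaOpticsId))
                stop("imaging settings of standard '", s@name,
                     "' (", s@opticsId, ") do not match the puncta (",
                     punctaOpticsId,
                     "); standards must be imaged with the same settings")
    }
    depthFactor <- exp(attenuationPerUm * (puncta$z - 1) * zStepUm)
    perMolA <- standardA@perStructureIntensity / standardA@molecules
    perMolB <- standardB@perStructureIntensity / standardB@molecules
    cA <- puncta$intensity * depthFactor / perMolA
    cB <- puncta$intensity * depthFactor / perMolB
    accepted <- !is.na(cA) & !is.na(cB) &
        abs(cA - cB) <= toleranceMolecules
    out <- puncta
    out[[paste0("count_", standardA@name)]] <- cA
    out[[paste0("count_", standardB@name)]] <- cB
    out$accepted <- accepted
    out$acceptedCount <- ifelse(accepted, (cA + cB) / 2, NA_real_)
    out
}

#' Single-standard molecule estimate
#'
#' Converts integrated intensities to molecule counts against one standard
#' (used, e.g., to count a test structure against the Mif2 standard alone).
#'
#' @param intensity integrated intensity (scalar or vector).
#' @param standard a [CalibrationStandard-class].
#' @return molecules.
#' @export
moleculesFromIntensity <- function(intensity, standard) {
    stopifnot(is(standard, "CalibrationStandard"))
    intensity / (standard@perStructureIntensity / standard@molecules)
}
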