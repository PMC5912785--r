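## Shared fixtures, rendered once per test session and cached.  All fixtures
## are generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
    if (!exists(key, envir = .fixtures))
        assign(key, build(), envir = .fixtures)
    get(key, envir = .fixtures)
}

## noiseless wild-type embryo at the default spec
wtNoiseless <- function() {
    fixture("wtNoiseless", function() renderEmbryo(embryoSpec(),
                                                   noise = FALSE))
}

## noisy wild-type embryo for a given seed
wtNoisy <- function(seed) {
    fixture(paste0("wtNoisy", seed), function()
        renderEmbryo(embryoSpec(seed = seed)))
}

## measured yeast standards under the default optics
defaultStandards <- function() {
    fixture("standards", function() {
        sN <- renderStandard(standardSpec("Ndc80", seed = 1L))
        sM <- renderStandard(standardSpec("Mif2", seed = 2L))
        list(ndc80 = measureStandard(sN$stack, 306, "Ndc80", sN$opticsId),
             mif2 = measureStandard(sM$stack, 58, "Mif2", sM$opticsId),
             opticsId = sN$opticsId)
    })
}

## detected + integrated + counted puncta for one noisy embryo seed,
## matched to ground truth
countedPuncta <- function(seed) {
    fixture(paste0("counted", seed), function() {
        out <- wtNoisy(seed)
        stack <- channelData(out$image, "gfp")
        det <- detectPuncta(stack)
        det <- suppressWarnings(
            integratePuncta(det[!det$edge, , drop = FALSE], stack))
        det <- saturationFilter(det, stack,
                                out$truth@spec@saturationLevel)$kept
        std <- defaultStandards()
        cc <- countMolecules(det, std$ndc80, std$mif2,
                             punctaOpticsId = out$image@meta$opticsId)
        tp <- out$truth@puncta
        mi <- vapply(seq_len(nrow(cc)), function(i)
            which.min((tp$y - cc$y[i])^2 + (tp$x - cc$x[i])^2), 0L)
        cc$trueMolecules <- tp$molecules[mi]
        cc$trueCompartment <- tp$compartment[mi]
        cc$matchDist <- sqrt((tp$y[mi] - cc$y)^2 + (tp$x[mi] - cc$x)^2)
        cc
    })
}

## 6-segment noiseless En fixture
enNoiseless <- function(rows = 2L) {
    fixture(paste0("en", rows), function()
        renderEnChannel(embryoSpec(nSegments = 6L,
                                   enRowsPerSegment = rows),
                        noise = FALSE))
}

## canonical projections of the noiseless wild type
wtProjections <- function() {
    fixture("wtProj", function() {
        out <- wtNoiseless()
        list(arm = sumProjection(out$image, role = "arm"),
             junction = sumProjection(out$image, role = "junction"),
             wg = sumProjection(out$image, role = "wg"),
             background = out$truth@spec@backgroundOffset *
                 (diff(out$truth@spec@signalSlices) + 1L))
    })
}
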