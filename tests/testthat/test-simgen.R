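test_that("spec constructors validate their invariants", {
    expect_s4_class(embryoSpec(), "EmbryoSpec")
    expect_error(embryoSpec(junctionalFraction = 1.2), "junctionalFraction")
    expect_error(embryoSpec(imageShape = c(12L, 50L, 60L)), "too small")
    expect_error(embryoSpec(enRowsPerSegment = 7L), "cellsPerSegment")
    expect_error(embryoSpec(punctaCountRange = c(0, 900)), "min >= 1")
    expect_error(standardSpec("Mif2", moleculesPerStructure = 0),
                 "moleculesPerStructure")
    expect_error(standardSpec("unknownStrain"), "known standards")
})

test_that("rendering is deterministic for identical spec and seed", {
    spec <- embryoSpec(nSegments = 2L, cellRows = 4L)
    a <- renderEmbryo(spec)
    b <- renderEmbryo(spec)
    expect_identical(a$image@data, b$image@data)
    expect_identical(a$truth@puncta, b$truth@puncta)
    s <- standardSpec("Mif2", nStructures = 12L)
    expect_identical(renderStandard(s)$stack, renderStandard(s)$stack)
})

test_that("junctional and cytoplasmic Arm truth decompose the Arm channel", {
    out <- wtNoiseless()
    tr <- out$truth
    ## conservation: pools sum to the total noiseless Arm signal
    armProj <- sumProjection(out$image, role = "arm")
    bg <- wtProjections()$background
    expect_equal(armProj, tr@armJunctional + tr@armCytoplasmic + bg,
                 tolerance = 1e-10, ignore_attr = TRUE)
    ## the junctional share matches the configured fraction
    f <- sum(tr@armJunctional) /
        sum(tr@armJunctional + tr@armCytoplasmic)
    expect_equal(f, 0.70, tolerance = 0.01)
})

test_that("degenerate junctional fractions behave as documented", {
    all0 <- renderEmbryo(embryoSpec(nSegments = 2L, cellRows = 4L,
                                    junctionalFraction = 1),
                         noise = FALSE)
    expect_true(all(all0$truth@armCytoplasmic == 0))
    none <- renderEmbryo(embryoSpec(nSegments = 2L, cellRows = 4L,
                                    junctionalFraction = 0),
                         noise = FALSE)
    expect_true(all(none$truth@armJunctional == 0))
})

test_that("zero stripe amplitude gives a flat cytoplasmic AP profile", {
    out <- renderEmbryo(embryoSpec(nSegments = 2L, cellRows = 4L,
                                   armStripeAmplitude = 1e-12),
                        noise = FALSE)
    cyto <- out$truth@armCytoplasmic
    ## columns that contain cytoplasm all carry the same mean level
    colHasCyto <- colSums(cyto > 0) > 0
    means <- colSums(cyto)[colHasCyto] / colSums(cyto > 0)[colHasCyto]
    expect_lt(max(means) - min(means), 1e-9)
})

test_that("puncta lie inside the cell field with consistent annotations", {
    out <- wtNoiseless()
    tr <- out$truth
    p <- tr@puncta
    sp <- tr@spec
    inLattice <- p$x > sp@marginPx & p$y > sp@marginPx &
        p$x <= ncol(tr@cellMap) - sp@marginPx &
        p$y <= nrow(tr@cellMap) - sp@marginPx
    expect_true(all(inLattice))
    ## membrane puncta sit within a few px of the membrane truth
    memD <- as.matrix(EBImage::distmap(1 - tr@membraneTruth))
    dAtP <- memD[cbind(round(p$y), round(p$x))]
    expect_true(all(dAtP[p$compartment == "membrane"] <= 3.5))
    expect_true(all(dAtP[p$compartment == "cytoplasmic"] > 3.5))
    ## counts respect the configured clip range
    expect_true(all(p$molecules >= 46 & p$molecules <= 931))
})

test_that("spot intensity scales with molecules per structure", {
    mk <- function(mol) renderStandard(
        standardSpec("x", moleculesPerStructure = mol, nStructures = 12L,
                     readNoiseSd = 0, backgroundOffset = 0),
        noise = FALSE)
    lo <- mk(58); hi <- mk(306)
    iLo <- sum(lo$stack); iHi <- sum(hi$stack)
    expect_equal(iHi / iLo, 306 / 58, tolerance = 1e-6)
    expect_gt(sum(mk(59)$stack), iLo)   # strictly increasing
})

test_that("camera noise follows Poisson shot noise plus read noise", {
    spec <- embryoSpec(nSegments = 2L, cellRows = 3L, enRowsPerSegment = 1L)
    ## a pixel inside an En-positive cell (last column of segment 1)
    px <- c(spec@marginPx + 10L, spec@marginPx + 110L)
    vals <- vapply(1:150, function(i)
        renderEnChannel(spec, enLevel = 100, seed = i)$image[px[1], px[2]],
        0)
    expected <- 100 + spec@backgroundOffset + spec@readNoiseSd^2
    expect_equal(var(vals), expected, tolerance = 0.25)
    expect_equal(mean(vals), 100 + spec@backgroundOffset, tolerance = 0.05)
})

test_that("the En channel renders the configured number of rows", {
    blank <- renderEnChannel(embryoSpec(nSegments = 6L,
                                        enRowsPerSegment = 0L),
                             noise = FALSE)
    expect_equal(max(blank$image) - min(blank$image), 0)
    expect_equal(enNoiseless(2L)$truth@enRows, 2L)
    expect_equal(enNoiseless(4L)$truth@enRows, 4L)
})
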