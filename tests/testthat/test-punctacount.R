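test_that("puncta detection handles blank and sparse inputs", {
    expect_equal(nrow(detectPuncta(array(0, dim = c(4, 30, 30)))), 0L)
    ## two spots 30 px apart are both found
    st <- array(0, dim = c(5, 60, 90))
    addSpot <- wgquant:::addSpot
    st <- addSpot(st, 3, 30, 30, 5000, 1.5, 1)
    st <- addSpot(st, 3, 30, 60, 5000, 1.5, 1)
    det <- detectPuncta(st, minHeight = 10)
    expect_equal(nrow(det), 2L)
    expect_equal(sort(det$x), c(30, 60))
})

test_that("detection recovers simulated puncta with few false positives", {
    cc <- countedPuncta(1L)
    truthN <- nrow(wtNoisy(1L)$truth@puncta)
    expect_gte(sum(cc$matchDist <= 2) / truthN, 0.90)     # recall
    expect_lte(mean(cc$matchDist > 2), 0.10)              # false discovery
    ## deterministic ordering: sorted by descending peak
    expect_true(all(diff(cc$peak) <= 0))
    expect_true(all(cc$zlo <= cc$z & cc$z <= cc$zhi))
})

test_that("nested-ROI integration is exact on synthetic spots", {
    ## uniform image: signal equals background
    flat <- array(7, dim = c(5, 60, 60))
    p <- list(z = 3L, y = 30L, x = 30L, zlo = 3L, zhi = 3L)
    expect_equal(integratedIntensity(p, flat), 0)
    ## a single-slice spot of known photon sum on zero background
    st <- array(0, dim = c(5, 60, 60))
    st <- wgquant:::addSpot(st, 3, 30.3, 29.6, 12345, 1.5, 0.05)
    det <- detectPuncta(st, minHeight = 10)
    ii <- integratedIntensity(det[1, ], st)
    expect_equal(ii, 12345, tolerance = 0.005)
    ## adding a constant background leaves the result unchanged
    ii2 <- integratedIntensity(det[1, ], st + 11)
    expect_equal(ii2, ii, tolerance = 1e-9)
    ## an ROI clipped by the edge is an error
    pe <- list(z = 3L, y = 5L, x = 30L, zlo = 3L, zhi = 3L)
    expect_error(integratedIntensity(pe, st), "edge")
})

test_that("standards are measured at their configured stoichiometry", {
    ## near-2-D spots, noiseless: per-structure intensity = molecules x
    ## brightness
    mk <- function(mol, bright = 80) renderStandard(
        standardSpec("s", moleculesPerStructure = mol, nStructures = 15L,
                     psfSigmaZ = 0.05, readNoiseSd = 0,
                     backgroundOffset = 0, brightnessPerMolecule = bright),
        noise = FALSE)
    s58 <- measureStandard(mk(58)$stack, 58, "Mif2")
    expect_equal(s58@perStructureIntensity, 58 * 80, tolerance = 0.005)
    ## linearity in brightness
    s58b <- measureStandard(mk(58, 160)$stack, 58, "Mif2")
    expect_equal(s58b@perStructureIntensity / s58@perStructureIntensity, 2,
                 tolerance = 0.005)
    ## identically rendered standards keep the 306/58 intensity ratio
    std <- defaultStandards()
    expect_equal(std$ndc80@perStructureIntensity /
                     std$mif2@perStructureIntensity,
                 306 / 58, tolerance = 0.03)
    ## too few structures is an error
    tiny <- renderStandard(standardSpec("Mif2", nStructures = 5L))
    expect_error(measureStandard(tiny$stack, 58, "Mif2"), ">= 10")
})

test_that("molecule counting follows the calibration identity", {
    idealA <- new("CalibrationStandard", name = "Ndc80", molecules = 306,
                  perStructureIntensity = 306 * 70, intensitySd = 0,
                  nStructures = 20L, opticsId = "o1")
    idealB <- new("CalibrationStandard", name = "Mif2", molecules = 58,
                  perStructureIntensity = 58 * 70, intensitySd = 0,
                  nStructures = 20L, opticsId = "o1")
    puncta <- data.frame(id = 1:2, z = 3L, y = 30L, x = 30L,
                         zlo = 3L, zhi = 3L, edge = FALSE,
                         intensity = c(58 * 70, 2 * 58 * 70))
    cc <- countMolecules(puncta, idealA, idealB, punctaOpticsId = "o1")
    expect_equal(cc$count_Mif2, c(58, 116))
    expect_equal(cc$count_Ndc80, c(58, 116))
    expect_true(all(cc$accepted))
    expect_equal(cc$acceptedCount, c(58, 116))
    ## estimates 250 vs 270 differ by 20 > 15: rejected
    skewB <- new("CalibrationStandard", name = "Mif2", molecules = 58,
                 perStructureIntensity = 58 * 70 * 250 / 270,
                 intensitySd = 0, nStructures = 20L, opticsId = "o1")
    p1 <- data.frame(id = 1L, z = 3L, y = 30L, x = 30L, zlo = 3L, zhi = 3L,
                     edge = FALSE, intensity = 250 * 70)
    cc2 <- countMolecules(p1, idealA, skewB, punctaOpticsId = "o1")
    expect_equal(cc2$count_Ndc80, 250)
    expect_equal(cc2$count_Mif2, 270)
    expect_false(cc2$accepted)
    expect_true(is.na(cc2$acceptedCount))
    ## mismatched imaging settings are rejected outright
    other <- initialize(idealB, opticsId = "o2")
    expect_error(countMolecules(p1, idealA, other, punctaOpticsId = "o1"),
                 "same settings")
})

test_that("the depth correction applies the configured attenuation", {
    std <- new("CalibrationStandard", name = "Mif2", molecules = 58,
               perStructureIntensity = 58 * 70, intensitySd = 0,
               nStructures = 20L, opticsId = "o1")
    p <- data.frame(id = 1L, z = 11L, y = 30L, x = 30L, zlo = 10L,
                    zhi = 12L, edge = FALSE, intensity = 58 * 70)
    cc <- countMolecules(p, std, std, punctaOpticsId = "o1",
                         attenuationPerUm = 0.02, zStepUm = 1)
    expect_equal(cc$acceptedCount, 58 * exp(0.02 * 10))
})

test_that("saturated puncta are excluded from counting", {
    st <- array(0, dim = c(5, 60, 90))
    st <- wgquant:::addSpot(st, 3, 30, 25, 5e5, 1.5, 1)   # clips
    st <- wgquant:::addSpot(st, 3, 30, 65, 5e3, 1.5, 1)
    ceiling <- 4000
    st[st > ceiling] <- ceiling
    det <- detectPuncta(st, minHeight = 10)
    sf <- saturationFilter(det, st, ceiling)
    ## every detection of the clipped spot is excluded (its flat top can
    ## yield more than one plateau maximum), the unclipped one is kept
    expect_gte(nrow(sf$excluded), 1L)
    expect_true(all(abs(sf$excluded$x - 25) <= 5))
    expect_equal(sf$kept$x, 65)
    ## an infinite ceiling keeps everything
    sfInf <- saturationFilter(det, st, Inf)
    expect_equal(nrow(sfInf$kept), nrow(det))
})

test_that("puncta are classified by compartment and region", {
    mask <- matrix(FALSE, 40, 40); mask[20, ] <- TRUE
    p <- data.frame(id = 1:2, z = 1L, y = c(20L, 35L), x = c(10L, 10L),
                    zlo = 1L, zhi = 1L, edge = FALSE)
    cl <- classifyPuncta(p, mask, wgRegionMap = matrix(TRUE, 40, 40))
    expect_equal(cl$compartment, c("membrane", "cytoplasmic"))
    expect_equal(cl$region, c("Wg-ON", "Wg-ON"))
    ## empty mask: everything cytoplasmic
    cl0 <- classifyPuncta(p, matrix(FALSE, 40, 40))
    expect_true(all(cl0$compartment == "cytoplasmic"))
    ## simulated embryo: >= 90% correct compartments
    out <- wtNoisy(1L)
    cc <- countedPuncta(1L)
    cl <- classifyPuncta(cc, out$truth@membraneTruth,
                         wgRegionMap(out$truth))
    expect_gte(mean(cl$compartment == cl$trueCompartment), 0.90)
})

test_that("calibration is linear and the consistency rule permissive", {
    cc <- do.call(rbind, lapply(1:3, countedPuncta))
    cc <- cc[cc$matchDist <= 2, ]
    expect_gte(nrow(cc), 200L)
    fit <- stats::lm(acceptedCount ~ trueMolecules, cc)
    expect_equal(unname(coef(fit)[2]), 1.00, tolerance = 0.05)
    expect_lt(abs(unname(coef(fit)[1])), 5)
    ## +/- 15 molecule rule accepts nearly all unsaturated puncta
    sub <- cc[cc$trueMolecules <= 400, ]
    expect_gte(mean(sub$accepted), 0.95)
})

test_that("percentile masks are nested and rank structures by brightness", {
    set.seed(51)
    img <- matrix(rexp(100 * 120), 100, 120)
    fg <- matrix(TRUE, 100, 120)
    r <- percentileThresholdRanking(img, fg,
                                    fractions = c(0.01, 0.05, 0.2, 1))
    expect_true(all(r$masks[[1]] <= r$masks[[2]]))
    expect_true(all(r$masks[[2]] <= r$masks[[3]]))
    expect_equal(sum(r$masks[[4]]), sum(fg))   # fraction 1 = foreground
    expect_error(percentileThresholdRanking(img, fg,
                                            fractions = c(0.1, 0.05)),
                 "increasing")
    ## wild-type embryo: the brightness ordering of Fig-8-style structures
    out <- wtNoisy(1L)
    gfpMax <- maxProjection(out$image, role = "gfp")
    fgw <- foregroundMask(out$image)
    cm <- structureClassMap(out$truth, radiusPx = 2)
    rr <- percentileThresholdRanking(gfpMax, fgw, classMap = cm)
    cov <- function(fr, cl)
        rr$coverage$coverage[rr$coverage$fraction == fr &
                                 rr$coverage$class == cl]
    ## the brightest 0.1% of pixels lie in Wg-OFF cytoplasmic puncta
    top <- rr$masks[["0.001"]]
    inOff <- sum(top & !is.na(cm) & cm == "puncta-WgOFF")
    expect_gte(inOff / sum(top), 0.90)
    ## membrane puncta appear later, the diffuse Wg-ON cytoplasm last
    expect_gt(cov(0.001, "puncta-WgOFF"), 0)
    expect_equal(cov(0.001, "puncta-WgON"), 0, tolerance = 1e-12)
    expect_gt(cov(0.01, "puncta-WgON"), 5 * cov(0.003, "puncta-WgON"))
    expect_lt(cov(0.01, "cytoplasm-WgON"), 0.005)
    expect_gte(cov(0.15, "cytoplasm-WgON"), 0.1)
    ## the elevated Wg-ON cytoplasm outranks the Wg-OFF cytoplasm
    expect_gt(cov(0.15, "cytoplasm-WgON"), cov(0.15, "cytoplasm-WgOFF"))
})
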