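test_that("segment profiles are valley-zeroed and offset-invariant", {
    ## constant image: valley-zeroing flattens everything to zero
    prof <- profileAcrossSegments(matrix(5, 60, 360), c(1, 1, 360, 60), 3L)
    expect_true(all(prof@intensity == 0))
    expect_length(prof@intensity, 300L)
    ## additive offsets cancel
    out <- wtNoiseless()
    sp <- out$truth@spec
    roi <- c(sp@marginPx + 1, sp@marginPx + 1, 3 * segmentPeriodPx(sp), 60)
    armM <- subtractMask(wtProjections()$arm, out$truth@membraneTruth)
    p1 <- profileAcrossSegments(armM, roi, 3L)
    p2 <- profileAcrossSegments(armM + 123.4, roi, 3L)
    expect_equal(p1@intensity, p2@intensity, tolerance = 1e-9)
    expect_error(profileAcrossSegments(armM, c(400, 1, 100, 60)),
                 "outside")
})

test_that("the wild-type profile has one peak per segment", {
    out <- wtNoiseless()
    sp <- out$truth@spec
    roi <- c(sp@marginPx + 1, sp@marginPx + 1, 3 * segmentPeriodPx(sp), 60)
    armM <- subtractMask(wtProjections()$arm, out$truth@membraneTruth)
    prof <- profileAcrossSegments(armM, roi, 3L,
                                  smoothSigmaPx = sp@cellDiameterPx / 2)
    expect_equal(countProfilePeaks(prof), 3L)
})

test_that("losing the stripes flattens the profile", {
    flat <- renderEmbryo(embryoSpec(armStripeAmplitude = 1e-12),
                         noise = FALSE)
    sp <- flat$truth@spec
    roi <- c(sp@marginPx + 1, sp@marginPx + 1, 3 * segmentPeriodPx(sp), 60)
    armFlat <- subtractMask(sumProjection(flat$image, role = "arm"),
                            flat$truth@membraneTruth)
    armWt <- subtractMask(wtProjections()$arm,
                          wtNoiseless()$truth@membraneTruth)
    pFlat <- profileAcrossSegments(armFlat, roi, 3L, smoothSigmaPx = 10)
    pWt <- profileAcrossSegments(armWt, roi, 3L, smoothSigmaPx = 10)
    expect_lt(max(pFlat@intensity), 0.1 * max(pWt@intensity))
})

test_that("stripe boxes are centred on the Wg stripes", {
    out <- wtNoiseless()
    bx <- placeStripeBoxes(wtProjections()$wg)
    expect_length(bx$stripeBoxes, 3L)
    expect_length(bx$interstripeBoxes, 2L)
    truthX <- trueStripeCenters(out$truth)
    expect_true(all(abs(sort(bx$stripeX) - sort(truthX)) <= 3))
    expect_error(placeStripeBoxes(matrix(0, 60, 200)), "no Wg signal")
    ## a single-stripe fixture yields a single centred box
    one <- renderEmbryo(embryoSpec(nSegments = 1L, cellRows = 4L),
                        noise = FALSE)
    b1 <- placeStripeBoxes(sumProjection(one$image, role = "wg"),
                           nStripes = 1L, boxShape = c(60L, 20L))
    expect_length(b1$stripeBoxes, 1L)
    expect_lt(abs(b1$stripeX - trueStripeCenters(one$truth)), 3)
})

test_that("stripe/interstripe levels subtract background correctly", {
    img <- matrix(9, 120, 400)
    boxes <- list(stripeBoxes = list(c(10, 10, 100, 30), c(150, 10, 100, 30),
                                     c(290, 10, 100, 30)),
                  interstripeBoxes = list(c(80, 50, 100, 30),
                                          c(220, 50, 100, 30)))
    r <- stripeInterstripe(img, boxes, background = 4)
    expect_equal(r@stripeMean, 5)
    expect_equal(r@interstripeMean, 5)
    expect_equal(r@difference, 0)
    ## the difference is invariant to the background estimate
    r2 <- stripeInterstripe(img + 100, boxes, background = 77)
    expect_equal(r2@difference, r@difference)
})

test_that("the configured stripe amplitude is recovered", {
    ## noiseless, ground-truth mask: the definition is exact
    out <- wtNoiseless()
    armM <- subtractMask(wtProjections()$arm, out$truth@membraneTruth)
    bx <- placeStripeBoxes(wtProjections()$wg)
    si <- stripeInterstripe(armM, bx,
                            background = wtProjections()$background)
    expect_equal(si@difference, 60, tolerance = 0.1)
    ## full pipeline (noise, segmented mask, estimated background), mean
    ## over seeds
    diffs <- vapply(1:8, function(s) {
        o <- wtNoisy(s)
        arm <- sumProjection(o$image, role = "arm")
        jp <- sumProjection(o$image, role = "junction")
        wg <- sumProjection(o$image, role = "wg")
        fg <- foregroundMask(o$image)
        bg <- estimateBackground(arm, foreground = fg)
        b <- placeStripeBoxes(wg)
        stripeInterstripe(subtractMask(arm, segmentMembrane(jp)), b,
                          background = bg)@difference
    }, 0)
    expect_equal(mean(diffs), 60, tolerance = 0.05)
})

test_that("a flat embryo yields a null stripe difference", {
    set.seed(31)
    diffs <- vapply(1:4, function(s) {
        o <- renderEmbryo(embryoSpec(armStripeAmplitude = 1e-12, seed = s))
        arm <- sumProjection(o$image, role = "arm")
        wg <- sumProjection(o$image, role = "wg")
        fg <- foregroundMask(o$image)
        bg <- estimateBackground(arm, foreground = fg)
        stripeInterstripe(subtractMask(arm, o$truth@membraneTruth),
                          placeStripeBoxes(wg), background = bg)@difference
    }, 0)
    ## indistinguishable from zero at the sampling noise scale
    expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 0.5)
})

test_that("pool separation decomposes intensity and area exactly", {
    set.seed(41)
    img <- matrix(runif(80 * 90, 0, 50), 80, 90)
    mask <- matrix(runif(80 * 90) < 0.25, 80, 90)
    roi <- c(11, 6, 60, 70)
    r <- poolSeparation(img, mask, roi, background = 3)
    expect_identical(r@membraneIntensity + r@cytoplasmicIntensity,
                     r@totalIntensity)
    expect_identical(r@membraneArea + r@cytoplasmicArea, r@roiArea)
    expect_equal(r@membraneMean, r@membraneIntensity / r@membraneArea)
    ## empty mask: everything is cytoplasmic
    r0 <- poolSeparation(img, matrix(FALSE, 80, 90), roi)
    expect_equal(r0@membraneIntensity, 0)
    expect_equal(r0@cytoplasmicIntensity, r0@totalIntensity)
    ## full mask leaves the cytoplasmic mean undefined
    expect_error(poolSeparation(img, matrix(TRUE, 80, 90), roi),
                 "undefined")
})

test_that("the junctional pool carries 70% of Arm in a Wg-OFF ROI", {
    out <- wtNoiseless()
    roi <- placePoolRoi(out$truth, regime = "off")
    r <- poolSeparation(wtProjections()$arm, out$truth@membraneTruth, roi,
                        background = wtProjections()$background)
    expect_equal(r@membraneIntensity / r@totalIntensity, 0.70,
                 tolerance = 0.02 / 0.70)
})
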