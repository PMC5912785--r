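test_that("projections match brute-force oracles", {
    set.seed(11)
    stack <- array(runif(6 * 10 * 12, 0, 100), dim = c(6, 10, 12))
    ## independent oracles: explicit loops over slices
    oracleSum <- matrix(0, 10, 12); oracleMax <- matrix(-Inf, 10, 12)
    for (z in 2:5) {
        oracleSum <- oracleSum + stack[z, , ]
        oracleMax <- pmax(oracleMax, stack[z, , ])
    }
    expect_equal(sumProjection(stack, depthUm = 4, zOrigin = 2), oracleSum)
    expect_equal(maxProjection(stack, depthUm = 4, zOrigin = 2), oracleMax)
    ## single slice is the identity
    expect_equal(sumProjection(stack, depthUm = 1, zOrigin = 3),
                 stack[3, , ])
    expect_equal(maxProjection(stack, depthUm = 1, zOrigin = 3),
                 stack[3, , ])
    ## all-ones stack over 8 slices
    ones <- array(1, dim = c(8, 4, 5))
    expect_true(all(sumProjection(ones, depthUm = 8) == 8))
    ## projections commute with scalar multiplication
    expect_equal(sumProjection(3 * stack, depthUm = 4, zOrigin = 2),
                 3 * sumProjection(stack, depthUm = 4, zOrigin = 2))
    expect_equal(maxProjection(3 * stack, depthUm = 4, zOrigin = 2),
                 3 * maxProjection(stack, depthUm = 4, zOrigin = 2))
    ## asking for more depth than available names the available depth
    expect_error(sumProjection(stack, depthUm = 10, zOrigin = 3),
                 "exceeds")
})

test_that("orientation flips are exact involutions", {
    out <- wtNoiseless()
    img <- out$image
    expect_identical(rotateToCanonical(img)@data, img@data)
    flipped <- rotateToCanonical(img, flipAP = TRUE, flipDV = TRUE)
    expect_false(identical(flipped@data, img@data))
    back <- rotateToCanonical(flipped, flipAP = TRUE, flipDV = TRUE)
    expect_identical(back@data, img@data)
    ## a posterior-left embryo flipped AP has mirrored Wg stripe positions
    wgFlip <- sumProjection(rotateToCanonical(img, flipAP = TRUE),
                            role = "wg")
    bx <- placeStripeBoxes(wgFlip)
    nx <- dim(img@data)[4]
    expect_equal(sort(nx + 1 - bx$stripeX),
                 sort(placeStripeBoxes(wtProjections()$wg)$stripeX),
                 tolerance = 1e-6)
})

test_that("membrane segmentation recovers the junctional lattice", {
    out <- wtNoiseless()
    mask <- segmentMembrane(wtProjections()$junction)
    mt <- out$truth@membraneTruth
    tp <- sum(mask@mask & mt); fp <- sum(mask@mask & !mt)
    fn <- sum(!mask@mask & mt)
    f1 <- 2 * tp / (2 * tp + fp + fn)
    expect_gte(tp / (tp + fn), 0.95)                  # recall
    expect_lte(fp / length(mt), 0.05)                 # false-positive area
    expect_gte(f1, 0.9)
    ## deterministic: same parameters give the identical mask
    expect_identical(mask@mask,
                     segmentMembrane(wtProjections()$junction)@mask)
})

test_that("membrane segmentation handles degenerate inputs", {
    expect_warning(m0 <- segmentMembrane(matrix(0, 40, 40)), "blank")
    expect_false(any(m0@mask))
    ## a uniform field has no ridges
    mu <- segmentMembrane(matrix(7, 60, 60))
    expect_lt(mean(mu@mask), 0.05)
})

test_that("mask subtraction conserves intensity exactly", {
    set.seed(21)
    img <- matrix(runif(50 * 40, 0, 10), 50, 40)
    mask <- matrix(runif(50 * 40) < 0.3, 50, 40)
    sub <- subtractMask(img, mask)
    expect_identical(sum(sub) + sum(img[mask]), sum(img))
    expect_identical(subtractMask(img, matrix(FALSE, 50, 40)), img)
    expect_true(all(subtractMask(img, matrix(TRUE, 50, 40)) == 0))
    expect_error(subtractMask(img, matrix(FALSE, 10, 10)), "shapes differ")
})

test_that("background estimation recovers the configured offset", {
    expect_equal(estimateBackground(matrix(3.5, 30, 30),
                                    roi = c(1, 1, 10, 10)), 3.5)
    out <- wtNoisy(1L)
    arm <- sumProjection(out$image, role = "arm")
    fg <- foregroundMask(out$image)
    est <- estimateBackground(arm, foreground = fg)
    truthBg <- wtProjections()$background
    nPix <- 30 * 30
    sdEst <- sqrt(truthBg / nPix)       # Poisson over the projection sum
    expect_lt(abs(est - truthBg), 3 * sdEst + 1)
    ## an ROI overlapping the foreground is flagged
    expect_warning(estimateBackground(arm, roi = c(150, 100, 20, 20),
                                      foreground = fg), "overlaps")
    expect_error(estimateBackground(arm, roi = c(1, 1, 0, 2)), "positive")
})

test_that("foreground mask covers the cell field as one component", {
    expect_false(any(foregroundMask(matrix(0, 30, 30))))
    out <- wtNoisy(1L)
    fg <- foregroundMask(out$image)
    cm <- out$truth@cellMap
    expect_gte(mean(fg[cm > 0]), 0.98)
    lab <- as.matrix(EBImage::bwlabel(fg + 0))
    expect_equal(max(lab), 1)
})
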