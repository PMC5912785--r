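## Small internal helpers shared across modules.

## Rectangles are c(x, y, w, h), 1-based top-left, inclusive.
rectCheck <- function(roi, dimYX, what = "roi") {
    if (length(roi) != 4L || any(roi[3:4] < 1))
        stop(what, " must be c(x, y, w, h) with positive extent")
    x2 <- roi[1] + roi[3] - 1
    y2 <- roi[2] + roi[4] - 1
    if (roi[1] < 1 || roi[2] < 1 || x2 > dimYX[2] || y2 > dimYX[1])
        stop(what, sprintf(
            " [x=%g..%g, y=%g..%g] falls outside the %d x %d image",
            roi[1], x2, roi[2], y2, dimYX[2], dimYX[1]))
    invisible(TRUE)
}

rectCrop <- function(img, roi) {
    rectCheck(roi, dim(img))
    img[roi[2]:(roi[2] + roi[4] - 1), roi[1]:(roi[1] + roi[3] - 1),
        drop = FALSE]
}

## Mix a user-facing seed with a stream label so sub-generators draw
## independent, reproducible streams while staying below 2^31.
mixSeed <- function(seed, stream = 0L) {
    ## double arithmetic stays exact here and avoids integer overflow
    as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
                   2147483629)
}

## Sample a 3-D Gaussian spot on the integer voxel grid.  Returns a list of
## (z, y, x) index vectors and weights normalised to sum to one, so that
## weight * totalPhotons integrates exactly to totalPhotons before noise.
## Lateral centre may be sub-pixel; axial centre is slice-aligned.
gaussSpotWeights <- function(cz, cy, cx, sigmaXY, sigmaZ, dimZYX) {
    rxy <- ceiling(4 * sigmaXY)
    rz <- max(1L, ceiling(3 * sigmaZ))
    zz <- max(1L, cz - rz):min(dimZYX[1], cz + rz)
    yy <- max(1L, round(cy) - rxy):min(dimZYX[2], round(cy) + rxy)
    xx <- max(1L, round(cx) - rxy):min(dimZYX[3], round(cx) + rxy)
    wz <- exp(-((zz - cz)^2) / (2 * sigmaZ^2))
    wy <- exp(-((yy - cy)^2) / (2 * sigmaXY^2))
    wx <- exp(-((xx - cx)^2) / (2 * sigmaXY^2))
    w <- outer(wz, outer(wy, wx))          # (z, y, x)
    list(z = zz, y = yy, x = xx, w = w / sum(w))
}

addSpot <- function(stack, cz, cy, cx, photons, sigmaXY, sigmaZ) {
    g <- gaussSpotWeights(cz, cy, cx, sigmaXY, sigmaZ, dim(stack))
    stack[g$z, g$y, g$x] <- stack[g$z, g$y, g$x] + photons * g$w
    stack
}

## Camera model: Poisson shot noise on (signal + offset), additive Gaussian
## read noise, floor at zero and hard clip at the saturation ceiling.
applyCamera <- function(signal, offset, readNoiseSd, saturation,
                        noise = TRUE) {
    if (noise) {
        out <- rpois(length(signal), lambda = as.vector(signal) + offset)
        if (readNoiseSd > 0)
            out <- out + rnorm(length(out), sd = readNoiseSd)
        out <- array(out, dim = dim(signal))
    } else {
        out <- signal + offset
    }
    out[out < 0] <- 0
    out[out > saturation] <- saturation
    out
}

## Connected runs of TRUE along a logical vector, merging gaps shorter than
## gapTol; returns a matrix with columns start, end (empty when none).
runIntervals <- function(flag, gapTol = 0L) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iv <- cbind(start = starts[r$values], end = ends[r$values])
    if (nrow(iv) <= 1L || gapTol <= 0L) return(iv)
    keep <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
        if (iv[i, 1] - keep[nrow(keep), 2] - 1L <= gapTol)
            keep[nrow(keep), 2] <- iv[i, 2]
        else keep <- rbind(keep, iv[i, , drop = FALSE])
    }
    keep
}

## 1-D local maxima with minimum separation and minimum height; greedy
## suppression from the highest peak down.  Returns sorted indices.
findPeaks1d <- function(v, minSep, minHeight = -Inf) {
    n <- length(v)
    if (n < 3L) return(integer())
    cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    cand <- cand[v[cand] >= minHeight]
    cand <- cand[order(v[cand], decreasing = TRUE)]
    kept <- integer()
    for (i in cand)
        if (!length(kept) || all(abs(kept - i) >= minSep))
            kept <- c(kept, i)
    sort(kept)
}
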