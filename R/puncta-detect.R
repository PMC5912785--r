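## Punctum detection and nested-ROI intensity integration.  A punctum's
## intensity is integrated over a 15 x 15 px inner ROI with the local
## background taken from the frame between the inner ROI and a surrounding
## 21 x 21 px ROI, per z slice, summed over the contiguous slices containing
## the spot (depth of field = number of Z slices containing a single
## punctum).

innerHalfDefault <- 7L    # 15 x 15 inner ROI
outerHalfDefault <- 10L   # 21 x 21 outer ROI

#' Detect puncta in a GFP Z stack
#'
#' Deterministic 3-D local-maxima detection: candidate voxels exceed all 26
#' neighbours and a minimum height (default: stack median plus `k` robust
#' sds), then greedy suppression enforces a minimum separation, brightest
#' first. For each punctum the contiguous z slices whose in-slice
#' background-subtracted integral exceeds half the peak-slice value are
#' recorded as its depth of field.
#'
#' @param stack numeric `(z, y, x)` array (GFP channel).
#' @param minHeight absolute detection threshold; default
#'   `median(stack) + k * mad(stack)`.
#' @param k robust threshold multiplier used when `minHeight` is `NULL`.
#' @param minSep minimum 3-D separation between puncta, pixels.
#' @param innerHalf,outerHalf half-widths of the nested ROIs (7 and 10 give
#'   the 15 x 15 / 21 x 21 geometry).
#' @return data.frame sorted by descending peak intensity with columns
#'   `id, z, y, x, peak, zlo, zhi, edge`; `edge` flags puncta whose outer ROI
#'   is clipped by the image border (these are excluded from integration).
#'   Empty (0-row) output is allowed.
#' @examples
#' std <- renderStandard(standardSpec("Mif2", nStructures = 12L))
#' nrow(detectPuncta(std$stack))
#' @export
detectPuncta <- function(stack, minHeight = NULL, k = 8, minSep = 4,
                         innerHalf = innerHalfDefault,
                         outerHalf = outerHalfDefault) {
    stopifnot(length(dim(stack)) == 3L)
    nz <- dim(stack)[1]; ny <- dim(stack)[2]; nx <- dim(stack)[3]
    if (is.null(minHeight))
        minHeight <- median(stack) + k * max(mad(stack), 1e-8)
    isMax <- array(TRUE, dim(stack))
    shift <- function(a, dz, dy, dx) {
        zz <- pmin(pmax(seq_len(nz) + dz, 1L), nz)
        yy <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
        xx <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
        a[zz, yy, xx, drop = FALSE]
    }
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        isMax <- isMax & (stack >= shift(stack, dz, dy, dx))
    }
    cand <- which(isMax & stack > minHeight, arr.ind = TRUE)
    if (nrow(cand) == 0L)
        return(data.frame(id = integer(), z = integer(), y = integer(),
                          x = integer(), peak = numeric(), zlo = integer(),
                          zhi = integer(), edge = logical()))
    vals <- stack[cand]
    ord <- order(vals, decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    vals <- vals[ord]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        prev <- which(keep)
        if (!length(prev) ||
            all((cand[prev, 1] - cand[i, 1])^2 +
                (cand[prev, 2] - cand[i, 2])^2 +
                (cand[prev, 3] - cand[i, 3])^2 >= minSep^2))
            keep[i] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    vals <- vals[keep]
    n <- nrow(cand)
    zlo <- zhi <- integer(n)
    edge <- logical(n)
    for (i in seq_len(n)) {
        z <- cand[i, 1]; y <- cand[i, 2]; x <- cand[i, 3]
        edge[i] <- y - outerHalf < 1 || y + outerHalf > ny ||
                   x - outerHalf < 1 || x + outerHalf > nx
        if (edge[i]) { zlo[i] <- zhi[i] <- z; next }
        inSlice <- vapply(seq_len(nz), function(zz)
            sliceIntegral(stack, zz, y, x, innerHalf, outerHalf), 0)
        pk <- inSlice[z]
        if (pk <= 0) { zlo[i] <- zhi[i] <- z; next }
        ok <- inSlice >= pk / 2
        lo <- z; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
        hi <- z; while (hi < nz && ok[hi + 1L]) hi <- hi + 1L
        zlo[i] <- lo; zhi[i] <- hi
    }
    data.frame(id = seq_len(n), z = cand[, 1], y = cand[, 2], x = cand[, 3],
               peak = vals, zlo = zlo, zhi = zhi, edge = edge)
}

## Background-subtracted in-slice integral over the nested ROIs.
sliceIntegral <- function(stack, z, y, x, innerHalf, outerHalf,
                          bgStat = "median") {
    inner <- stack[z, (y - innerHalf):(y + innerHalf),
                   (x - innerHalf):(x + innerHalf)]
    outer <- stack[z, (y - outerHalf):(y + outerHalf),
                   (x - outerHalf):(x + outerHalf)]
    frameSum <- sum(outer) - sum(inner)
    frameN <- length(outer) - length(inner)
    bg <- if (bgStat == "median") {
        om <- outer
        om[(outerHalf - innerHalf + 1):(outerHalf + innerHalf + 1),
           (outerHalf - innerHalf + 1):(outerHalf + innerHalf + 1)] <- NA
        median(om, na.rm = TRUE)
    } else frameSum / frameN
    sum(inner) - length(inner) * bg
}

#' Integrated intensity of one punctum
#'
#' Per-slice (sum over the 15 x 15 inner ROI) minus (inner area times a
#' background statistic of the 21 x 21 outer-frame pixels), summed over the
#' punctum's contiguous z slices. Constant background offsets cancel
#' exactly. Negative totals are clipped to zero with a warning.
#'
#' @param punctum one row of a [detectPuncta()] data.frame (or any list with
#'   `z, y, x, zlo, zhi`).
#' @param stack numeric `(z, y, x)` array.
#' @param innerHalf,outerHalf nested-ROI half-widths.
#' @param bgStat background statistic over the outer frame: `"median"`
#'   (default; robust to neighbouring structures overlapping the frame in
#'   a dense epithelium) or `"mean"`.
#' @return scalar background-subtracted integrated intensity.
#' @export
integratedIntensity <- function(punctum, stack,
                                innerHalf = innerHalfDefault,
                                outerHalf = outerHalfDefault,
                                bgStat = c("median", "mean")) {
    bgStat <- match.arg(bgStat)
    ny <- dim(stack)[2]; nx <- dim(stack)[3]
    y <- punctum$y; x <- punctum$x
    if (y - outerHalf < 1 || y + outerHalf > ny ||
        x - outerHalf < 1 || x + outerHalf > nx)
        stop("outer ROI clipped by the image edge; punctum excluded")
    zz <- punctum$zlo:punctum$zhi
    tot <- sum(vapply(zz, function(z)
        sliceIntegral(stack, z, y, x, innerHalf, outerHalf, bgStat), 0))
    if (tot < 0) {
        warning("negative integrated intensity clipped to 0")
        tot <- 0
    }
    tot
}

#' Integrate intensities for a table of detected puncta
#'
#' Applies [integratedIntensity()] to every non-edge punctum; edge puncta
#' receive `NA` and stay flagged.
#'
#' @param puncta data.frame from [detectPuncta()].
#' @param stack numeric `(z, y, x)` array.
#' @param ... passed to [integratedIntensity()].
#' @return the table with an `intensity` column added.
#' @export
integratePuncta <- function(puncta, stack, ...) {
    puncta$intensity <- NA_real_
    for (i in seq_len(nrow(puncta)))
        if (!puncta$edge[i])
            puncta$intensity[i] <-
                integratedIntensity(puncta[i, ], stack, ...)
    puncta
}

#' Exclude puncta that reach the camera saturation ceiling
#'
#' A punctum is excluded when any pixel of its inner ROI, within its z
#' slices, is at or above `saturationLevel` -- the brightest (presumed
#' largest) structures exceed the linear range of the calibration standards
#' and cannot be counted.
#'
#' @param puncta data.frame from [detectPuncta()].
#' @param stack numeric `(z, y, x)` array.
#' @param saturationLevel camera ceiling; `Inf` keeps everything.
#' @param innerHalf inner-ROI half-width.
#' @return list with `kept` and `excluded` data.frames.
#' @export
saturationFilter <- function(puncta, stack, saturationLevel,
                             innerHalf = innerHalfDefault) {
    if (nrow(puncta) == 0L || !is.finite(saturationLevel))
        return(list(kept = puncta, excluded = puncta[0, ]))
    ny <- dim(stack)[2]; nx <- dim(stack)[3]
    sat <- vapply(seq_len(nrow(puncta)), function(i) {
        y <- puncta$y[i]; x <- puncta$x[i]
        yy <- max(1, y - innerHalf):min(ny, y + innerHalf)
        xx <- max(1, x - innerHalf):min(nx, x + innerHalf)
        any(stack[puncta$zlo[i]:puncta$zhi[i], yy, xx] >= saturationLevel)
    }, TRUE)
    list(kept = puncta[!sat, , drop = FALSE],
         excluded = puncta[sat, , drop = FALSE])
}
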