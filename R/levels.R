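#' Construct a FoldMeasure
#'
#' A fold ratio between two species (e.g. from immunoblot densitometry).
#' Folds above 5 or below 0.2 must be verified by serial dilution; an
#' unverified extreme fold triggers a warning (values acquired from
#' dilutions are the ones to report).
#'
#' @param numerator,denominator species labels.
#' @param fold ratio (> 0).
#' @param sd standard deviation over blots.
#' @param nBlots number of blots.
#' @param dilutionVerified whether an extreme fold was dilution-verified.
#' @return a [FoldMeasure-class].
#' @examples
#' foldMeasure("GFP:APC2", "Axin:GFP", 4.3, 1.4, 4L)
#' @export
foldMeasure <- function(numerator, denominator, fold, sd = 0, nBlots = 1L,
                        dilutionVerified = FALSE) {
    if ((fold > 5 || fold < 0.2) && !dilutionVerified)
        warning("fold ", signif(fold, 3), " (", numerator, "/", denominator,
                ") exceeds 5-fold and is not dilution-verified")
    new("FoldMeasure", numerator = numerator, denominator = denominator,
        fold = fold, sd = sd, nBlots = as.integer(nBlots),
        dilutionVerified = dilutionVerified)
}

#' FPKM abundance ratio between two genes at a stage
#'
#' @param table data.frame with columns `gene`, `stage`, `fpkm`
#'   (non-negative; one row per gene/stage).
#' @param geneA,geneB numerator and denominator genes.
#' @param stage developmental stage label.
#' @param rounded also round to the nearest integer fold, the printed "~Nx"
#'   convention.
#' @return list with `ratio` and (when `rounded`) `fold` (integer).
#' @examples
#' tab <- data.frame(gene = c("APC2", "APC1"), stage = "early",
#'                   fpkm = c(484, 26))
#' fpkmRatio(tab, "APC2", "APC1", "early")$fold   # ~19x
#' @export
fpkmRatio <- function(table, geneA, geneB, stage, rounded = TRUE) {
    pick <- function(g) {
        r <- table[table$gene == g & table$stage == stage, "fpkm"]
        if (length(r) != 1L)
            stop("need exactly one FPKM value for ", g, " at stage ", stage,
                 " (found ", length(r), ")")
        r
    }
    a <- pick(geneA); b <- pick(geneB)
    if (b == 0) stop("denominator FPKM is zero for ", geneB)
    out <- list(ratio = a / b)
    if (rounded) out$fold <- round(a / b)
    out
}

#' Normalize a blot band to its loading control
#'
#' @param bandIntensity band densitometry value.
#' @param loadingIntensity loading-control (tubulin) densitometry value
#'   (> 0).
#' @return normalized intensity.
#' @export
normalizeBand <- function(bandIntensity, loadingIntensity) {
    if (any(loadingIntensity <= 0))
        stop("loading-control intensity must be > 0")
    bandIntensity / loadingIntensity
}

#' Chain fold measures into a combined fold
#'
#' Composes an ordered chain of fold ratios into a single fold between the
#' first numerator and the last denominator, inverting links as needed so
#' adjacent labels match; an unmatched link is an error. The combined fold
#' is the product of the (possibly inverted) folds; its sd comes from
#' first-order propagation, with relative sds added in quadrature.
#'
#' @param measures list of [FoldMeasure-class] in chain order.
#' @return a [FoldMeasure-class] for the combined comparison.
#' @examples
#' m <- list(foldMeasure("GFP:APC2", "Axin:GFP", 4.3, 1.4, 4L),
#'           foldMeasure("Axin:GFP", "Axin", 1.0, 0.5, 4L),
#'           foldMeasure("GFP:APC2", "APC2", 0.9, 0.4, 4L))
#' chainFolds(m)   # GFP:APC2 cancels: APC2-to-Axin fold ~ 4.8
#' @export
chainFolds <- function(measures) {
    stopifnot(length(measures) >= 1L,
              all(vapply(measures, is, TRUE, "FoldMeasure")))
    if (length(measures) == 1L) return(measures[[1]])
    num <- measures[[1]]@numerator
    den <- measures[[1]]@denominator
    fold <- measures[[1]]@fold
    relVar <- (measures[[1]]@sd / measures[[1]]@fold)^2
    for (i in 2:length(measures)) {
        nxt <- measures[[i]]
        ## a link may extend the chain at either open end, inverted if
        ## needed, so shared labels cancel
        if (identical(den, nxt@numerator)) {
            den <- nxt@denominator; fold <- fold * nxt@fold
        } else if (identical(den, nxt@denominator)) {
            den <- nxt@numerator; fold <- fold / nxt@fold
        } else if (identical(num, nxt@denominator)) {
            num <- nxt@numerator; fold <- fold * nxt@fold
        } else if (identical(num, nxt@numerator)) {
            num <- nxt@denominator; fold <- fold / nxt@fold
        } else {
            stop("chain broken at link ", i, ": '", num, "/", den,
                 "' does not compose with '", nxt@numerator, "/",
                 nxt@denominator, "'")
        }
        relVar <- relVar + (nxt@sd / nxt@fold)^2
    }
    cur <- new("FoldMeasure", numerator = num, denominator = den,
               fold = fold, sd = 0, nBlots = 1L, dilutionVerified = TRUE)
    new("FoldMeasure", numerator = cur@numerator,
        denominator = cur@denominator, fold = fold,
        sd = fold * sqrt(relVar),
        nBlots = min(vapply(measures, function(m) m@nBlots, 1L)),
        dilutionVerified = TRUE)
}

#' Format a fold the way results are printed
#'
#' @param fold numeric fold.
#' @return character like `"~5x"`.
#' @export
formatFold <- function(fold) paste0("~", round(fold), "x")

#' One-sample t test of blot folds against no change
#'
#' Tests whether fold values across blots differ from `null` (default 1, no
#' change) with a standard one-sample t test.
#'
#' @param folds numeric vector of per-blot fold values (n >= 2).
#' @param null null fold.
#' @return list with `t`, `p`, `df`, `degenerate` (`TRUE` when the sd is
#'   zero, where the t statistic is undefined).
#' @export
oneSampleFoldTest <- function(folds, null = 1) {
    if (length(folds) < 2L) stop("need at least 2 blots")
    if (sd(folds) == 0) {
        return(list(t = if (mean(folds) == null) 0 else Inf,
                    p = if (mean(folds) == null) 1 else 0,
                    df = length(folds) - 1L, degenerate = TRUE))
    }
    tt <- t.test(folds, mu = null)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), degenerate = FALSE)
}
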