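## The statistical battery applied to quantification outputs.  All tests are
## two-sided; stripe/interstripe Arm values were generally normally
## distributed (checked with both normality tests below), so parametric
## tests are the default.

#' Paired t test between intragroup measurements
#'
#' @param groupA,groupB equal-length, pair-aligned numeric vectors (n >= 2
#'   pairs).
#' @return list with `t`, `p`, `df`, `degenerate` (`TRUE` when the paired
#'   differences have zero sd).
#' @export
pairedT <- function(groupA, groupB) {
    if (length(groupA) != length(groupB))
        stop("paired groups must be aligned: lengths ", length(groupA),
             " and ", length(groupB), " differ")
    if (length(groupA) < 2L) stop("need at least 2 pairs")
    d <- groupA - groupB
    if (sd(d) == 0)
        return(list(t = if (mean(d) == 0) 0 else Inf,
                    p = if (mean(d) == 0) 1 else 0,
                    df = length(d) - 1L, degenerate = TRUE))
    tt <- t.test(groupA, groupB, paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), degenerate = FALSE)
}

#' Unpaired t test between intergroup measurements
#'
#' Classic (equal-variance) two-sample t test by default; Welch via
#' `welch = TRUE`.
#'
#' @param groupA,groupB numeric vectors (each n >= 2).
#' @param welch use the Welch unequal-variance form.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
unpairedT <- function(groupA, groupB, welch = FALSE) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("need at least 2 values per group")
    if (sd(c(groupA, groupB)) == 0)
        return(list(t = 0, p = 1,
                    df = length(groupA) + length(groupB) - 2L,
                    degenerate = TRUE))
    tt <- t.test(groupA, groupB, var.equal = !welch)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), degenerate = FALSE)
}

#' One-way ANOVA with Dunnett's multiple-comparisons test
#'
#' Ordinary one-way ANOVA followed by Dunnett's test of every group against
#' the control, with familywise-adjusted p values.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param controlLabel name of the control group.
#' @return list with `F`, `anovaP`, and `comparisons` (data.frame `group,
#'   estimate, t, pAdjusted`).
#' @examples
#' set.seed(1)
#' g <- list(wt = rnorm(8), mutA = rnorm(8), mutB = rnorm(8, 2))
#' anovaDunnett(g, "wt")$comparisons
#' @export
anovaDunnett <- function(groups, controlLabel) {
    if (length(groups) < 2L) stop("need at least 2 groups")
    if (!controlLabel %in% names(groups))
        stop("control group '", controlLabel, "' not found (have: ",
             paste(names(groups), collapse = ", "), ")")
    df <- data.frame(
        value = unlist(groups, use.names = FALSE),
        group = factor(rep(names(groups), lengths(groups)),
                       levels = c(controlLabel,
                                  setdiff(names(groups), controlLabel))))
    fit <- aov(value ~ group, data = df)
    an <- anova(fit)
    gl <- multcomp::glht(fit,
                         linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    comp <- data.frame(
        group = sub(" - .*$", "", names(sm$test$coefficients)),
        estimate = unname(sm$test$coefficients),
        t = unname(sm$test$tstat),
        pAdjusted = unname(sm$test$pvalues))
    list(F = an[["F value"]][1], anovaP = an[["Pr(>F)"]][1],
         comparisons = comp)
}

#' Significance stars for p values
#'
#' The conventional `*` (p < 0.05) to `****` (p < 0.0001) coding.
#'
#' @param p numeric p values.
#' @return character vector of stars (`"ns"` when p >= 0.05).
#' @export
pStars <- function(p) {
    cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
        labels = c("****", "***", "**", "*", "ns"))
}

#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines z transforms of sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into the omnibus K2 statistic, chi-squared with 2 df
#' under normality. Requires n >= 20 for the kurtosis approximation.
#'
#' @param values numeric sample.
#' @return list with `k2`, `p`, `zSkew`, `zKurt`, `n`.
#' @export
dagostinoPearson <- function(values) {
    x <- values[!is.na(values)]
    n <- length(x)
    if (n < 20L) stop("D'Agostino-Pearson test needs n >= 20 (n = ", n, ")")
    if (sd(x) == 0) stop("sample is constant; normality test undefined")
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    b1 <- m3 / m2^1.5
    b2 <- m4 / m2^2
    ## skewness transform (D'Agostino 1970)
    y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    w2 <- -1 + sqrt(2 * (beta2 - 1))
    delta <- 1 / sqrt(log(sqrt(w2)))
    alpha <- sqrt(2 / (w2 - 1))
    zS <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
    ## kurtosis transform (Anscombe & Glynn 1983)
    eb2 <- 3 * (n - 1) / (n + 1)
    vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    xk <- (b2 - eb2) / sqrt(vb2)
    sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
        sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
    zK <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
        sqrt(2 / (9 * a))
    k2 <- zS^2 + zK^2
    list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
         zSkew = zS, zKurt = zK, n = n)
}

#' Run both normality tests used for the Arm level values
#'
#' D'Agostino-Pearson omnibus and Shapiro-Wilk; a test whose sample-size
#' requirements are not met is skipped with a note rather than failing.
#'
#' @param values numeric sample.
#' @return data.frame with `test`, `statistic`, `p`, `note`.
#' @export
normalityCheck <- function(values) {
    x <- values[!is.na(values)]
    out <- data.frame(test = c("dagostino_pearson", "shapiro_wilk"),
                      statistic = NA_real_, p = NA_real_, note = "")
    if (length(x) >= 2L && sd(x) == 0) {
        out$note <- "constant sample; tests undefined"
        return(out)
    }
    if (length(x) >= 20L) {
        dp <- dagostinoPearson(x)
        out$statistic[1] <- dp$k2; out$p[1] <- dp$p
    } else out$note[1] <- "n < 20: skipped"
    if (length(x) >= 3L && length(x) <= 5000L) {
        sw <- shapiro.test(x)
        out$statistic[2] <- unname(sw$statistic); out$p[2] <- sw$p.value
    } else out$note[2] <- "n outside 3..5000: skipped"
    out
}
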