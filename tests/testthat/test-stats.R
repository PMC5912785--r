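## Hand-coded formula oracles, independent of stats::t.test
oracleUnpairedT <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}
oraclePairedT <- function(a, b) {
    d <- a - b; n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
    list(t = t, p = 2 * pt(-abs(t), n - 1))
}

test_that("paired t test matches its formula oracle", {
    expect_equal(pairedT(c(1, 2, 3), c(1, 2, 3))$t, 0)
    expect_equal(pairedT(c(1, 2, 3), c(1, 2, 3))$p, 1)
    ## constant nonzero difference: sd zero, flagged degenerate
    r <- pairedT(c(2, 3, 4), c(1, 2, 3))
    expect_true(r$degenerate)
    set.seed(81)
    a <- rnorm(12, 10); b <- a + rnorm(12, 0.5)
    got <- pairedT(a, b); want <- oraclePairedT(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_error(pairedT(1:3, 1:4), "aligned")
})

test_that("unpaired t test matches its formula oracle", {
    g <- c(4, 5, 6)
    expect_equal(unpairedT(g, g)$p, 1)
    expect_lt(unpairedT(rnorm(20), rnorm(20) + 50)$p, 1e-10)
    set.seed(82)
    a <- rnorm(10, 5); b <- rnorm(14, 6)
    got <- unpairedT(a, b); want <- oracleUnpairedT(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    ## Welch variant reports fractional degrees of freedom
    expect_false(unpairedT(a, b, welch = TRUE)$df == got$df)
})

test_that("ANOVA/Dunnett behaves on identical and shifted groups", {
    v <- c(1.2, 1.8, 0.9, 1.5, 1.1, 1.6)
    same <- list(ctrl = v, g1 = v, g2 = v)
    r <- anovaDunnett(same, "ctrl")
    expect_equal(r$F, 0, tolerance = 1e-12)
    expect_equal(r$anovaP, 1, tolerance = 1e-12)
    expect_true(all(r$comparisons$pAdjusted > 0.99))
    ## adjusted p is never smaller than the per-comparison p
    set.seed(83)
    g <- list(ctrl = rnorm(8), a = rnorm(8, 0.5), b = rnorm(8, 1),
              c = rnorm(8, 1.5))
    rr <- anovaDunnett(g, "ctrl")
    dfres <- sum(lengths(g)) - length(g)
    unadj <- 2 * pt(-abs(rr$comparisons$t), dfres)
    expect_true(all(rr$comparisons$pAdjusted >= unadj - 1e-6))
    expect_error(anovaDunnett(g, "missing"), "not found")
})

test_that("Dunnett familywise type-I error is controlled at 5%", {
    set.seed(84)
    reps <- 3000
    hits <- 0L
    for (i in seq_len(reps)) {
        g <- split(rnorm(50), rep(1:5, each = 10))
        names(g) <- c("ctrl", "a", "b", "c", "d")
        p <- anovaDunnett(g, "ctrl")$comparisons$pAdjusted
        if (any(p < 0.05)) hits <- hits + 1L
    }
    expect_equal(hits / reps, 0.05, tolerance = 0.01 / 0.05)
})

test_that("significance stars follow the conventional coding", {
    expect_equal(as.character(pStars(c(0.2, 0.03, 0.004, 3e-4, 5e-5))),
                 c("ns", "*", "**", "***", "****"))
})

test_that("the D'Agostino-Pearson omnibus matches scipy's oracle", {
    x <- c(12.1, 9.8, 10.5, 11.2, 8.9, 10.1, 9.5, 11.8, 10.9, 9.2,
           10.4, 11.1, 9.9, 10.2, 8.5, 12.4, 10.8, 9.4, 10.6, 11.5,
           9.1, 10.3, 11.9, 8.8, 10.7)
    dp <- dagostinoPearson(x)
    expect_equal(dp$k2, 1.0764227608, tolerance = 1e-8)
    expect_equal(dp$p, 0.5837915000, tolerance = 1e-8)
    z <- c(0.1, 0.2, 0.2, 0.3, 0.4, 0.4, 0.5, 0.6, 0.8, 1.0, 1.2, 1.5,
           2.0, 2.6, 3.5, 4.7, 6.0, 8.2, 11.0, 15.0)
    dz <- dagostinoPearson(z)
    expect_equal(dz$k2, 15.2290927650, tolerance = 1e-8)
    expect_equal(dz$p, 0.0004932244, tolerance = 1e-6)
    expect_error(dagostinoPearson(rnorm(10)), "n >= 20")
    expect_error(dagostinoPearson(rep(1, 25)), "constant")
})

test_that("normality checks behave across sample types", {
    set.seed(85)
    ## a large normal sample usually passes both tests
    passes <- vapply(1:40, function(i) {
        r <- normalityCheck(rnorm(100))
        all(r$p > 0.05, na.rm = TRUE)
    }, TRUE)
    expect_gt(mean(passes), 0.7)
    ## heavy-tailed samples are rejected far above the 5% rate
    rejects <- vapply(1:40, function(i) {
        r <- normalityCheck(rcauchy(100))
        any(r$p < 0.05, na.rm = TRUE)
    }, TRUE)
    expect_gt(mean(rejects), 0.9)
    ## degenerate / too-small samples are noted, not errors
    rc <- normalityCheck(rep(2, 30))
    expect_true(all(rc$note != ""))
    rs <- normalityCheck(rnorm(10))
    expect_match(rs$note[1], "skipped")
    expect_false(is.na(rs$p[2]))   # Shapiro-Wilk still runs at n = 10
})
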