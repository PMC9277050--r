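test_that("the mean + 2SD cutoff uses the sample SD and a strict boundary", {
    expect_equal(methylationCutoff(rep(0.10, 5)), 0.10)
    expect_equal(methylationCutoff(c(0, 2)), 1 + 2 * sqrt(2))
    expect_error(methylationCutoff(0.5), ">= 2")
    # a value exactly at the cutoff is non-hypermethylated
    cut <- methylationCutoff(c(0.1, 0.2, 0.3))
    expect_equal(as.character(dichotomize(c(cut, cut + 1e-9), cut)),
                 c("non", "hyper"))
})

test_that("about 2.3% of normal controls exceed their mean + 2SD cutoff", {
    set.seed(123)
    rate <- mean(replicate(400, {
        ctrl <- rnorm(500, 0.3, 0.1)
        mean(rnorm(2000, 0.3, 0.1) > methylationCutoff(ctrl))
    }))
    expect_lt(abs(rate - pnorm(-2)), 0.01)
})

test_that("Fisher exact reproduces the published mutation comparisons", {
    # counts from the two-group mutation rows of the clinical table
    expect_equal(round(fisherExact2x2(1, 61, 2, 30), 3), 0.266)   # CEBPA
    expect_equal(round(fisherExact2x2(3, 59, 1, 31), 3), 1.000)   # IDH1/2
    expect_equal(round(fisherExact2x2(2, 60, 1, 31), 3), 1.000)   # DNMT3A
    expect_equal(round(fisherExact2x2(1, 61, 5, 27), 3), 0.016)   # U2AF1
    expect_equal(round(fisherExact2x2(2, 60, 1, 31), 3), 1.000)   # SRSF2
    expect_equal(round(fisherExact2x2(3, 59, 3, 29), 3), 0.406)   # SF3B1
    expect_equal(fisherExact2x2(0, 62, 1, 31), 32 / 94)           # SETBP1
    expect_equal(fisherExact2x2(1, 1, 1, 1), 1)
    expect_warning(p <- fisherExact2x2(0, 0, 3, 4), "degenerate")
    expect_equal(p, 1)
})

test_that("Fisher exact equals exhaustive enumeration and is swap-invariant", {
    set.seed(99)
    for (i in 1:60) {
        n <- sample(4:200, 1)
        a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
        c <- sample(0:(n - a - b), 1); d <- n - a - b - c
        if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
        p <- fisherExact2x2(a, b, c, d)
        expect_equal(p, fisherEnumOracle(a, b, c, d), tolerance = 1e-7)
        # simultaneous row + column swap leaves p unchanged
        expect_equal(p, fisherExact2x2(d, c, b, a), tolerance = 1e-12)
    }
})

test_that("Pearson chi-square matches the direct formula", {
    expect_equal(pearsonChi2(matrix(c(10, 10, 10, 10), 2))$p.value, 1)
    tab <- matrix(c(8, 2, 5, 5, 12, 1, 7, 3, 2, 9, 4, 6), 3, 4)
    r <- pearsonChi2(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r$statistic, sum((tab - E)^2 / E))
    expect_equal(r$df, 6)
    expect_equal(r$p.value, pchisq(sum((tab - E)^2 / E), 6,
                                   lower.tail = FALSE))
    expect_error(pearsonChi2(matrix(c(0, 0, 3, 4), 2)), "Fisher")
})

test_that("Mann-Whitney switches between exact and normal branches", {
    expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
    r <- mannWhitney(c(1, 2), c(3, 4))
    expect_equal(r$method, "exact")
    expect_equal(r$p.value, 2 / 6)
    expect_equal(r$p.value, mannWhitneyEnumOracle(c(1, 2), c(3, 4)))
    # exact and normal branches agree closely at n1 = n2 = 6
    set.seed(7)
    x <- rnorm(6); y <- rnorm(6, 1)
    exact <- mannWhitney(x, y)$p.value
    normal <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value
    expect_lt(abs(exact - normal), 0.02)
    # a larger exact case against the enumeration oracle
    expect_equal(mannWhitney(x, y)$p.value, mannWhitneyEnumOracle(x, y))
})

test_that("Spearman correlation is rank-then-Pearson with a t p-value", {
    expect_equal(spearmanCor(1:10, (1:10)^2)$rho, 1)
    expect_equal(spearmanCor(1:10, -(1:10)^3)$rho, -1)
    set.seed(8)
    x <- rnorm(30); y <- x + rnorm(30)
    r <- spearmanCor(x, y)
    rho <- cor(rank(x), rank(y))
    expect_equal(r$rho, rho)
    tstat <- rho * sqrt(28 / (1 - rho^2))
    expect_equal(r$p.value, 2 * pt(-abs(tstat), 28), tolerance = 1e-6)
    expect_warning(r0 <- spearmanCor(rep(1, 5), 1:5), "constant")
    expect_true(is.na(r0$rho))
})

test_that("group comparison dispatches to the conventional test", {
    df <- data.frame(
        grp = rep(c("non", "hyper"), c(62, 32)),
        U2AF1 = c(rep(1, 1), rep(0, 61), rep(1, 5), rep(0, 27)),
        sex = c(rep("m", 39), rep("f", 23), rep("m", 19), rep("f", 13)),
        blasts = c(rnorm(62, 6, 3), rnorm(32, 3, 2)))
    r <- compareGroups(df, "U2AF1", "grp", "categorical")
    expect_equal(r$test, "fisher")
    expect_equal(round(r$p.value, 3), 0.016)
    r2 <- compareGroups(df, "sex", "grp", "categorical")
    expect_equal(r2$test, "chi-square")
    r3 <- compareGroups(df, "blasts", "grp", "continuous")
    expect_match(r3$test, "mann-whitney")
    df$empty <- NA_real_
    expect_error(compareGroups(df, "empty", "grp", "continuous"),
                 "no non-missing")
    expect_error(compareGroups(df, "nope", "grp", "continuous"), "unknown")
    tab <- clinicalComparison(df, "grp", continuous = "blasts",
                              categorical = c("sex", "U2AF1"))
    expect_equal(nrow(tab), 3)
    expect_true(all(tab$p >= 0 & tab$p <= 1))
})
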