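makeCalls <- function(M, U, pos, group = NULL) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
    cd <- S4Vectors::DataFrame(sample = colnames(M),
                               row.names = colnames(M))
    if (!is.null(group)) cd$group <- group
    CpGCallSet(M, U, gr, cd)
}

test_that("unit aggregation sums covered CpGs and applies the filters", {
    # two CpGs in the unit: (5 meth / 10 total), (15/20) -> 20/30
    M <- cbind(s1 = c(5L, 15L, 3L))
    U <- cbind(s1 = c(5L, 5L, 0L))
    calls <- makeCalls(M, U, pos = c(100, 150, 300))
    units <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(50, 280), c(200, 320)))
    units$unit_id <- c("uA", "uB"); units$kind <- "fragment"
    m <- unitMethylation(calls, units, min_cov = 5)
    expect_equal(methFraction(m)["uA", "s1"], 20 / 30)
    # CpG with coverage 3 < min_cov 5 leaves uB uncovered -> dropped
    expect_false("uB" %in% rownames(m))
    # but retained at a permissive threshold
    m2 <- unitMethylation(calls, units, min_cov = 1)
    expect_equal(methFraction(m2)["uB", "s1"], 1)

    # a unit uncovered in any one sample is dropped entirely
    M3 <- cbind(s1 = 5L, s2 = 0L); U3 <- cbind(s1 = 5L, s2 = 0L)
    calls3 <- makeCalls(M3, U3, pos = 100)
    u3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150))
    u3$unit_id <- "u"; u3$kind <- "fragment"
    expect_warning(m3 <- unitMethylation(calls3, u3, min_cov = 5),
                   "no unit")
    expect_equal(nrow(m3), 0L)
})

test_that("global methylation is the read-weighted fraction", {
    M <- cbind(s1 = c(2L, 2L)); U <- cbind(s1 = c(0L, 0L))
    expect_equal(unname(globalMethylation(makeCalls(M, U, c(10, 20)),
                                          min_cov = 1)), 1)
    M2 <- cbind(s1 = c(1L, 0L)); U2 <- cbind(s1 = c(1L, 2L))
    expect_equal(unname(globalMethylation(makeCalls(M2, U2, c(10, 20)),
                                          min_cov = 1)), 0.25)
    # no covered CpG -> NA with warning
    expect_warning(
        g <- globalMethylation(makeCalls(M2, U2, c(10, 20)), min_cov = 50),
        "without covered")
    expect_true(is.na(g[["s1"]]))
})

test_that("pooled t test reproduces the published global comparison", {
    p <- compareGlobal(c(51.2, 38.9, 43.3, 42.3, 44.8),
                       c(51.0, 49.3, 49.4, 45.4))$p.value
    expect_equal(round(p, 3), 0.106)
    expect_equal(compareGlobal(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
    expect_warning(r <- compareGlobal(c(0, 0), c(1, 1)), "degenerate")
    expect_equal(r$p.value, 0)
    expect_warning(r2 <- compareGlobal(c(2, 2), c(2, 2)), "degenerate")
    expect_equal(r2$p.value, 1)
    expect_error(compareGlobal(1, c(1, 2)), ">= 2 values")
})

test_that("BH adjustment follows the step-up formula", {
    expect_equal(bhAdjust(0.05), 0.05)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0,1\\]")
    set.seed(1)
    p <- runif(100)
    q <- bhAdjust(p)
    expect_true(all(q >= p - 1e-12 & q <= 1))
    # q order is monotone in p order
    expect_true(all(diff(q[order(p)]) > -1e-12))
})

test_that("DMF status obeys the triple-threshold invariant", {
    d <- makeTinyDataset(seed = 31, contig_len = 40000,
        planted = NULL)
    fr <- d$fragments
    eff <- data.frame(unit_id = fr$unit_id[seq_len(20)],
                      delta = rep(c(0.4, -0.4), 10))
    des <- simDesign(plantedEffects = eff, seed = 32)
    calls <- simulateMethylome(d$sim$genome, fr, des)
    m <- unitMethylation(calls, fr)
    for (test in c("ttest", "fisher")) {
        dm <- callDmf(m, test = test)
        sig <- dm$p < 0.05 & dm$q < 0.05
        expect_identical(dm$status == "hyper", sig & dm$diff > 0.25)
        expect_identical(dm$status == "hypo", sig & dm$diff < -0.25)
        expect_equal(sum(dm$status %in% c("hyper", "hypo", "ns")), nrow(dm))
        # group means are unweighted means over samples
        fr_m <- methFraction(m)
        ca <- colData(m)$group == "case"
        expect_equal(dm$mean_case, unname(rowMeans(fr_m[, ca])))
        expect_equal(dm$diff, dm$mean_case - dm$mean_ctrl)
    }
})

test_that("pooled Fisher p per unit equals hypergeometric enumeration", {
    d <- makeTinyDataset(seed = 41, contig_len = 20000, depthMean = 8)
    m <- unitMethylation(d$calls, d$fragments, min_cov = 1)
    dm <- callDmf(m, test = "fisher")
    ca <- colData(m)$group == "case"
    m1 <- rowSums(methCounts(m)[, ca]); t1 <- rowSums(totalCounts(m)[, ca])
    m2 <- rowSums(methCounts(m)[, !ca]); t2 <- rowSums(totalCounts(m)[, !ca])
    small <- which(t1 + t2 <= 500)
    expect_gt(length(small), 20)
    for (i in small[seq_len(min(50, length(small)))])
        expect_equal(dm$p[i],
                     fisherEnumOracle(m1[i], t1[i] - m1[i], m2[i],
                                      t2[i] - m2[i]),
                     tolerance = 1e-7)
})

test_that("the default per-unit test needs replicates, Fisher does not", {
    M <- cbind(case_1 = 10L, ctrl_1 = 2L)
    U <- cbind(case_1 = 2L, ctrl_1 = 10L)
    calls <- makeCalls(M, U, pos = 100, group = c("case", "ctrl"))
    u <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150))
    u$unit_id <- "u"; u$kind <- "fragment"
    m <- unitMethylation(calls, u, min_cov = 1)
    expect_error(callDmf(m, test = "ttest"), "2 samples per group")
    dm <- callDmf(m, test = "fisher")
    expect_equal(dm$p, fisherEnumOracle(10, 2, 2, 10), tolerance = 1e-7)
})
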