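simSurv <- function(n, beta = 0, seed = 1, censor = 0.02, h0 = 0.05) {
    set.seed(seed)
    x <- rbinom(n, 1, 0.4)
    ev <- rexp(n, h0 * exp(beta * x))
    cn <- rexp(n, censor)
    list(x = x, time = pmin(ev, cn), event = as.integer(ev <= cn))
}

test_that("product-limit estimate matches hand computation and survfit", {
    km <- kmFit(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km@surv, c(2 / 3, 1 / 3, 0))
    expect_equal(km@n.risk, c(3L, 2L, 1L))

    expect_true(all(kmFit(c(1, 2, 3), c(0, 0, 0))@surv == 1))

    d <- simSurv(80, seed = 4)
    km2 <- kmFit(d$time, d$event)
    sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    expect_equal(km2@surv, sf$surv, tolerance = 1e-12)
    expect_equal(km2@n.risk, sf$n.risk)
    expect_equal(km2@n.event, sf$n.event)
})

test_that("without censoring the KM curve is 1 - ECDF of event times", {
    set.seed(15)
    t <- rexp(60)
    km <- kmFit(t, rep(1, 60))
    expect_equal(km@surv, 1 - ecdf(t)(km@time), tolerance = 1e-12)
    expect_equal(kmSurvAt(km, -1), 1)
})

test_that("log-rank is zero for identical groups and label-swap invariant", {
    t <- c(2, 4, 4, 7, 9, 12); e <- c(1, 1, 0, 1, 0, 1)
    r <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 6))
    expect_equal(r$statistic, 0)
    expect_equal(r$p.value, 1)

    d <- simSurv(100, beta = 0.8, seed = 5)
    r1 <- logrankTest(d$time, d$event, d$x)
    r2 <- logrankTest(d$time, d$event, 1 - d$x)
    expect_equal(r1$statistic, r2$statistic)
    sd1 <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$x)
    expect_equal(r1$statistic, sd1$chisq, tolerance = 1e-10)
    expect_error(logrankTest(d$time, d$event, rep("a", 100)), "two non-empty")
})

test_that("log-rank keeps its nominal size under label permutation", {
    d <- simSurv(40, beta = 0, seed = 6)
    set.seed(60)
    rej <- mean(replicate(1000, {
        g <- sample(d$x)
        logrankTest(d$time, d$event, g)$p.value < 0.05
    }))
    expect_lt(abs(rej - 0.05), 0.02)
})

test_that("log-rank detects a strong hazard ratio", {
    hits <- vapply(1:30, function(i) {
        d <- simSurv(400, beta = log(3), seed = 100 + i)
        logrankTest(d$time, d$event, d$x)$p.value < 0.001
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("Cox fit agrees with the reference implementation on tied data", {
    set.seed(20)
    n <- 120
    x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
    ev <- rexp(n, 0.1 * exp(0.5 * x[, "a"] - 0.3 * x[, "b"]))
    time <- ceiling(ev * 4) / 4                        # force ties
    event <- rbinom(n, 1, 0.8)
    for (ties in c("efron", "breslow")) {
        fit <- coxFit(x, time, event, ties = ties)
        ref <- survival::coxph(survival::Surv(time, event) ~ a + b,
                               data = data.frame(x), ties = ties)
        expect_equal(unname(fit@coef), unname(coef(ref)), tolerance = 1e-6)
        expect_equal(unname(fit@se),
                     unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
        expect_equal(fit@loglik, ref$loglik[2], tolerance = 1e-8)
    }
})

test_that("the score vanishes at the optimum and matches numeric gradients", {
    d <- simSurv(150, beta = 0.7, seed = 21)
    fit <- coxFit(cbind(x = d$x), d$time, d$event)
    at <- coxPartialLik(fit@coef, cbind(x = d$x), d$time, d$event)
    expect_lt(max(abs(at$score)), 1e-6)

    # analytic score vs central differences at an arbitrary point
    x2 <- cbind(a = d$x, b = rnorm(150))
    beta <- c(0.3, -0.2)
    pl <- coxPartialLik(beta, x2, d$time, d$event)
    h <- 1e-6
    for (j in 1:2) {
        ej <- c(0, 0); ej[j] <- h
        num <- (coxPartialLik(beta + ej, x2, d$time, d$event)$loglik -
                coxPartialLik(beta - ej, x2, d$time, d$event)$loglik) / (2 * h)
        expect_equal(unname(pl$score[j]), num, tolerance = 1e-5)
    }
})

test_that("identical survival in both arms gives a null hazard ratio", {
    t <- c(1, 3, 5, 7, 9, 11, 13, 16); e <- c(1, 1, 0, 1, 1, 0, 1, 1)
    fit <- coxFit(cbind(g = rep(c(0, 1), each = 8)), c(t, t), c(e, e))
    expect_lt(abs(fit@coef[["g"]]), 1e-6)
    tab <- coxTable(fit)
    expect_equal(tab$hr, exp(tab$coef))
    expect_true(tab$lower95 <= tab$hr & tab$hr <= tab$upper95)
})

test_that("Cox recovers a planted log hazard ratio", {
    est <- vapply(1:30, function(i) {
        d <- simSurv(400, beta = 0.7, seed = 300 + i)
        coxFit(cbind(x = d$x), d$time, d$event)@coef[["x"]]
    }, numeric(1))
    expect_lt(abs(mean(est) - 0.7), 0.06)
})

test_that("perfect separation is flagged as non-converged", {
    time <- c(1, 2, 3, 4, 10, 11, 12, 13)
    event <- rep(1, 8)
    x <- cbind(g = c(1, 1, 1, 1, 0, 0, 0, 0))   # all early deaths in group 1
    expect_warning(fit <- coxFit(x, time, event), "monotone|converge")
    expect_false(fit@converged)
    expect_error(coxFit(cbind(g = rep(1, 8)), time, event), "constant")
})

test_that("multivariate entry takes exactly the p < 0.200 univariate hits", {
    set.seed(30)
    n <- 300
    df <- data.frame(
        strong = rbinom(n, 1, 0.5), noise1 = rnorm(n), noise2 = rnorm(n),
        weak = rbinom(n, 1, 0.3))
    haz <- 0.05 * exp(0.9 * df$strong + 0.25 * df$weak)
    ev <- rexp(n, haz); cn <- rexp(n, 0.02)
    df$os_time <- pmin(ev, cn); df$os_event <- as.integer(ev <= cn)
    mv <- multivariateCox(df, c("strong", "noise1", "noise2", "weak"))
    expect_identical(mv$selected,
                     mv$table$variable[mv$table$uni_p < 0.200])
    expect_true("strong" %in% mv$selected)
    expect_true(all(is.na(mv$table$multi_p[!mv$table$variable %in%
                                           mv$selected])))
    expect_false(anyNA(mv$table$multi_p[mv$table$variable %in% mv$selected]))
    # no covariate entering -> univariate results only
    df2 <- df
    expect_message(
        mv2 <- multivariateCox(df2, c("noise1", "noise2"), entry_p = 1e-9),
        "univariate results only")
    expect_null(mv2$fit)
})
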