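#' Kaplan-Meier product-limit estimator
#'
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over event times,
#' where \eqn{d_i} deaths occur among \eqn{n_i} at risk. Censored subjects
#' leave the risk set after their censoring time. With no censoring the
#' estimate reduces to one minus the empirical CDF of the event times.
#'
#' @param times non-negative observed times.
#' @param events event indicators, 1 = event, 0 = censored.
#' @return A \linkS4class{KMFit}.
#' @examples
#' kmFit(c(1, 2, 3), c(1, 1, 1))@surv  # 2/3, 1/3, 0
#' @export
kmFit <- function(times, events) {
    if (!length(times)) stop("empty input")
    if (any(times < 0)) stop("times must be non-negative")
    if (!all(events %in% c(0, 1))) stop("events must be 0/1")
    ut <- sort(unique(times))
    d <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
    cns <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
    nrisk <- vapply(ut, function(t) sum(times >= t), numeric(1))
    surv <- cumprod(1 - d / nrisk)
    new("KMFit", time = ut, n.risk = as.integer(nrisk),
        n.event = as.integer(d), n.censor = as.integer(cns),
        surv = surv, n = length(times))
}

#' @describeIn kmFit survival estimate at arbitrary times (right-continuous
#'   step function; 1 before the first observed time)
#' @param fit a \code{KMFit}
#' @param t times at which to evaluate S(t)
#' @export
kmSurvAt <- function(fit, t) {
    idx <- findInterval(t, fit@time)
    ifelse(idx == 0, 1, fit@surv[pmax(idx, 1)])
}

#' Two-group log-rank test
#'
#' At each event time the observed deaths in group 1 are compared with
#' their hypergeometric expectation given the margins; the statistic
#' \eqn{(\sum (O_{1i} - E_{1i}))^2 / \sum V_i} is referred to chi-square
#' with 1 df. Invariant to swapping the group labels.
#'
#' @param times,events as in \code{kmFit}.
#' @param group two-level grouping vector; both groups must be non-empty.
#' @return List with \code{statistic}, \code{df}, \code{p.value},
#'   \code{observed} and \code{expected} (per group).
#' @export
logrankTest <- function(times, events, group) {
    g <- factor(group)
    if (nlevels(g) != 2 || any(table(g) == 0))
        stop("need two non-empty groups")
    g1 <- g == levels(g)[1]
    ut <- sort(unique(times[events == 1]))
    O1 <- E1 <- V <- 0
    for (t in ut) {
        at <- times >= t
        n <- sum(at); n1 <- sum(at & g1)
        d <- sum(times == t & events == 1)
        d1 <- sum(times == t & events == 1 & g1)
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    stat <- if (V > 0) (O1 - E1)^2 / V else 0
    Ototal <- sum(events == 1)
    list(statistic = stat, df = 1L,
         p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         observed = c(O1, Ototal - O1),
         expected = c(E1, Ototal - E1))
}

#' Cox partial log-likelihood, score and information
#'
#' Evaluates the Efron- (or Breslow-) approximated partial likelihood of a
#' proportional-hazards model at a given coefficient vector, together with
#' its analytic gradient (score) and the observed information matrix.
#' Exposed so the likelihood surface itself can be inspected and verified
#' (e.g. against numerical differentiation).
#'
#' @param beta numeric coefficient vector, length \code{ncol(x)}.
#' @param x covariate matrix (n x p).
#' @param times,events observed times and 0/1 event indicators.
#' @param ties \code{"efron"} or \code{"breslow"}.
#' @return List with \code{loglik}, \code{score} (length p) and
#'   \code{info} (p x p).
#' @export
coxPartialLik <- function(beta, x, times, events, ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    x <- as.matrix(x)
    n <- nrow(x); p <- ncol(x)
    # events sort before censorings within a tied time, so the first index
    # of a tie block starts the full risk set (censored ties stay at risk)
    ord <- order(times, -events)
    x <- x[ord, , drop = FALSE]; times <- times[ord]; events <- events[ord]
    eta <- drop(x %*% beta)
    w <- exp(eta)
    revcum <- function(m) {
        m <- as.matrix(m)
        apply(m, 2, function(v) rev(cumsum(rev(v))))
    }
    pairIdx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    S0 <- rev(cumsum(rev(w)))
    S1 <- revcum(w * x)
    S2 <- revcum(w * x[, pairIdx[, 1], drop = FALSE] *
                     x[, pairIdx[, 2], drop = FALSE])
    toMat <- function(v) {
        m <- matrix(0, p, p)
        m[cbind(pairIdx[, 1], pairIdx[, 2])] <- v
        m[cbind(pairIdx[, 2], pairIdx[, 1])] <- v
        m
    }
    ll <- 0; score <- numeric(p); info <- matrix(0, p, p)
    evt <- which(events == 1)
    for (i0 in split(evt, times[evt])) {
        first <- min(i0)                       # risk set = all with time >= t
        risk0 <- S0[first]
        risk1 <- S1[first, ]; risk2 <- S2[first, ]
        d <- length(i0)
        wD <- w[i0]
        S0D <- sum(wD)
        S1D <- colSums(wD * x[i0, , drop = FALSE])
        S2D <- colSums(wD * x[i0, pairIdx[, 1], drop = FALSE] *
                            x[i0, pairIdx[, 2], drop = FALSE])
        ll <- ll + sum(eta[i0])
        for (l in seq_len(d) - 1L) {
            f <- if (ties == "efron") l / d else 0
            phi0 <- risk0 - f * S0D
            phi1 <- risk1 - f * S1D
            phi2 <- toMat(risk2 - f * S2D)
            ll <- ll - log(phi0)
            score <- score - phi1 / phi0
            info <- info + phi2 / phi0 - tcrossprod(phi1) / phi0^2
        }
        score <- score + colSums(x[i0, , drop = FALSE])
    }
    list(loglik = ll, score = score, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with Efron tie
#' handling (Breslow available), step-halving whenever a step would
#' decrease the likelihood, convergence when the largest score component
#' falls below \code{tol}. Standard errors come from the inverse observed
#' information. A monotone likelihood (perfect separation, coefficients
#' running away) or hitting the iteration cap flags the fit as
#' non-converged with a warning; coefficients are still reported.
#'
#' @param x covariate matrix or data.frame of numeric columns (n x p);
#'   no column may be constant.
#' @param times,events observed times and 0/1 event indicators.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param tol convergence tolerance on \code{max |score|}.
#' @param max_iter Newton iteration cap.
#' @return A \linkS4class{CoxFit}.
#' @export
coxFit <- function(x, times, events, ties = c("efron", "breslow"),
                   tol = 1e-7, max_iter = 50) {
    ties <- match.arg(ties)
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    if (sum(events) < 1) stop("need at least one event")
    if (any(apply(x, 2, function(v) length(unique(v)) == 1L)))
        stop("constant covariate")
    beta <- numeric(ncol(x))
    cur <- coxPartialLik(beta, x, times, events, ties)
    converged <- FALSE; it <- 0L
    while (it < max_iter) {
        it <- it + 1L
        if (max(abs(cur$score)) < tol) { converged <- TRUE; break }
        delta <- solve(cur$info, cur$score)
        step <- 1
        repeat {
            cand <- beta + step * delta
            nxt <- coxPartialLik(cand, x, times, events, ties)
            if (nxt$loglik >= cur$loglik - 1e-12 || step < 1e-6) break
            step <- step / 2
        }
        beta <- cand; cur <- nxt
    }
    if (!converged && max(abs(cur$score)) < tol) converged <- TRUE
    if (any(abs(beta) > 15)) {
        converged <- FALSE
        warning("monotone partial likelihood (perfect separation?); ",
                "coefficients unreliable")
    } else if (!converged) {
        warning("Newton-Raphson did not converge in ", max_iter, " iterations")
    }
    se <- sqrt(diag(solve(cur$info)))
    names(beta) <- names(se) <- colnames(x)
    new("CoxFit", coef = beta, se = se, loglik = cur$loglik, iter = it,
        converged = converged, ties = ties, n = length(times),
        nevent = as.integer(sum(events)))
}

#' Univariate screening with multivariate Cox entry rule
#'
#' Fits one univariate Cox model per covariate; covariates with a
#' univariate Wald p strictly below \code{entry_p} (default 0.200) enter a
#' single joint multivariate fit. With no covariate below the threshold,
#' only the univariate results are returned (with a message).
#'
#' @param data data.frame holding numeric/binary covariate columns.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col names of the time and 0/1 event columns.
#' @param entry_p multivariate entry threshold (strict \code{<}).
#' @param ties tie handling, passed to \code{coxFit}.
#' @return List with \code{table} (per covariate: univariate HR, 95\% CI,
#'   p; multivariate columns where selected), \code{selected} covariate
#'   names, and \code{fit} (the multivariate \code{CoxFit} or NULL).
#' @export
multivariateCox <- function(data, covariates, time_col = "os_time",
                            event_col = "os_event", entry_p = 0.200,
                            ties = "efron") {
    times <- data[[time_col]]; events <- data[[event_col]]
    uni <- lapply(covariates, function(v) {
        fit <- coxFit(data[, v, drop = FALSE], times, events, ties = ties)
        coxTable(fit)[1, ]
    })
    tab <- do.call(rbind, uni)
    rownames(tab) <- covariates
    tab <- data.frame(variable = covariates,
                      uni_hr = tab$hr, uni_lower = tab$lower95,
                      uni_upper = tab$upper95, uni_p = tab$p,
                      multi_hr = NA_real_, multi_lower = NA_real_,
                      multi_upper = NA_real_, multi_p = NA_real_,
                      stringsAsFactors = FALSE)
    selected <- covariates[tab$uni_p < entry_p]
    fit <- NULL
    if (length(selected)) {
        fit <- coxFit(data[, selected, drop = FALSE], times, events,
                      ties = ties)
        mt <- coxTable(fit)
        idx <- match(selected, tab$variable)
        tab$multi_hr[idx] <- mt$hr
        tab$multi_lower[idx] <- mt$lower95
        tab$multi_upper[idx] <- mt$upper95
        tab$multi_p[idx] <- mt$p
    } else {
        message("no covariate below the entry threshold; ",
                "univariate results only")
    }
    list(table = tab, selected = selected, fit = fit)
}
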