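#' Aggregate CpG calls into unit-level methylation
#'
#' For every unit and sample, methylated and total read counts are summed
#' over the CpGs inside the unit whose coverage in that sample is at least
#' \code{min_cov}. A unit is retained only if every sample has at least
#' \code{min_sites} covered CpGs in it, so the resulting matrix is
#' complete — the group comparison then never mixes units observed in
#' different sample subsets.
#'
#' @param calls a \linkS4class{CpGCallSet}.
#' @param units \code{GRanges} of analysis units with \code{unit_id} and
#'   \code{kind} columns.
#' @param min_cov minimum per-sample read coverage for a CpG to count.
#' @param min_sites minimum covered CpGs per sample for unit retention.
#' @return A \linkS4class{UnitMethMatrix}. Zero retained units yields an
#'   empty matrix with a warning.
#' @export
unitMethylation <- function(calls, units, min_cov = 5, min_sites = 1) {
    stopifnot(is(calls, "CpGCallSet"))
    M <- methReads(calls); U <- unmethReads(calls)
    keep <- (M + U) >= min_cov
    ov <- findOverlaps(rowRanges(calls), units, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    sumBy <- function(x) {
        part <- rowsum(x[qh, , drop = FALSE], group = sh)
        full <- matrix(0, length(units), ncol(x))
        full[as.integer(rownames(part)), ] <- part
        full
    }
    msum <- sumBy(M * keep)
    tsum <- sumBy((M + U) * keep)
    nsit <- sumBy(keep + 0L)
    retain <- rowSums(nsit >= min_sites) == ncol(calls)
    if (!any(retain))
        warning("no unit is covered in every sample; empty matrix returned")
    msum <- msum[retain, , drop = FALSE]
    tsum <- tsum[retain, , drop = FALSE]
    nsit <- nsit[retain, , drop = FALSE]
    fr <- ifelse(tsum > 0, msum / tsum, NA_real_)
    dimnames(fr) <- dimnames(msum) <- dimnames(tsum) <- dimnames(nsit) <-
        list(mcols(units)$unit_id[retain], colnames(calls))
    se <- SummarizedExperiment(
        assays = list(fraction = fr, meth = msum, total = tsum,
                      nSites = nsit),
        rowRanges = units[retain], colData = colData(calls))
    new("UnitMethMatrix", se)
}

#' Per-sample global methylation level
#'
#' Read-weighted global methylation: summed methylated reads over summed
#' total reads across all CpGs with coverage >= \code{min_cov}. A sample
#' with no covered CpG gets \code{NA} with a warning.
#'
#' @param calls a \linkS4class{CpGCallSet}.
#' @param min_cov minimum coverage for a CpG to contribute.
#' @return Named numeric vector of fractions in [0,1], one per sample.
#' @export
globalMethylation <- function(calls, min_cov = 5) {
    M <- methReads(calls); U <- unmethReads(calls)
    keep <- (M + U) >= min_cov
    tot <- colSums((M + U) * keep)
    res <- ifelse(tot > 0, colSums(M * keep) / tot, NA_real_)
    names(res) <- colnames(calls)
    if (anyNA(res))
        warning("sample(s) without covered CpGs: ",
                paste(names(res)[is.na(res)], collapse = ", "))
    res
}

#' Pooled-variance two-sample t test for global methylation
#'
#' Compares per-sample global methylation levels between groups with the
#' classical independent t test (pooled variance, df = n1 + n2 - 2),
#' two-sided. Degenerate zero-variance input is handled explicitly: p = 1
#' when the means are also equal, p = 0 otherwise (with a warning).
#'
#' @param case_values,ctrl_values numeric vectors, >= 2 values each.
#' @return List with \code{statistic}, \code{df} and \code{p.value}.
#' @examples
#' compareGlobal(c(51.2, 38.9, 43.3, 42.3, 44.8),
#'               c(51.0, 49.3, 49.4, 45.4))$p.value  # 0.106
#' @export
compareGlobal <- function(case_values, ctrl_values) {
    n1 <- length(case_values); n2 <- length(ctrl_values)
    if (n1 < 2 || n2 < 2) stop("need >= 2 values per group")
    m1 <- mean(case_values); m2 <- mean(ctrl_values)
    sp2 <- ((n1 - 1) * stats::var(case_values) +
            (n2 - 1) * stats::var(ctrl_values)) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
        warning("zero pooled variance; degenerate p-value returned")
        return(list(statistic = if (m1 == m2) 0 else Inf, df = df,
                    p.value = if (m1 == m2) 1 else 0))
    }
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(statistic = tstat, df = df, p.value = 2 * pt(-abs(tstat), df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_i = \min_{j \ge i} p_{(j)} m / j} mapped
#' back to input order, so \eqn{q \in [p, 1]}.
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @return Adjusted q-values in input order.
#' @export
bhAdjust <- function(p_values) {
    if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
        stop("p-values must lie in [0,1]")
    p.adjust(p_values, method = "BH")
}

#' Call differentially methylated fragments (units)
#'
#' Per unit, group means are the unweighted means of per-sample methylation
#' fractions (a mean over patients, not a read-pooled ratio) and
#' \code{diff = mean_case - mean_ctrl}. A unit is \emph{hyper}methylated
#' when \code{p < p_thr}, \code{q < q_thr} and \code{diff > diff_thr};
#' \emph{hypo}methylated with \code{diff < -diff_thr}; otherwise \emph{ns}.
#' Defaults encode the triple threshold P < 0.05, Q < 0.05 and > 25
#' percentage points mean difference.
#'
#' Two per-unit tests are available:
#' \describe{
#'   \item{\code{"ttest"} (default)}{pooled-variance two-sample t test on
#'     the per-sample unit fractions. Because each sample contributes one
#'     fraction, between-sample (beta-binomial) overdispersion is absorbed
#'     into the empirical variance and the test stays calibrated.}
#'   \item{\code{"fisher"}}{two-sided Fisher exact test on read counts
#'     pooled within each group — the classical no-replicate choice. With
#'     replicated, overdispersed samples it is anti-conservative (pooling
#'     discards between-sample variance), so it is not the default; see the
#'     package vignette.}
#' }
#'
#' @param x a \linkS4class{UnitMethMatrix}.
#' @param group factor/character of \code{"case"}/\code{"ctrl"} per sample;
#'   defaults to \code{colData(x)$group}.
#' @param p_thr,q_thr,diff_thr the triple threshold (strict inequalities).
#' @param test per-unit test, \code{"ttest"} or \code{"fisher"}.
#' @return A \linkS4class{DMResults} with one row per tested unit.
#' @export
callDmf <- function(x, group = NULL, p_thr = 0.05, q_thr = 0.05,
                    diff_thr = 0.25, test = c("ttest", "fisher")) {
    test <- match.arg(test)
    stopifnot(is(x, "UnitMethMatrix"))
    if (is.null(group)) group <- colData(x)$group
    if (is.null(group)) stop("no 'group' given and none in colData")
    group <- as.character(group)
    if (!all(group %in% c("case", "ctrl")))
        stop("group labels must be 'case' or 'ctrl'")
    ca <- group == "case"; co <- group == "ctrl"
    if (!any(ca) || !any(co)) stop("need >= 1 sample per group")
    if (nrow(x) == 0L) stop("empty methylation matrix")
    fr <- methFraction(x)
    meanCase <- rowMeans(fr[, ca, drop = FALSE])
    meanCtrl <- rowMeans(fr[, co, drop = FALSE])
    diff <- meanCase - meanCtrl
    if (test == "ttest") {
        p <- .rowPooledT(fr[, ca, drop = FALSE], fr[, co, drop = FALSE])
    } else {
        M <- methCounts(x); Tt <- totalCounts(x)
        m1 <- rowSums(M[, ca, drop = FALSE]); t1 <- rowSums(Tt[, ca, drop = FALSE])
        m2 <- rowSums(M[, co, drop = FALSE]); t2 <- rowSums(Tt[, co, drop = FALSE])
        p <- vapply(seq_len(nrow(x)), function(i) {
            if (t1[i] + t2[i] == 0) return(1)
            fisher.test(matrix(c(m1[i], t1[i] - m1[i],
                                 m2[i], t2[i] - m2[i]), nrow = 2))$p.value
        }, numeric(1))
    }
    q <- bhAdjust(p)
    status <- rep("ns", nrow(x))
    sig <- p < p_thr & q < q_thr
    status[sig & diff > diff_thr] <- "hyper"
    status[sig & diff < -diff_thr] <- "hypo"
    rd <- mcols(rowRanges(x))
    res <- DataFrame(
        unit_id = rd$unit_id, kind = rd$kind,
        gene_id = if (!is.null(rd$gene_id)) rd$gene_id
                  else rep(NA_character_, nrow(x)),
        mean_case = unname(meanCase), mean_ctrl = unname(meanCtrl),
        diff = unname(diff), p = unname(p), q = unname(q), status = status)
    metadata(res) <- list(p_thr = p_thr, q_thr = q_thr, diff_thr = diff_thr,
                          test = test)
    new("DMResults", res)
}

# Row-wise pooled-variance two-sample t on fraction matrices; degenerate
# zero-variance rows get p = 1 (equal means) or p = 0.
.rowPooledT <- function(a, b) {
    n1 <- ncol(a); n2 <- ncol(b)
    if (n1 < 2 || n2 < 2)
        stop("the t test needs >= 2 samples per group; use test = 'fisher'")
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- rowSums((a - m1)^2) / (n1 - 1)
    v2 <- rowSums((b - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs((m1 - m2) / se), df = n1 + n2 - 2)
    degen <- sp2 == 0
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    p
}
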