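#' Mean + 2SD methylation cutoff from controls
#'
#' The dichotomization rule for a continuous methylation biomarker: the
#' cutoff is the control mean plus two sample standard deviations (n-1
#' denominator). Values strictly greater than the cutoff are called
#' hypermethylated — a patient must exceed the control envelope, so a
#' value exactly at the cutoff is non-hypermethylated. Under normally
#' distributed controls about 2.3\% of control-like values exceed the
#' cutoff.
#'
#' @param control_values numeric vector of control measurements (>= 2).
#' @param n_sd number of standard deviations above the mean (default 2).
#' @return The cutoff value.
#' @examples
#' methylationCutoff(c(0, 2))  # 1 + 2*sqrt(2)
#' @export
methylationCutoff <- function(control_values, n_sd = 2) {
    if (length(control_values) < 2)
        stop("need >= 2 control values")
    mean(control_values) + n_sd * sd(control_values)
}

#' @rdname methylationCutoff
#' @param values patient measurements to dichotomize.
#' @param cutoff cutoff from \code{methylationCutoff}.
#' @return \code{dichotomize}: factor with levels \code{non}/\code{hyper}.
#' @export
dichotomize <- function(values, cutoff) {
    factor(ifelse(values > cutoff, "hyper", "non"), levels = c("non", "hyper"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Minimum-likelihood two-sided rule: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (within relative tolerance 1e-7).
#' A table with an all-zero row or column carries no information and
#' returns p = 1 with a warning.
#'
#' @param a,b,c,d cell counts, row-wise: \code{a b} / \code{c d}.
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(1, 61, 5, 27)   # 0.016
#' fisherExact2x2(0, 62, 1, 31)   # 32/94
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
    if (a + b + c + d == 0) stop("empty table")
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
        warning("degenerate margin; p = 1")
        return(1)
    }
    fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Pearson chi-square test without continuity correction
#'
#' @param table an r x c matrix/table of non-negative counts (r, c >= 2).
#' @return List with \code{statistic}, \code{df}, \code{p.value}.
#' @export
pearsonChi2 <- function(table) {
    table <- as.matrix(table)
    if (nrow(table) < 2 || ncol(table) < 2) stop("need an r x c table, r,c >= 2")
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    if (any(expected == 0))
        stop("zero expected cell; use the Fisher exact branch")
    res <- suppressWarnings(chisq.test(table, correct = FALSE))
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p.value = res$p.value)
}

#' Mann-Whitney U test
#'
#' Exact permutation p-value when the combined sample size is at most 12
#' and there are no ties; otherwise the tie-corrected normal approximation
#' (no continuity correction).
#'
#' @param x,y numeric vectors, >= 1 value each.
#' @return List with \code{statistic} (U for \code{x}), \code{p.value} and
#'   \code{method} ("exact" or "normal").
#' @export
mannWhitney <- function(x, y) {
    if (!length(x) || !length(y)) stop("need >= 1 value per group")
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y) <= 12) && !ties
    res <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = FALSE))
    list(statistic = unname(res$statistic), p.value = res$p.value,
         method = if (exact) "exact" else "normal")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; p-value from the t approximation with
#' n - 2 degrees of freedom. A constant input vector has no defined rank
#' correlation and returns \code{NA} with a warning.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return List with \code{rho} and \code{p.value}.
#' @export
spearmanCor <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must be paired")
    if (length(x) < 3) stop("need n >= 3")
    if (sd(x) == 0 || sd(y) == 0) {
        warning("constant vector; rho undefined")
        return(list(rho = NA_real_, p.value = NA_real_))
    }
    res <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(res$estimate), p.value = res$p.value)
}

#' Group comparison with test dispatch
#'
#' Reproduces a clinical-table comparison for one variable between two
#' patient groups, choosing the test the way such tables are assembled:
#' continuous variables use the Mann-Whitney U test (or the pooled t test
#' on request); categorical 2x2 tables use Fisher's exact test when any
#' expected cell is below 5 and the Pearson chi-square otherwise; larger
#' r x c tables use the Pearson chi-square. Missing values (\code{NA}) are
#' dropped pairwise, so denominators may differ between variables.
#'
#' @param data data.frame of patient records.
#' @param variable column to compare.
#' @param group column (or factor) defining the two groups.
#' @param kind \code{"continuous"} or \code{"categorical"}.
#' @param continuous_test \code{"mannwhitney"} (default) or \code{"ttest"}.
#' @return List with \code{variable}, \code{test}, \code{p.value} and the
#'   group summaries (medians or the contingency table).
#' @export
compareGroups <- function(data, variable, group, kind = c("continuous",
                          "categorical"),
                          continuous_test = c("mannwhitney", "ttest")) {
    kind <- match.arg(kind)
    continuous_test <- match.arg(continuous_test)
    if (!variable %in% names(data)) stop("unknown variable: ", variable)
    g <- if (length(group) == 1L && is.character(group)) data[[group]] else group
    v <- data[[variable]]
    ok <- !is.na(v) & !is.na(g)
    v <- v[ok]; g <- factor(g[ok])
    if (!length(v)) stop("variable '", variable, "' has no non-missing values")
    if (nlevels(g) != 2) stop("group must have exactly two levels")
    if (kind == "continuous") {
        x <- v[g == levels(g)[1]]; y <- v[g == levels(g)[2]]
        if (continuous_test == "mannwhitney") {
            r <- mannWhitney(x, y)
            list(variable = variable, test = paste0("mann-whitney (", r$method, ")"),
                 p.value = r$p.value,
                 summary = c(median_1 = stats::median(x), median_2 = stats::median(y)))
        } else {
            r <- compareGlobal(x, y)
            list(variable = variable, test = "t-test (pooled)",
                 p.value = r$p.value,
                 summary = c(mean_1 = mean(x), mean_2 = mean(y)))
        }
    } else {
        tab <- table(v, g)
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (nrow(tab) == 2 && ncol(tab) == 2 && any(expected < 5)) {
            p <- fisherExact2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
            list(variable = variable, test = "fisher", p.value = p,
                 summary = tab)
        } else {
            r <- pearsonChi2(tab)
            list(variable = variable, test = "chi-square", p.value = r$p.value,
                 summary = tab)
        }
    }
}

#' Clinical comparison table
#'
#' Runs \code{compareGroups} over a set of variables, producing the rows
#' of a two-group clinical characteristics table.
#'
#' @param data data.frame of patient records.
#' @param group grouping column name.
#' @param continuous,categorical character vectors of column names.
#' @return data.frame with variable, test used and p-value.
#' @export
clinicalComparison <- function(data, group, continuous = character(),
                               categorical = character()) {
    rows <- c(
        lapply(continuous, function(v)
            compareGroups(data, v, group, "continuous")),
        lapply(categorical, function(v)
            compareGroups(data, v, group, "categorical")))
    data.frame(
        variable = vapply(rows, `[[`, character(1), "variable"),
        test = vapply(rows, `[[`, character(1), "test"),
        p = vapply(rows, `[[`, numeric(1), "p.value"),
        stringsAsFactors = FALSE)
}
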