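#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom BiocGenerics start end width strand strand<-
#' @importFrom GenomicRanges GRanges granges findOverlaps seqnames
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlevels<- seqlengths<-
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
#' @importFrom stats rbeta rbinom rpois rexp runif rlnorm rnorm pchisq pnorm pt p.adjust fisher.test chisq.test wilcox.test cor.test sd quantile
#' @importFrom utils read.table write.table
NULL

#' Per-sample CpG methylation calls on a genome
#'
#' A \linkS4class{RangedSummarizedExperiment} holding methylated and
#' unmethylated read counts per CpG (rows, width-1 ranges at the cytosine)
#' per sample (columns). Strand-merged counts are assumed: each row is the
#' forward-strand C of a CpG dinucleotide with reads from both strands
#' already combined.
#'
#' Assays: \code{M} (methylated reads), \code{U} (unmethylated reads).
#' \code{colData} carries at least \code{group} (\code{"case"}/\code{"ctrl"})
#' when a two-group design is present.
#'
#' @export
setClass("CpGCallSet", contains = "RangedSummarizedExperiment")

setValidity("CpGCallSet", function(object) {
    msg <- NULL
    if (!all(c("M", "U") %in% names(assays(object))))
        msg <- c(msg, "assays 'M' and 'U' are required")
    else {
        M <- assay(object, "M"); U <- assay(object, "U")
        if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
            msg <- c(msg, "read counts must be non-negative")
    }
    if (length(object) && any(width(rowRanges(object)) != 1L))
        msg <- c(msg, "CpG positions must have width 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CpGCallSet
#'
#' @param M,U integer matrices (CpG x sample) of methylated / unmethylated
#'   read counts, with identical dimensions.
#' @param positions \code{GRanges} of width 1 locating each CpG's cytosine
#'   (one per row of \code{M}).
#' @param sampleData \code{DataFrame}/\code{data.frame} of per-sample
#'   annotation; a \code{group} column with levels \code{case}/\code{ctrl}
#'   enables differential analysis.
#' @return A \linkS4class{CpGCallSet}.
#' @examples
#' pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1))
#' cs <- CpGCallSet(M = cbind(s1 = c(5L, 2L)), U = cbind(s1 = c(5L, 8L)),
#'                  positions = pos)
#' cpgCoverage(cs)
#' @export
CpGCallSet <- function(M, U, positions, sampleData = NULL) {
    M <- as.matrix(M); U <- as.matrix(U)
    stopifnot(identical(dim(M), dim(U)))
    if (is.null(sampleData)) {
        cn <- colnames(M)
        if (is.null(cn)) cn <- paste0("sample_", seq_len(ncol(M)))
        sampleData <- DataFrame(sample = cn, row.names = cn)
    }
    se <- SummarizedExperiment(
        assays = list(M = M, U = U),
        rowRanges = positions,
        colData = as(sampleData, "DataFrame"))
    new("CpGCallSet", se)
}

#' @describeIn CpGCallSet methylated read counts (CpG x sample matrix)
#' @param x a \code{CpGCallSet}
#' @export
methReads <- function(x) assay(x, "M")

#' @describeIn CpGCallSet unmethylated read counts
#' @export
unmethReads <- function(x) assay(x, "U")

#' @describeIn CpGCallSet total read coverage per CpG per sample
#' @export
cpgCoverage <- function(x) assay(x, "M") + assay(x, "U")

#' Unit-by-sample methylation matrix
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are analysis units
#' (MspI fragments, promoters, gene bodies or CpG islands) and whose columns
#' are samples. Assays:
#' \describe{
#'   \item{fraction}{unit methylation fraction, \code{meth/total}; \code{NA}
#'     where a cell has no covered CpG (missing, never zero)}
#'   \item{meth, total}{summed methylated and total read counts over the
#'     unit's covered CpGs}
#'   \item{nSites}{number of CpGs passing the coverage filter in the cell}
#' }
#' Row ranges carry \code{unit_id}, \code{kind} and (for promoters / gene
#' bodies) \code{gene_id} metadata columns.
#'
#' @export
setClass("UnitMethMatrix", contains = "RangedSummarizedExperiment")

setValidity("UnitMethMatrix", function(object) {
    need <- c("fraction", "meth", "total", "nSites")
    if (!all(need %in% names(assays(object))))
        return(sprintf("assays %s are required", paste(need, collapse = ", ")))
    tot <- assay(object, "total"); fr <- assay(object, "fraction")
    ok <- tot > 0
    if (any(abs(fr[ok] - assay(object, "meth")[ok] / tot[ok]) > 1e-8))
        return("fraction must equal meth/total where total > 0")
    if (any(!is.na(fr[!ok])))
        return("cells with zero total coverage must be NA")
    if (!all(c("unit_id", "kind") %in% names(mcols(rowRanges(object)))))
        return("row ranges need unit_id and kind columns")
    TRUE
})

#' @describeIn UnitMethMatrix unit methylation fractions (NA = uncovered)
#' @param x a \code{UnitMethMatrix}
#' @export
methFraction <- function(x) assay(x, "fraction")

#' @describeIn UnitMethMatrix summed methylated counts per unit per sample
#' @export
methCounts <- function(x) assay(x, "meth")

#' @describeIn UnitMethMatrix summed total counts per unit per sample
#' @export
totalCounts <- function(x) assay(x, "total")

#' @describeIn UnitMethMatrix covered-CpG count per unit per sample
#' @export
coveredSites <- function(x) assay(x, "nSites")

#' @describeIn UnitMethMatrix the unit intervals (\code{GRanges} with
#'   \code{unit_id}, \code{kind}, \code{gene_id}) of the retained rows
#' @export
unitRanges <- function(x) rowRanges(x)

#' Differential methylation results
#'
#' A \code{DataFrame} subclass with one row per tested unit: group means,
#' difference, P, Q (Benjamini-Hochberg) and hyper/hypo/ns status. Threshold
#' settings are stored in \code{metadata()}.
#'
#' @export
setClass("DMResults", contains = "DFrame")

setMethod("show", "DMResults", function(object) {
    st <- table(factor(object$status, levels = c("hyper", "hypo", "ns")))
    cat(sprintf(
        "DMResults with %d tested units: %d hyper, %d hypo, %d ns\n",
        nrow(object), st[["hyper"]], st[["hypo"]], st[["ns"]]))
    thr <- metadata(object)
    if (length(thr))
        cat(sprintf("thresholds: p < %g, q < %g, |diff| > %g (test: %s)\n",
                    thr$p_thr, thr$q_thr, thr$diff_thr, thr$test))
    callNextMethod()
})

#' Kaplan-Meier fit
#'
#' Product-limit estimate of the survivor function. Slots record, per
#' distinct observed time: the number at risk, events, censorings and the
#' survival estimate after that time.
#'
#' @slot time distinct observed times, increasing
#' @slot n.risk subjects at risk just before each time
#' @slot n.event deaths at each time
#' @slot n.censor censorings at each time
#' @slot surv product-limit estimate S(t), non-increasing from 1
#' @slot n total number of subjects
#' @export
setClass("KMFit", representation(
    time = "numeric", n.risk = "integer", n.event = "integer",
    n.censor = "integer", surv = "numeric", n = "integer"))

setValidity("KMFit", function(object) {
    if (is.unsorted(object@time, strictly = TRUE))
        return("times must be strictly increasing")
    if (any(diff(object@surv) > 1e-12) || any(object@surv > 1 + 1e-12))
        return("survival estimate must be non-increasing and start <= 1")
    if (any(diff(object@n.risk) > 0L))
        return("at-risk counts must be non-increasing")
    TRUE
})

setMethod("show", "KMFit", function(object) {
    cat(sprintf("Kaplan-Meier fit: n = %d, events = %d\n",
                object@n, sum(object@n.event)))
    print(utils::head(data.frame(time = object@time, n.risk = object@n.risk,
                                 n.event = object@n.event, surv = object@surv), 10))
    if (length(object@time) > 10) cat("...\n")
})

#' Cox proportional-hazards fit
#'
#' Result of maximizing the Efron (or Breslow) partial likelihood by
#' Newton-Raphson. Hazard ratios are \code{exp(coef)} with Wald 95\%
#' confidence intervals \code{exp(coef +/- 1.96 se)}.
#'
#' @slot coef named log-hazard coefficients
#' @slot se standard errors from the inverse observed information
#' @slot loglik maximized log partial likelihood
#' @slot iter Newton iterations used
#' @slot converged FALSE flags non-convergence or monotone likelihood
#' @slot ties tie-handling method used
#' @slot n,nevent subjects and events
#' @export
setClass("CoxFit", representation(
    coef = "numeric", se = "numeric", loglik = "numeric", iter = "integer",
    converged = "logical", ties = "character", n = "integer", nevent = "integer"))

setMethod("show", "CoxFit", function(object) {
    cat(sprintf("Cox fit (%s ties): n = %d, events = %d, loglik = %.4f%s\n",
                object@ties, object@n, object@nevent, object@loglik,
                if (object@converged) "" else "  [NOT CONVERGED]"))
    print(coxTable(object))
})

#' @describeIn CoxFit coefficient table with HR, 95\% CI and Wald p
#' @param fit a \code{CoxFit}
#' @export
coxTable <- function(fit) {
    z <- fit@coef / fit@se
    data.frame(
        coef = fit@coef, se = fit@se, hr = exp(fit@coef),
        lower95 = exp(fit@coef - 1.96 * fit@se),
        upper95 = exp(fit@coef + 1.96 * fit@se),
        p = 2 * stats::pnorm(-abs(z)),
        row.names = names(fit@coef))
}

#' Simulation design for a two-group RRBS methylome
#'
#' Defaults emulate a small discovery cohort: 5 cases vs 4 controls, mean
#' methylation 0.45 (the mid-40s\% global methylation typical of bone-marrow
#' RRBS), beta-binomial dispersion 0.1 and mean coverage 30 reads per CpG.
#'
#' @slot nCase,nCtrl samples per group (>= 1)
#' @slot baselineMu baseline mean methylation in [0,1]
#' @slot dispersionPhi beta-binomial dispersion; Var = mu(1-mu)phi
#' @slot plantedEffects data.frame(unit_id, delta) of unit-level shifts
#'   applied to case samples; mu + delta is clamped to [0,1]
#' @slot depthMean mean Poisson read depth per CpG per sample
#' @slot seed RNG seed; identical seeds give bit-identical output
#' @export
setClass("SimDesign", representation(
    nCase = "integer", nCtrl = "integer", baselineMu = "numeric",
    dispersionPhi = "numeric", plantedEffects = "data.frame",
    depthMean = "numeric", seed = "integer"))

setValidity("SimDesign", function(object) {
    msg <- NULL
    if (object@nCase < 1L || object@nCtrl < 1L)
        msg <- c(msg, "need at least one sample per group")
    if (object@baselineMu < 0 || object@baselineMu > 1)
        msg <- c(msg, "baselineMu must lie in [0,1]")
    if (object@dispersionPhi <= 0 || object@dispersionPhi >= 1)
        msg <- c(msg, "dispersionPhi must lie in (0,1)")
    if (object@depthMean < 0)
        msg <- c(msg, "depthMean must be non-negative")
    if (nrow(object@plantedEffects) &&
        !all(c("unit_id", "delta") %in% names(object@plantedEffects)))
        msg <- c(msg, "plantedEffects needs unit_id and delta columns")
    if (is.null(msg)) TRUE else msg
})

#' @rdname SimDesign-class
#' @param nCase,nCtrl,baselineMu,dispersionPhi,plantedEffects,depthMean,seed
#'   see slot documentation
#' @export
simDesign <- function(nCase = 5, nCtrl = 4, baselineMu = 0.45,
                      dispersionPhi = 0.1,
                      plantedEffects = data.frame(unit_id = character(),
                                                  delta = numeric()),
                      depthMean = 30, seed = 1) {
    new("SimDesign", nCase = as.integer(nCase), nCtrl = as.integer(nCtrl),
        baselineMu = baselineMu, dispersionPhi = dispersionPhi,
        plantedEffects = plantedEffects, depthMean = depthMean,
        seed = as.integer(seed))
}

#' Simulation design for a survival cohort
#'
#' Exponential event times with hazard \code{baselineHazard *
#' exp(betaMeth * hyper)} and independent exponential censoring; binary
#' mutation covariates drawn at \code{covariateFreqs}. Defaults sketch a
#' Table 1-scale MDS cohort (hypermethylation frequency ~0.35, mutation
#' frequencies of a few percent).
#'
#' @slot n cohort size (>= 2)
#' @slot betaMeth log hazard ratio of the hypermethylated group
#' @slot baselineHazard events per month in the reference group
#' @slot censorRate rate of the independent exponential censoring time
#' @slot methFreq probability a patient is hypermethylated
#' @slot covariateFreqs named mutant frequencies for binary mutation flags
#' @slot seed RNG seed
#' @export
setClass("SurvivalSimDesign", representation(
    n = "integer", betaMeth = "numeric", baselineHazard = "numeric",
    censorRate = "numeric", methFreq = "numeric",
    covariateFreqs = "numeric", seed = "integer"))

setValidity("SurvivalSimDesign", function(object) {
    msg <- NULL
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
    if (object@censorRate < 0) msg <- c(msg, "censorRate must be >= 0")
    if (object@methFreq <= 0 || object@methFreq >= 1)
        msg <- c(msg, "methFreq must lie in (0,1)")
    if (is.null(msg)) TRUE else msg
})

#' @rdname SurvivalSimDesign-class
#' @param n,betaMeth,baselineHazard,censorRate,methFreq,covariateFreqs,seed
#'   see slot documentation
#' @export
survivalSimDesign <- function(n = 105, betaMeth = 0, baselineHazard = 0.03,
                              censorRate = 0.015, methFreq = 0.35,
                              covariateFreqs = c(CEBPA = 0.03, IDH1_2 = 0.04,
                                                 DNMT3A = 0.03, U2AF1 = 0.06,
                                                 SRSF2 = 0.03, SF3B1 = 0.06,
                                                 SETBP1 = 0.01),
                              seed = 1) {
    new("SurvivalSimDesign", n = as.integer(n), betaMeth = betaMeth,
        baselineHazard = baselineHazard, censorRate = censorRate,
        methFreq = methFreq, covariateFreqs = covariateFreqs,
        seed = as.integer(seed))
}
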