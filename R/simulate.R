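#' Simulate a toy genome with genes and CpG islands
#'
#' Generates random contigs emulating the CpG-enriched, MspI-accessible
#' fraction of a genome that reduced-representation libraries capture:
#' a CpG-depleted background with CpG dinucleotides at \code{cpg_rate} per
#' bp, CCGG motifs planted at \code{ccgg_rate} per bp (all background CCGG
#' occurrences are scrubbed first, so \code{ccgg_rate = 0} yields a genome
#' with no MspI site at all), GC- and CpG-rich islands that satisfy the
#' \code{detectCgi} criteria, and random gene models with TSS/TES inside
#' the contigs.
#'
#' @param n_contigs number of contigs.
#' @param contig_len contig length in bp (>= 1000).
#' @param cpg_rate target CpG dinucleotide rate per bp outside islands.
#' @param ccgg_rate target CCGG motif rate per bp.
#' @param n_genes genes per contig.
#' @param n_cgi planted CpG islands per contig.
#' @param cgi_len planted island length in bp.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return List with \code{genome} (\code{DNAStringSet}), \code{genes}
#'   (gene-model \code{GRanges}), and \code{cgi} (planted islands,
#'   \code{GRanges} with \code{unit_id}/\code{kind}).
#' @export
simulateGenome <- function(n_contigs = 1, contig_len = 50000,
                           cpg_rate = 0.025, ccgg_rate = 0.01,
                           n_genes = 10, n_cgi = 2, cgi_len = 600,
                           seed = 1) {
    if (n_contigs < 1 || contig_len < 1000 || n_genes < 0 || n_cgi < 0)
        stop("counts must be positive and contig_len >= 1000")
    if (cpg_rate < 0 || cpg_rate >= 1 || ccgg_rate < 0 || ccgg_rate >= 1)
        stop("rates must lie in [0,1)")
    set.seed(seed)
    contigs <- character(n_contigs)
    cgi_all <- list(); gene_rows <- list()
    for (ci in seq_len(n_contigs)) {
        cname <- paste0("contig_", ci)
        v <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
        # plant islands: iid C/G at 0.3 gives GC ~0.6 and CpG O/E ~1
        island_at <- integer(0)
        if (n_cgi > 0 && contig_len > (cgi_len + 200) * n_cgi + 400) {
            slots <- floor(seq(400, contig_len - cgi_len - 400,
                               length.out = n_cgi + 1))
            island_at <- vapply(seq_len(n_cgi), function(k)
                slots[k] + sample.int(max(slots[k + 1] - slots[k] - cgi_len, 1), 1),
                numeric(1))
            for (p in island_at)
                v[p:(p + cgi_len - 1)] <- sample(
                    c("A", "C", "G", "T"), cgi_len, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2))
        }
        in_island <- rep(FALSE, contig_len)
        for (p in island_at) in_island[p:(p + cgi_len - 1)] <- TRUE
        # thin background CpGs down to cpg_rate (iid background has ~0.04/bp)
        cg <- which(v[-contig_len] == "C" & v[-1] == "G")
        cg <- cg[!in_island[cg]]
        p_bg <- 0.04
        if (cpg_rate < p_bg && length(cg)) {
            drop <- cg[runif(length(cg)) > cpg_rate / p_bg]
            v[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
        }
        # scrub all CCGG, then plant them at the requested rate
        s <- paste(v, collapse = "")
        hit <- findCcggSites(s)
        if (length(hit)) v[hit + 3L] <- "T"
        n_plant <- rbinom(1, contig_len - 3L, ccgg_rate)
        if (n_plant > 0) {
            pos <- sort(sample.int(contig_len - 3L, min(n_plant, contig_len %/% 8)))
            pos <- pos[c(TRUE, diff(pos) >= 4L)]
            for (off in 0:3) v[pos + off] <- c("C", "C", "G", "G")[off + 1]
        }
        contigs[ci] <- paste(v, collapse = "")
        if (length(island_at))
            cgi_all[[cname]] <- data.frame(contig = cname,
                                           start = island_at)
        if (n_genes > 0) {
            glen <- pmin(round(runif(n_genes, 2000, 8000)), contig_len - 200)
            gstart0 <- vapply(glen, function(l)
                sample.int(contig_len - l - 100, 1), numeric(1))
            gstrand <- sample(c("+", "-"), n_genes, replace = TRUE)
            gene_rows[[cname]] <- data.frame(
                contig = cname, strand = gstrand,
                tss = ifelse(gstrand == "+", gstart0, gstart0 + glen),
                tes = ifelse(gstrand == "+", gstart0 + glen, gstart0))
        }
    }
    genome <- Biostrings::DNAStringSet(contigs)
    names(genome) <- paste0("contig_", seq_len(n_contigs))
    lens <- stats::setNames(width(genome), names(genome))
    genes <- if (length(gene_rows)) {
        gdf <- do.call(rbind, gene_rows)
        geneModels(sprintf("gene_%04d", seq_len(nrow(gdf))), gdf$contig,
                   gdf$strand, gdf$tss, gdf$tes, contig_lengths = lens)
    } else geneModels(character(), character(), character(), integer(),
                      integer(), contig_lengths = lens)
    cgi <- if (length(cgi_all)) {
        cdf <- do.call(rbind, unname(cgi_all))
        GRanges(cdf$contig, IRanges(cdf$start, width = cgi_len))
    } else GRanges()
    seqlevels(cgi) <- names(genome)
    seqlengths(cgi) <- lens
    mcols(cgi)$unit_id <- sprintf("cgi_planted_%03d", seq_along(cgi))
    mcols(cgi)$kind <- rep("cgi", length(cgi))
    list(genome = genome, genes = genes, cgi = cgi)
}

#' Simulate beta-binomial RRBS methylation calls
#'
#' Every CpG (forward-strand C of a CG dinucleotide) in the genome gets,
#' per sample, a Poisson read depth and a methylated count drawn from a
#' beta-binomial: the per-CpG-per-sample methylation probability is
#' Beta-distributed with mean \eqn{\mu} and variance
#' \eqn{\mu(1-\mu)\phi}. CpGs inside planted-effect units have their mean
#' shifted by \code{delta} in case samples only, clamped to [0,1] (with a
#' warning when clamping occurs) — effects act at the unit level, matching
#' the fragment-level analysis granularity.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param units \code{GRanges} with \code{unit_id}; only needed when the
#'   design plants effects.
#' @param design a \linkS4class{SimDesign}.
#' @return A \linkS4class{CpGCallSet} with \code{colData} columns
#'   \code{sample} and \code{group}, and the planted-effect table in
#'   \code{metadata()$planted}.
#' @export
simulateMethylome <- function(genome, units = NULL, design = simDesign()) {
    stopifnot(is(design, "SimDesign"))
    eff <- design@plantedEffects
    if (nrow(eff)) {
        if (is.null(units)) stop("planted effects require 'units'")
        missing <- setdiff(eff$unit_id, mcols(units)$unit_id)
        if (length(missing))
            stop("planted unit id(s) not in units: ",
                 paste(utils::head(missing, 5), collapse = ", "))
    }
    set.seed(design@seed)
    hits <- Biostrings::vmatchPattern("CG", genome)
    pos <- do.call(c, lapply(seq_along(genome), function(i)
        GRanges(names(genome)[i], IRanges(start(hits[[i]]), width = 1L))))
    seqlevels(pos) <- names(genome)
    seqlengths(pos) <- width(genome)
    ncpg <- length(pos)
    n1 <- design@nCase; n2 <- design@nCtrl
    samples <- c(paste0("case_", seq_len(n1)), paste0("ctrl_", seq_len(n2)))
    group <- rep(c("case", "ctrl"), c(n1, n2))
    mu0 <- rep(design@baselineMu, ncpg)
    muCase <- mu0
    if (nrow(eff)) {
        sel <- units[match(eff$unit_id, mcols(units)$unit_id)]
        ov <- findOverlaps(pos, sel, ignore.strand = TRUE)
        shift <- eff$delta[S4Vectors::subjectHits(ov)]
        idx <- S4Vectors::queryHits(ov)
        muCase[idx] <- mu0[idx] + shift
        if (any(muCase < 0 | muCase > 1)) {
            warning("planted delta pushed mu outside [0,1]; clamped")
            muCase <- pmin(pmax(muCase, 0), 1)
        }
    }
    phi <- design@dispersionPhi
    nu <- 1 / phi - 1                     # Beta(mu*nu, (1-mu)*nu)
    M <- U <- matrix(0L, ncpg, n1 + n2, dimnames = list(NULL, samples))
    for (j in seq_len(n1 + n2)) {
        mu <- if (group[j] == "case") muCase else mu0
        depth <- rpois(ncpg, design@depthMean)
        pj <- numeric(ncpg)
        inner <- mu > 0 & mu < 1
        pj[inner] <- rbeta(sum(inner), mu[inner] * nu, (1 - mu[inner]) * nu)
        pj[mu >= 1] <- 1
        mj <- rbinom(ncpg, depth, pj)
        M[, j] <- mj
        U[, j] <- depth - mj
    }
    cs <- CpGCallSet(M, U, pos,
                     DataFrame(sample = samples, group = group,
                               row.names = samples))
    metadata(cs)$planted <- eff
    cs
}

#' Simulate a clinical/survival cohort
#'
#' Event times are exponential with hazard
#' \code{baselineHazard * exp(betaMeth * hyper)}; censoring times are
#' independent exponential at \code{censorRate}; observed time is the
#' minimum, with event indicator 1 when the event came first. Overall and
#' leukemia-free survival are drawn from the same model (LFS hazard scaled
#' by 1.2). Binary mutation flags are Bernoulli at
#' \code{covariateFreqs}; age, blood counts and IPSS are drawn from
#' distributions sketching an MDS cohort.
#'
#' @param design a \linkS4class{SurvivalSimDesign}.
#' @return \code{data.frame}, one row per patient, with methylation value
#'   and group, covariates, mutation flags, and \code{os_time}/
#'   \code{os_event}/\code{lfs_time}/\code{lfs_event} (times in months).
#' @export
simulateClinical <- function(design = survivalSimDesign()) {
    stopifnot(is(design, "SurvivalSimDesign"))
    set.seed(design@seed)
    n <- design@n
    meth_value <- rlnorm(n, meanlog = log(0.25), sdlog = 0.7)
    thr <- quantile(meth_value, 1 - design@methFreq)
    hyper <- as.integer(meth_value > thr)
    haz <- design@baselineHazard * exp(design@betaMeth * hyper)
    drawSurv <- function(scale) {
        ev <- rexp(n, haz * scale)
        cn <- if (design@censorRate > 0) rexp(n, design@censorRate) else Inf
        list(time = pmin(ev, cn), event = as.integer(ev <= cn))
    }
    os <- drawSurv(1); lfs <- drawSurv(1.2)
    age <- pmin(pmax(round(rnorm(n, 60, 14)), 14), 90)
    out <- data.frame(
        patient_id = sprintf("pt_%04d", seq_len(n)),
        methylation_value = meth_value,
        meth_group = factor(ifelse(hyper == 1, "hyper", "non"),
                            levels = c("non", "hyper")),
        age = age,
        age_gt60 = as.integer(age > 60),
        sex = sample(c("male", "female"), n, replace = TRUE, prob = c(.55, .45)),
        wbc = round(rlnorm(n, log(2.8), 0.6), 1),
        hemoglobin = round(rnorm(n, 70, 20)),
        platelets = round(rlnorm(n, log(60), 0.9)),
        bm_blasts = round(pmin(rexp(n, 1 / 5), 19), 1),
        ipss = sample(c("Low", "Int-1", "Int-2", "High"), n, replace = TRUE,
                      prob = c(0.13, 0.54, 0.22, 0.11)),
        os_time = os$time, os_event = os$event,
        lfs_time = lfs$time, lfs_event = lfs$event,
        stringsAsFactors = FALSE)
    for (nm in names(design@covariateFreqs))
        out[[nm]] <- rbinom(n, 1, design@covariateFreqs[[nm]])
    out
}
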