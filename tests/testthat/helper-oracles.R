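# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# naive O(n*4) sliding-window scan for CCGG (1-based starts)
naiveCcggScan <- function(seq) {
    v <- strsplit(seq, "")[[1]]
    n <- length(v)
    if (n < 4) return(integer())
    which(vapply(seq_len(n - 3), function(i)
        v[i] == "C" && v[i + 1] == "C" && v[i + 2] == "G" && v[i + 3] == "G",
        logical(1)))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (minimum-likelihood rule, rel tol 1e-7)
fisherEnumOracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    xs <- max(0, c1 - r2):min(r1, c1)
    pr <- dhyper(xs, r1, r2, c1)
    obs <- dhyper(a, r1, r2, c1)
    sum(pr[pr <= obs * (1 + 1e-7)])
}

# all-pairs interval overlap: which sites (width-1, 1-based) fall in which
# closed intervals
bruteForceAssign <- function(site_contig, site_pos, unit_contig,
                             unit_start, unit_end) {
    lapply(seq_along(unit_start), function(u)
        which(site_contig == unit_contig[u] &
              site_pos >= unit_start[u] & site_pos <= unit_end[u]))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mannWhitneyEnumOracle <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    pooled <- c(x, y)
    uStat <- function(idx) {
        xx <- pooled[idx]; yy <- pooled[-idx]
        sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    }
    obs <- uStat(seq_len(n1))
    us <- apply(utils::combn(n, n1), 2, uStat)
    min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# genes whose promoters are isolated (no other promoter within `gap` bp), so
# a planted fragment supports exactly one gene
isolatedPromoterGenes <- function(fr, proms, gap = 300) {
    wide <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(proms),
        IRanges::IRanges(pmax(BiocGenerics::start(proms) - gap, 1),
                         BiocGenerics::end(proms) + gap))
    clash <- GenomicRanges::countOverlaps(wide, wide,
                                          ignore.strand = TRUE) > 1
    covered <- IRanges::overlapsAny(proms, fr, ignore.strand = TRUE)
    proms$gene_id[!clash & covered]
}

# tiny simulated RRBS dataset builder used by several files
makeTinyDataset <- function(seed = 11, contig_len = 50000, n_genes = 10,
                            planted = NULL, delta = 0.4, ...) {
    sim <- simulateGenome(contig_len = contig_len, n_genes = n_genes,
                          seed = seed)
    fr <- mspFragments(sim$genome)
    eff <- if (is.null(planted))
        data.frame(unit_id = character(), delta = numeric())
    else data.frame(unit_id = planted, delta = delta)
    des <- simDesign(plantedEffects = eff, seed = seed + 1, ...)
    calls <- suppressWarnings(simulateMethylome(sim$genome, fr, des))
    list(sim = sim, fragments = fr, calls = calls, design = des)
}
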