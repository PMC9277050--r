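mkDm <- function(unit_id, diff, status, kind = "fragment") {
    res <- S4Vectors::DataFrame(
        unit_id = unit_id, kind = rep(kind, length(unit_id)),
        gene_id = rep(NA_character_, length(unit_id)),
        mean_case = 0.5 + diff / 2, mean_ctrl = 0.5 - diff / 2,
        diff = diff, p = ifelse(status == "ns", 0.5, 1e-4),
        q = ifelse(status == "ns", 0.8, 1e-3), status = status)
    S4Vectors::metadata(res) <- list(p_thr = 0.05, q_thr = 0.05,
                                     diff_thr = 0.25, test = "ttest")
    new("DMResults", res)
}

mkUnits <- function(unit_id, start, end) {
    u <- GRanges(rep("chr1", length(unit_id)), IRanges(start, end))
    u$unit_id <- unit_id; u$kind <- rep("fragment", length(unit_id))
    u
}

test_that("DMF-to-gene annotation uses >= 1 bp promoter/body overlap", {
    genes <- geneModels(c("G1", "G2"), "chr1", "+",
                        tss = c(5000, 7050), tes = c(9000, 9500),
                        contig_lengths = c(chr1 = 30000L))
    proms <- promoterRegions(genes)     # G1: [3001,7000]; G2: [5051,9050]
    bodies <- geneBodyRegions(genes)
    dm <- mkDm(c("f1", "f2", "f3"), c(0.3, 0.4, -0.3),
               c("hyper", "hyper", "hypo"))
    units <- mkUnits(c("f1", "f2", "f3"),
                     start = c(3101, 20000, 6900),
                     end = c(3200, 20100, 7010))
    ann <- annotateDmfs(dm, units, proms, bodies)
    # f1 overlaps only G1's promoter
    a1 <- ann[ann$unit_id == "f1", ]
    expect_equal(a1$gene_id, "G1")
    expect_true(a1$in_promoter)
    # f2 overlaps nothing -> intergenic
    expect_true(is.na(ann$gene_id[ann$unit_id == "f2"]))
    # f3 spans both promoters -> linked to both genes
    expect_setequal(ann$gene_id[ann$unit_id == "f3"], c("G1", "G2"))
})

test_that("candidate direction follows unanimity of promoter DMFs", {
    genes <- geneModels(c("G1", "G2"), "chr1", "+",
                        tss = c(5000, 20000), tes = c(9000, 24000),
                        contig_lengths = c(chr1 = 40000L))
    proms <- promoterRegions(genes)
    bodies <- geneBodyRegions(genes)
    dm <- mkDm(c("f1", "f2", "f3", "f4"), c(0.3, 0.45, 0.5, -0.4),
               c("hyper", "hyper", "hyper", "hypo"))
    units <- mkUnits(c("f1", "f2", "f3", "f4"),
                     start = c(3101, 4000, 18500, 19000),
                     end = c(3200, 4100, 18600, 19100))
    cand <- selectCandidates(annotateDmfs(dm, units, proms, bodies))
    expect_setequal(cand$gene_id, c("G1", "G2"))
    expect_equal(cand$direction[cand$gene_id == "G1"], "hyper")
    expect_equal(cand$n_supporting[cand$gene_id == "G1"], 2L)
    expect_equal(cand$direction[cand$gene_id == "G2"], "ambiguous")
    # sorted by |best_diff| descending; G2 carries the 0.5 fragment
    expect_equal(cand$gene_id[1], "G2")
    expect_equal(cand$best_diff[cand$gene_id == "G1"], 0.45)
    # partition property
    expect_equal(sum(cand$direction %in% c("hyper", "hypo", "ambiguous")),
                 nrow(cand))
    expect_equal(nrow(selectCandidates(
        annotateDmfs(mkDm(character(), numeric(), character()),
                     mkUnits(character(), integer(), integer()),
                     proms, bodies))), 0L)
})

test_that("planted promoter effects are recovered end to end", {
    sim <- simulateGenome(contig_len = 120000, n_genes = 12, seed = 71)
    fr <- mspFragments(sim$genome)
    proms <- promoterRegions(sim$genes)
    bodies <- geneBodyRegions(sim$genes)
    planted_genes <- isolatedPromoterGenes(fr, proms)
    expect_gte(length(planted_genes), 4)
    sign <- rep(c(1, -1), length.out = length(planted_genes))
    ov <- findOverlaps(fr, proms[match(planted_genes, proms$gene_id)],
                       ignore.strand = TRUE)
    pf <- data.frame(unit_id = fr$unit_id[queryHits(ov)],
                     delta = 0.4 * sign[subjectHits(ov)])
    pf <- pf[!duplicated(pf$unit_id), ]
    calls <- simulateMethylome(sim$genome, fr,
                               simDesign(plantedEffects = pf, seed = 72))
    m <- unitMethylation(calls, fr)
    dm <- callDmf(m)
    cand <- selectCandidates(annotateDmfs(dm, rowRanges(m), proms, bodies,
                                          sim$cgi))
    found <- cand$gene_id[cand$direction != "ambiguous"]
    recall <- mean(planted_genes %in% found)
    expect_gte(recall, 0.9)
    dir_ok <- vapply(intersect(planted_genes, found), function(g)
        cand$direction[cand$gene_id == g] ==
            ifelse(sign[match(g, planted_genes)] > 0, "hyper", "hypo"),
        logical(1))
    expect_true(all(dir_ok))
    # supporting units all pass the triple threshold, re-checked from the table
    sup <- unlist(strsplit(cand$supporting_units, ","))
    rec <- dm[match(sup, dm$unit_id), ]
    expect_true(all(rec$p < 0.05 & rec$q < 0.05 & abs(rec$diff) > 0.25))
})
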