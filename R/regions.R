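#' Build gene models from coordinates
#'
#' Gene coordinates follow the gene-model TSV dialect: 0-based
#' \code{tss}/\code{tes} with the TES exclusive, so a plus-strand gene
#' spans \code{[tss, tes)} and a minus-strand gene (\code{tss > tes})
#' spans \code{[tes, tss)}. Internally the gene body is stored as a
#' 1-based closed \code{GRanges} and the 1-based TSS base is kept in the
#' \code{tss} metadata column.
#'
#' @param gene_id character gene identifiers (unique).
#' @param contig contig name per gene.
#' @param strand "+" or "-" per gene.
#' @param tss,tes 0-based transcription start / end coordinates; for minus
#'   strand genes \code{tss > tes}.
#' @param contig_lengths optional named integer vector of contig lengths,
#'   used for clipping promoters at contig edges.
#' @return \code{GRanges} spanning each gene body, with \code{gene_id} and
#'   \code{tss} (1-based TSS base) metadata columns.
#' @export
geneModels <- function(gene_id, contig, strand, tss, tes,
                       contig_lengths = NULL) {
    if (anyDuplicated(gene_id)) stop("gene ids must be unique")
    if (any(tss == tes)) stop("tss must differ from tes")
    plus <- strand == "+"
    if (any(plus & tss > tes) || any(!plus & tss < tes))
        stop("strand + requires tss < tes; strand - requires tss > tes")
    if (!is.null(contig_lengths)) {
        unknown <- setdiff(unique(contig), names(contig_lengths))
        if (length(unknown))
            stop("gene(s) on unknown contig: ", paste(unknown, collapse = ", "))
    }
    gr <- GRanges(contig,
                  IRanges(pmin(tss, tes) + 1L, pmax(tss, tes)),
                  strand = strand)
    if (!is.null(contig_lengths)) {
        seqlevels(gr) <- names(contig_lengths)
        seqlengths(gr) <- contig_lengths
    }
    mcols(gr) <- DataFrame(gene_id = as.character(gene_id),
                           tss = as.integer(tss) + 1L)
    gr
}

#' Promoter windows around transcription start sites
#'
#' The promoter of a gene is the symmetric window of \code{flank} bp on
#' each side of its TSS, clipped at contig boundaries. Strand is used only
#' to locate the TSS; the window itself is strand-symmetric.
#'
#' @param genes gene models from \code{geneModels}/\code{readGeneModels}.
#' @param flank half-width of the window in bp (default 2000, i.e. a
#'   +/- 2 kb promoter).
#' @return \code{GRanges} of width \code{2*flank} (except at contig edges)
#'   with \code{unit_id}, \code{kind = "promoter"} and \code{gene_id}.
#' @examples
#' g <- geneModels("G1", "chr1", "+", tss = 5000, tes = 8000,
#'                 contig_lengths = c(chr1 = 20000L))
#' promoterRegions(g)  # 1-based [3001, 7000] == 0-based [3000, 7000)
#' @export
promoterRegions <- function(genes, flank = 2000) {
    if (flank <= 0) stop("flank must be positive")
    tss1 <- mcols(genes)$tss
    if (is.null(tss1)) stop("gene models must carry a 'tss' column")
    s <- pmax(tss1 - flank, 1L)
    e <- tss1 + flank - 1L
    sl <- seqlengths(genes)[as.character(seqnames(genes))]
    if (!all(is.na(sl))) e <- pmin(e, ifelse(is.na(sl), e, sl))
    out <- GRanges(seqnames(genes), IRanges(s, e),
                   seqinfo = GenomeInfoDb::seqinfo(genes))
    mcols(out)$unit_id <- sprintf("prom_%s", mcols(genes)$gene_id)
    mcols(out)$kind <- rep("promoter", length(out))
    mcols(out)$gene_id <- mcols(genes)$gene_id
    out
}

#' Gene-body analysis units
#'
#' The gene body is the interval spanned from TSS to TES, irrespective of
#' strand.
#'
#' @param genes gene models.
#' @return \code{GRanges} with \code{unit_id}, \code{kind = "gene_body"}
#'   and \code{gene_id}.
#' @export
geneBodyRegions <- function(genes) {
    out <- granges(genes, use.names = FALSE)
    strand(out) <- "*"
    mcols(out)$unit_id <- sprintf("body_%s", mcols(genes)$gene_id)
    mcols(out)$kind <- rep("gene_body", length(out))
    mcols(out)$gene_id <- mcols(genes)$gene_id
    out
}

#' Detect CpG islands (Gardiner-Garden style)
#'
#' Slides a window of \code{window} bp (1 bp step) and marks windows with
#' GC fraction >= \code{gc_min} and observed/expected CpG ratio
#' \eqn{(n_{CpG} \cdot L)/(n_C \cdot n_G)} >= \code{oe_min}. Overlapping
#' qualifying windows are merged, and merged runs shorter than
#' \code{min_len} are dropped. This is the classical island rule
#' (GC >= 50\%, O/E >= 0.6, >= 200 bp); an externally supplied island
#' track (\code{readCgiTrack}) bypasses detection entirely.
#'
#' @param genome a named \code{DNAStringSet}, or a single sequence string.
#' @param window window size in bp (>= 100).
#' @param gc_min minimum GC fraction per window.
#' @param oe_min minimum observed/expected CpG ratio per window.
#' @param min_len minimum merged island length in bp.
#' @return \code{GRanges} with \code{unit_id} and \code{kind = "cgi"}.
#' @export
detectCgi <- function(genome, window = 200, gc_min = 0.50, oe_min = 0.60,
                      min_len = 200) {
    if (window < 100) stop("window must be >= 100")
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(c(seq1 = genome))
    res <- lapply(seq_along(genome), function(i) {
        x <- genome[[i]]
        L <- length(x)
        if (L < window) return(NULL)
        v <- strsplit(as.character(x), "")[[1]]
        isC <- as.integer(v == "C"); isG <- as.integer(v == "G")
        isCpG <- c(as.integer(v[-L] == "C" & v[-1] == "G"), 0L)
        winsum <- function(z, w) {
            cs <- cumsum(z)
            cs[w:length(z)] - c(0, cs)[seq_len(length(z) - w + 1L)]
        }
        nC <- winsum(isC, window); nG <- winsum(isG, window)
        nCpG <- winsum(isCpG[-L], window - 1L)  # CpG starts fully inside window
        gc <- (nC + nG) / window
        oe <- ifelse(nC * nG > 0, nCpG * window / (nC * nG), 0)
        ok <- which(gc >= gc_min & oe >= oe_min)
        if (!length(ok)) return(NULL)
        merged <- IRanges::reduce(IRanges(ok, ok + window - 1L))
        merged <- merged[width(merged) >= min_len]
        if (!length(merged)) return(NULL)
        GRanges(names(genome)[i], merged)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    out <- if (length(res)) do.call(c, res) else GRanges()
    if (!is.null(names(genome))) {
        seqlevels(out) <- names(genome)
        seqlengths(out) <- width(genome)
    }
    mcols(out)$unit_id <- sprintf("cgi_%04d", seq_along(out))
    mcols(out)$kind <- rep("cgi", length(out))
    out
}

#' Assign CpG sites to analysis units
#'
#' A site belongs to every unit whose interval contains it; overlapping
#' units (e.g. a fragment inside a promoter) each receive the site.
#'
#' @param sites \code{GRanges} of width-1 CpG positions.
#' @param units \code{GRanges} of analysis units with a \code{unit_id}
#'   metadata column.
#' @return Named \code{IntegerList}: for each unit id, the indices into
#'   \code{sites} that fall inside it (empty where none do).
#' @export
assignSitesToUnits <- function(sites, units) {
    uid <- mcols(units)$unit_id
    if (is.null(uid)) stop("units must carry a unit_id column")
    ov <- findOverlaps(sites, units, ignore.strand = TRUE)
    f <- factor(uid[S4Vectors::subjectHits(ov)], levels = uid)
    S4Vectors::splitAsList(S4Vectors::queryHits(ov), f)
}

#' Combine unit sets into one catalog
#'
#' @param ... \code{GRanges} unit sets (fragments, promoters, gene bodies,
#'   islands), each with \code{unit_id} and \code{kind} columns.
#' @return A single \code{GRanges}; \code{gene_id} is \code{NA} where a
#'   set does not define it.
#' @export
unitCatalog <- function(...) {
    sets <- list(...)
    sets <- lapply(sets, function(g) {
        if (is.null(mcols(g)$gene_id))
            mcols(g)$gene_id <- rep(NA_character_, length(g))
        mcols(g) <- mcols(g)[, c("unit_id", "kind", "gene_id")]
        g
    })
    out <- do.call(c, sets)
    if (anyDuplicated(mcols(out)$unit_id)) stop("duplicate unit ids")
    out
}
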