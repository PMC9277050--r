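#' Read a genome FASTA
#'
#' Contig names are the first whitespace-delimited token of each header;
#' sequences are uppercased on load. Duplicate contig names are an error.
#'
#' @param path FASTA file, wrapped or unwrapped, multi-contig.
#' @return Named \code{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    g <- Biostrings::readDNAStringSet(path)
    if (length(g) == 0L) stop("empty FASTA: ", path)
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g)))
        stop("duplicate contig name in ", path)
    Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome FASTA
#' @param genome named \code{DNAStringSet}
#' @param path output file
#' @export
writeGenomeFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}

#' Read Bismark-style coverage files into a CpGCallSet
#'
#' Each file has six tab-separated columns: contig, start, end (1-based
#' inclusive, start = end = the C position), methylation percentage,
#' methylated count, unmethylated count. The percentage column is
#' recomputed from the counts; a discrepancy beyond 0.1 raises a warning
#' and the counts win. Positions absent from a file are zero-coverage
#' CpGs.
#'
#' @param paths named character vector of file paths; names become sample
#'   names (else file base names are used).
#' @param groups optional case/ctrl label per sample.
#' @return A \linkS4class{CpGCallSet} over the union of positions.
#' @export
readCoverage <- function(paths, groups = NULL) {
    if (is.null(names(paths)))
        names(paths) <- sub("\\.(cov|txt|tsv)(\\.gz)?$", "", basename(paths))
    tabs <- lapply(paths, function(p) {
        if (!file.exists(p)) stop("no such file: ", p)
        if (file.size(p) == 0L) {
            warning("empty coverage file: ", p)
            return(data.frame(contig = character(), pos = integer(),
                              M = integer(), U = integer()))
        }
        d <- read.table(p, sep = "\t", header = FALSE,
                        col.names = c("contig", "start", "end", "pct",
                                      "M", "U"),
                        colClasses = c("character", "integer", "integer",
                                       "numeric", "integer", "integer"))
        if (any(d$M < 0 | d$U < 0)) stop("negative counts in ", p)
        tot <- d$M + d$U
        recomputed <- ifelse(tot > 0, 100 * d$M / tot, 0)
        if (any(abs(recomputed - d$pct) > 0.1))
            warning("inconsistent methylation% column in ", p,
                    "; counts take precedence")
        data.frame(contig = d$contig, pos = d$start, M = d$M, U = d$U)
    })
    allpos <- unique(do.call(rbind,
        lapply(tabs, function(d) d[, c("contig", "pos")])))
    allpos <- allpos[order(allpos$contig, allpos$pos), , drop = FALSE]
    key <- paste(allpos$contig, allpos$pos)
    M <- U <- matrix(0L, nrow(allpos), length(tabs),
                     dimnames = list(NULL, names(paths)))
    for (j in seq_along(tabs)) {
        i <- match(paste(tabs[[j]]$contig, tabs[[j]]$pos), key)
        M[i, j] <- tabs[[j]]$M
        U[i, j] <- tabs[[j]]$U
    }
    pos <- GRanges(allpos$contig, IRanges(allpos$pos, width = 1L))
    cd <- DataFrame(sample = names(paths), row.names = names(paths))
    if (!is.null(groups)) cd$group <- groups
    CpGCallSet(M, U, pos, cd)
}

#' Write per-sample coverage files
#'
#' Writes one Bismark-dialect coverage file per sample (rows with zero
#' coverage are omitted).
#'
#' @param calls a \linkS4class{CpGCallSet}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeCoverage <- function(calls, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    M <- methReads(calls); U <- unmethReads(calls)
    contig <- as.character(seqnames(rowRanges(calls)))
    pos <- start(rowRanges(calls))
    paths <- vapply(seq_len(ncol(calls)), function(j) {
        keep <- (M[, j] + U[, j]) > 0
        d <- data.frame(contig[keep], pos[keep], pos[keep],
                        round(100 * M[keep, j] / (M[keep, j] + U[keep, j]), 6),
                        M[keep, j], U[keep, j])
        f <- file.path(dir, paste0(colnames(calls)[j], ".cov"))
        write.table(d, f, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        f
    }, character(1))
    invisible(stats::setNames(paths, colnames(calls)))
}

#' Read a gene-model TSV
#'
#' Columns: gene_id, contig, strand, tss, tes (tab-separated, with
#' header), coordinates 0-based with exclusive TES, minus-strand genes
#' having tss > tes.
#'
#' @param path input file.
#' @param contig_lengths optional named lengths for boundary clipping.
#' @return Gene-model \code{GRanges} (see \code{geneModels}).
#' @export
readGeneModels <- function(path, contig_lengths = NULL) {
    d <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    need <- c("gene_id", "contig", "strand", "tss", "tes")
    if (!all(need %in% names(d)))
        stop("gene-model file needs columns: ", paste(need, collapse = ", "))
    geneModels(d$gene_id, d$contig, d$strand, d$tss, d$tes, contig_lengths)
}

#' @rdname readGeneModels
#' @param genes gene-model \code{GRanges}
#' @export
writeGeneModels <- function(genes, path) {
    m <- mcols(genes)
    plus <- as.character(strand(genes)) == "+"
    tss0 <- m$tss - 1L
    tes0 <- ifelse(plus, end(genes), start(genes) - 1L)
    write.table(
        data.frame(gene_id = m$gene_id,
                   contig = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   tss = tss0, tes = tes0),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an externally supplied CpG-island BED track
#'
#' A supplied island annotation bypasses \code{detectCgi} and is loaded
#' verbatim (BED 0-based half-open coordinates converted on import).
#'
#' @param path BED file (>= 3 columns).
#' @return \code{GRanges} with \code{unit_id} and \code{kind = "cgi"}.
#' @export
readCgiTrack <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    strand(gr) <- "*"
    out <- granges(gr)
    mcols(out)$unit_id <- if (!is.null(mcols(gr)$name) &&
                              !anyNA(mcols(gr)$name))
        as.character(mcols(gr)$name) else sprintf("cgi_%04d", seq_along(gr))
    mcols(out)$kind <- rep("cgi", length(out))
    out
}

#' Write analysis units as BED
#'
#' BED3+1: contig, 0-based half-open interval, unit id as the name field.
#'
#' @param units \code{GRanges} with \code{unit_id}.
#' @param path output .bed path.
#' @export
writeUnitsBed <- function(units, path) {
    out <- granges(units)
    names(out) <- mcols(units)$unit_id
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read/write the unit catalog TSV
#'
#' Catalog columns: unit_id, contig, start (0-based), end (half-open
#' exclusive), kind, gene_id.
#'
#' @param units \code{GRanges} with \code{unit_id}, \code{kind} and
#'   optionally \code{gene_id}.
#' @param path file path.
#' @export
writeUnitCatalog <- function(units, path) {
    m <- mcols(units)
    write.table(
        data.frame(unit_id = m$unit_id,
                   contig = as.character(seqnames(units)),
                   start = start(units) - 1L, end = end(units),
                   kind = m$kind,
                   gene_id = if (!is.null(m$gene_id)) m$gene_id
                             else NA_character_),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeUnitCatalog
#' @export
readUnitCatalog <- function(path) {
    d <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    gr <- GRanges(d$contig, IRanges(d$start + 1L, d$end))
    mcols(gr)$unit_id <- d$unit_id
    mcols(gr)$kind <- d$kind
    mcols(gr)$gene_id <- d$gene_id
    gr
}

#' Read a sample sheet
#'
#' Two tab-separated columns with header: sample, group (case/ctrl).
#'
#' @param path input file.
#' @return data.frame with sample and group columns.
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    d <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(d)))
        stop("sample sheet needs 'sample' and 'group' columns")
    if (!all(d$group %in% c("case", "ctrl")))
        stop("group must be 'case' or 'ctrl'")
    d
}

#' Read a clinical table TSV
#'
#' Tab-separated with header; empty fields and "NA" load as missing
#' (mutation flags are tri-state: 0, 1 or missing).
#'
#' @param path input file.
#' @return data.frame of patient records.
#' @export
readClinicalTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    read.table(path, sep = "\t", header = TRUE, na.strings = c("NA", ""),
               stringsAsFactors = FALSE)
}

#' Write a differential-methylation table
#' @param dm a \linkS4class{DMResults}
#' @param path output TSV
#' @export
writeDmfTable <- function(dm, path) {
    write.table(as.data.frame(dm), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
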