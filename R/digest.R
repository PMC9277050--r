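#' Find MspI recognition sites (CCGG) in a sequence
#'
#' Reports the 1-based start position of every CCGG occurrence on the
#' forward strand. CCGG is its own reverse complement, so a single-strand
#' scan is complete. \code{N} bases never match.
#'
#' @param sequence an uppercase nucleotide string over A,C,G,T,N (or a
#'   \code{DNAString}).
#' @return Integer vector of ascending 1-based match start positions.
#' @examples
#' findCcggSites("ACCGGTCCGG")  # 2, 7
#' @export
findCcggSites <- function(sequence) {
    if (is.character(sequence)) {
        if (length(sequence) != 1L)
            stop("'sequence' must be a single string")
        if (grepl("[^ACGTN]", sequence))
            stop("sequence must be uppercase over {A,C,G,T,N}")
        sequence <- Biostrings::DNAString(sequence)
    }
    start(Biostrings::matchPattern("CCGG", sequence))
}

#' In-silico MspI digestion with size selection
#'
#' MspI cleaves C^CGG, i.e. one base into the recognition site. Fragments
#' are the intervals between consecutive cut points on a contig; the
#' terminal segments before the first and after the last cut are not
#' flanked by two cuts and are excluded by default. Retained fragments
#' satisfy \code{min_len <= width <= max_len} (both inclusive), the
#' reduced-representation size selection.
#'
#' With sites at 1-based starts \eqn{s_1 < s_2}, the fragment between them
#' is \code{[s1 + 1, s2]} (width \code{s2 - s1}): it begins with the CGG of
#' the upstream site — so every fragment contains at least one CpG — and
#' ends with the first C of the downstream site.
#'
#' @param genome a named \code{DNAStringSet} (see \code{readGenomeFasta}).
#' @param min_len,max_len inclusive size-selection bounds in bp.
#' @param include_terminal also keep the unflanked terminal segments of
#'   each contig (subject to the same size selection).
#' @return \code{GRanges} with metadata columns \code{unit_id} and
#'   \code{kind = "fragment"}, sorted and non-overlapping per contig.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = paste0(
#'     strrep("A", 10), "CCGG", strrep("T", 96), "CCGG", strrep("A", 10))))
#' mspFragments(g)  # one fragment of width 100
#' @export
mspFragments <- function(genome, min_len = 40, max_len = 220,
                         include_terminal = FALSE) {
    if (min_len > max_len) stop("min_len must be <= max_len")
    if (min_len < 1) stop("fragment size bounds must be positive")
    if (length(genome) == 0L)
        return(GRanges(unit_id = character(), kind = character()))
    hits <- Biostrings::vmatchPattern("CCGG", genome)
    res <- lapply(seq_along(genome), function(i) {
        s <- start(hits[[i]])
        len <- width(genome)[i]
        cuts <- s + 1L                    # C^CGG: cut one base into the site
        starts <- cuts[-length(cuts)]
        ends <- if (length(cuts) >= 2L) cuts[-1L] - 1L else integer()
        if (include_terminal && length(cuts)) {
            starts <- c(1L, starts, cuts[length(cuts)])
            ends <- c(cuts[1L] - 1L, ends, len)
        }
        if (!length(starts)) return(NULL)
        keep <- (ends - starts + 1L) >= min_len & (ends - starts + 1L) <= max_len
        if (!any(keep)) return(NULL)
        GRanges(names(genome)[i], IRanges(starts[keep], ends[keep]))
    })
    res <- res[!vapply(res, is.null, logical(1))]
    out <- if (length(res)) do.call(c, res) else GRanges()
    seqlevels(out) <- names(genome)
    seqlengths(out) <- width(genome)
    mcols(out)$unit_id <- sprintf("frag_%05d", seq_along(out))
    mcols(out)$kind <- rep("fragment", length(out))
    out
}
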