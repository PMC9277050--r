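#' Annotate differentially methylated units to genes and region classes
#'
#' Links every significant unit (status \code{hyper}/\code{hypo}) to each
#' gene whose promoter or gene body it overlaps by at least 1 bp; CpG
#' island overlap is recorded as a flag. A unit overlapping no gene region
#' is kept with \code{gene_id = NA} (intergenic) and is excluded from
#' gene-level counting downstream. Units spanning several genes' regions
#' are linked to all of them.
#'
#' @param dm a \linkS4class{DMResults} from \code{callDmf}.
#' @param units \code{GRanges} of the tested units (same \code{unit_id}s).
#' @param promoters,gene_bodies \code{GRanges} from
#'   \code{promoterRegions}/\code{geneBodyRegions}.
#' @param cgis optional \code{GRanges} of CpG islands.
#' @return \code{DataFrame}: one row per unit-gene link (or one row with
#'   \code{NA} gene for intergenic units), columns \code{unit_id},
#'   \code{gene_id}, \code{in_promoter}, \code{in_gene_body},
#'   \code{in_cgi}, \code{status}, \code{diff}, \code{q}.
#' @export
annotateDmfs <- function(dm, units, promoters, gene_bodies = NULL,
                         cgis = NULL) {
    stopifnot(is(dm, "DMResults"))
    sig <- dm[dm$status != "ns", , drop = FALSE]
    idx <- match(sig$unit_id, mcols(units)$unit_id)
    if (anyNA(idx)) stop("DM unit(s) missing from 'units'")
    gr <- units[idx]
    inCgi <- if (!is.null(cgis) && length(cgis))
        IRanges::overlapsAny(gr, cgis, ignore.strand = TRUE)
    else rep(FALSE, length(gr))
    linkTo <- function(regions) {
        if (is.null(regions) || !length(regions))
            return(data.frame(u = integer(), g = character()))
        ov <- findOverlaps(gr, regions, ignore.strand = TRUE)
        data.frame(u = S4Vectors::queryHits(ov),
                   g = mcols(regions)$gene_id[S4Vectors::subjectHits(ov)])
    }
    pl <- linkTo(promoters); bl <- linkTo(gene_bodies)
    links <- unique(rbind(pl, bl))
    rows <- lapply(seq_along(gr), function(i) {
        gi <- links$g[links$u == i]
        if (!length(gi)) gi <- NA_character_
        DataFrame(unit_id = sig$unit_id[i], gene_id = gi,
                  in_promoter = gi %in% pl$g[pl$u == i],
                  in_gene_body = gi %in% bl$g[bl$u == i],
                  in_cgi = inCgi[i], status = sig$status[i],
                  diff = sig$diff[i], q = sig$q[i],
                  kind = sig$kind[i])
    })
    if (!length(rows))
        return(DataFrame(unit_id = character(), gene_id = character(),
                         in_promoter = logical(), in_gene_body = logical(),
                         in_cgi = logical(), status = character(),
                         diff = numeric(), q = numeric(), kind = character()))
    do.call(rbind, rows)
}

#' Select promoter-associated candidate genes
#'
#' A gene becomes a candidate when at least one significant unit overlaps
#' its promoter. Direction is assigned by unanimity of the signs of its
#' promoter-overlapping units: all hyper gives \code{hyper}, all hypo
#' gives \code{hypo}, mixed signs give \code{ambiguous} (kept explicit
#' rather than silently dropped, so hyper + hypo + ambiguous counts always
#' add up to the number of candidates). Output is sorted by largest
#' absolute methylation difference.
#'
#' @param ann annotation table from \code{annotateDmfs}.
#' @return \code{DataFrame}: \code{gene_id}, \code{direction},
#'   \code{n_supporting}, \code{supporting_units} (comma-separated),
#'   \code{kinds_hit}, \code{best_diff} (signed, max |diff|),
#'   \code{best_q}.
#' @export
selectCandidates <- function(ann) {
    pa <- ann[!is.na(ann$gene_id) & ann$in_promoter, , drop = FALSE]
    if (!nrow(pa))
        return(DataFrame(gene_id = character(), direction = character(),
                         n_supporting = integer(),
                         supporting_units = character(),
                         kinds_hit = character(),
                         best_diff = numeric(), best_q = numeric()))
    parts <- split(as.data.frame(pa), pa$gene_id)
    rows <- lapply(parts, function(d) {
        dirs <- unique(d$status)
        direction <- if (length(dirs) == 1L) dirs else "ambiguous"
        kinds <- sort(unique(c(d$kind,
                               "promoter"[any(d$in_promoter)],
                               "gene_body"[any(d$in_gene_body)],
                               "cgi"[any(d$in_cgi)])))
        best <- which.max(abs(d$diff))
        DataFrame(gene_id = d$gene_id[1], direction = direction,
                  n_supporting = nrow(d),
                  supporting_units = paste(sort(unique(d$unit_id)),
                                           collapse = ","),
                  kinds_hit = paste(kinds, collapse = ","),
                  best_diff = d$diff[best], best_q = min(d$q))
    })
    out <- do.call(rbind, rows)
    out[order(-abs(out$best_diff)), , drop = FALSE]
}
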