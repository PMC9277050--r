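#' Pipeline configuration
#'
#' All tunable thresholds of the analysis in one validated list. Defaults
#' encode the analysis conventions: 40-220 bp MspI size selection,
#' +/- 2 kb promoters, coverage >= 5 reads, the P < 0.05 / Q < 0.05 /
#' > 25 percentage-point DMF triple threshold, and the P < 0.200
#' multivariate Cox entry rule.
#'
#' @param min_len,max_len fragment size-selection bounds (bp).
#' @param flank promoter half-width (bp).
#' @param min_cov,min_sites CpG coverage filters (see
#'   \code{unitMethylation}).
#' @param p_thr,q_thr,diff_thr DMF thresholds.
#' @param test per-unit test ("ttest" or "fisher").
#' @param entry_p multivariate Cox entry threshold.
#' @param ties Cox tie handling.
#' @param cutoff_sd SDs above the control mean for dichotomization.
#' @param seed random seed recorded in the manifest.
#' @return Named list of settings (class \code{pipelineConfig}).
#' @export
pipelineConfig <- function(min_len = 40, max_len = 220, flank = 2000,
                           min_cov = 5, min_sites = 1, p_thr = 0.05,
                           q_thr = 0.05, diff_thr = 0.25,
                           test = "ttest", entry_p = 0.200,
                           ties = "efron", cutoff_sd = 2, seed = 1) {
    stopifnot(min_len <= max_len, flank > 0, min_cov >= 0, min_sites >= 0,
              p_thr > 0, p_thr <= 1, q_thr > 0, q_thr <= 1, diff_thr >= 0,
              test %in% c("ttest", "fisher"), entry_p > 0, entry_p <= 1,
              ties %in% c("efron", "breslow"), cutoff_sd > 0)
    structure(list(min_len = min_len, max_len = max_len, flank = flank,
                   min_cov = min_cov, min_sites = min_sites, p_thr = p_thr,
                   q_thr = q_thr, diff_thr = diff_thr, test = test,
                   entry_p = entry_p, ties = ties, cutoff_sd = cutoff_sd,
                   seed = seed),
              class = "pipelineConfig")
}

#' Run the fragment-methylation pipeline end to end
#'
#' Digest -> region building -> unit methylation -> differential calling
#' per unit kind -> promoter-associated candidate genes, and optionally
#' the clinical/survival stage. All tabular outputs are TSV; a JSON
#' manifest records the configuration, input checksums and per-stage row
#' counts, which together suffice to reproduce the run.
#'
#' @param genome_fasta path to the genome FASTA.
#' @param gene_model_tsv path to the gene-model TSV.
#' @param coverage_files named character vector of per-sample coverage
#'   files.
#' @param sample_sheet path to the sample sheet TSV (sample, group).
#' @param out_dir output directory (created).
#' @param cgi_bed optional CpG-island BED; when absent islands are
#'   detected from the sequence.
#' @param clinical_tsv optional clinical table for the survival stage.
#' @param config a \code{pipelineConfig}.
#' @return Invisibly, a list with the in-memory results (units, matrices,
#'   DM tables, candidates, manifest).
#' @export
runPipeline <- function(genome_fasta, gene_model_tsv, coverage_files,
                        sample_sheet, out_dir, cgi_bed = NULL,
                        clinical_tsv = NULL, config = pipelineConfig()) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    genome <- stage("read_genome", readGenomeFasta(genome_fasta))
    lens <- stats::setNames(width(genome), names(genome))
    genes <- stage("gene_models", readGeneModels(gene_model_tsv, lens))
    sheet <- stage("sample_sheet", readSampleSheet(sample_sheet))
    miss <- setdiff(sheet$sample, names(coverage_files))
    if (length(miss))
        stop("pipeline stage 'coverage' failed: no coverage file for ",
             paste(miss, collapse = ", "))
    calls <- stage("coverage", readCoverage(
        coverage_files[sheet$sample], groups = sheet$group))

    frags <- stage("digest", mspFragments(genome, config$min_len,
                                          config$max_len))
    proms <- stage("regions", promoterRegions(genes, config$flank))
    bodies <- geneBodyRegions(genes)
    cgis <- stage("regions", if (!is.null(cgi_bed)) readCgiTrack(cgi_bed)
                  else detectCgi(genome))

    writeUnitsBed(frags, file.path(out_dir, "fragments.bed"))
    writeUnitCatalog(unitCatalog(frags, proms, bodies, cgis),
                     file.path(out_dir, "units.tsv"))

    kinds <- list(fragment = frags, promoter = proms, gene_body = bodies,
                  cgi = cgis)
    dms <- list(); mats <- list()
    for (k in names(kinds)) {
        if (!length(kinds[[k]])) next
        m <- stage(paste0("unit_methylation_", k), suppressWarnings(
            unitMethylation(calls, kinds[[k]], config$min_cov,
                            config$min_sites)))
        if (nrow(m) == 0L) next
        dm <- stage(paste0("dmf_", k), callDmf(
            m, p_thr = config$p_thr, q_thr = config$q_thr,
            diff_thr = config$diff_thr, test = config$test))
        writeDmfTable(dm, file.path(out_dir, paste0("dmf_", k, ".tsv")))
        mats[[k]] <- m; dms[[k]] <- dm
    }

    candidates <- NULL
    if (!is.null(dms$fragment)) {
        ann <- stage("annotate", annotateDmfs(
            dms$fragment, rowRanges(mats$fragment), proms, bodies, cgis))
        candidates <- stage("candidates", selectCandidates(ann))
        write.table(as.data.frame(candidates),
                    file.path(out_dir, "candidates.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }

    clinical <- NULL
    if (!is.null(clinical_tsv)) {
        clin <- stage("clinical", readClinicalTable(clinical_tsv))
        mut <- intersect(c("CEBPA", "IDH1_2", "DNMT3A", "U2AF1", "SRSF2",
                           "SF3B1", "SETBP1"), names(clin))
        # variables constant in the cohort carry no information to test
        mut <- mut[vapply(mut, function(v)
            length(unique(stats::na.omit(clin[[v]]))) > 1, logical(1))]
        cont <- intersect(c("age", "wbc", "hemoglobin", "platelets",
                            "bm_blasts"), names(clin))
        tab1 <- stage("clinstats", clinicalComparison(
            clin, "meth_group", continuous = cont,
            categorical = c("sex"[!is.null(clin$sex)], mut)))
        write.table(tab1, file.path(out_dir, "clinical_comparison.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        lr <- stage("survival", logrankTest(clin$os_time, clin$os_event,
                                            clin$meth_group))
        clin$meth_hyper <- as.integer(clin$meth_group == "hyper")
        covs <- c("age_gt60"[!is.null(clin$age_gt60)],
                  "meth_hyper", mut)
        mv <- stage("survival", multivariateCox(
            clin, covs, "os_time", "os_event", entry_p = config$entry_p,
            ties = config$ties))
        write.table(mv$table, file.path(out_dir, "cox_table.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        clinical <- list(comparison = tab1, logrank = lr, cox = mv)
    }

    inputs <- c(genome = genome_fasta, genes = gene_model_tsv,
                samples = sample_sheet, coverage_files,
                if (!is.null(cgi_bed)) c(cgi = cgi_bed),
                if (!is.null(clinical_tsv)) c(clinical = clinical_tsv))
    manifest <- list(
        package = "fragmeth",
        version = as.character(utils::packageVersion("fragmeth")),
        config = unclass(config),
        inputs = as.list(stats::setNames(tools::md5sum(unname(inputs)),
                                         names(inputs))),
        counts = c(list(contigs = length(genome), genes = length(genes),
                        samples = ncol(calls), cpgs = nrow(calls)),
                   lapply(dms, nrow),
                   list(candidates = if (is.null(candidates)) 0L
                        else nrow(candidates))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(fragments = frags, promoters = proms, bodies = bodies,
                   cgis = cgis, matrices = mats, dm = dms,
                   candidates = candidates, clinical = clinical,
                   manifest = manifest))
}
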