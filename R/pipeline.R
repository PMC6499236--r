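#' @include mspBuilder.R simulate.R
NULL

.paramsAsList <- function(params) {
    sl <- slotNames("MspParams")
    stats::setNames(lapply(sl, function(s) slot(params, s)), sl)
}

#' Run the full MSP reconstruction pipeline
#'
#' Filters rare genes, builds non-redundant seeds with the
#' split-apply-combine strategy, selects core seeds, associates and
#' classifies genes, assembles MSPs, and quantifies each MSP per sample by
#' aggregating its top core genes. Identical inputs and parameters always
#' produce identical outputs.
#'
#' When \code{outdir} is given the following files are written: one
#' \code{msp_XXXX.tsv} per MSP (columns gene_id, class, module_id,
#' pnr_vs_core, pr_vs_core), \code{msp_summary.tsv} (msp_id, n_core,
#' n_accessory, n_shared_core, n_shared_accessory, prevalence = fraction of
#' samples with nonzero MSP abundance), \code{msp_abundance.tsv}, and the
#' effective parameters in \code{params.yaml}.
#'
#' @param input a raw \linkS4class{GeneCountMatrix} or the path of a count
#'   TSV for \code{\link{readCountTable}}.
#' @param outdir optional output directory (created if missing).
#' @param params an \linkS4class{MspParams}.
#' @param verbose log per-stage counts via \code{message()}.
#' @return Invisibly, a list with \code{msps}, \code{seeds},
#'   \code{abundance}, \code{summary} (data.frame) and \code{params}.
#' @examples
#' sim <- simulateCounts(PanGenomeSpec(nCore = 40, nAccessory = 0,
#'                                     nSamples = 30, rngSeed = 11L))
#' res <- runPipeline(sim$matrix, params = MspParams(minSeedSize = 10),
#'                    verbose = FALSE)
#' res$summary
#' @export
runPipeline <- function(input, outdir = NULL, params = MspParams(),
                        verbose = TRUE) {
    say <- function(...) if (verbose) message(sprintf(...))
    M <- if (is.character(input)) readCountTable(input) else input
    stopifnot(is(M, "GeneCountMatrix"))
    if (countScale(M) != "raw")
        stop("stage input: pipeline input must be raw counts")
    say("input: %d genes x %d samples", nrow(M), ncol(M))
    Mf <- filterRareGenes(M, t = params@t, minSamples = params@minSamples)
    say("filter: %d genes retained (counts > %g in >= %d samples)",
        nrow(Mf), params@t, params@minSamples)
    if (nrow(Mf) == 0L) {
        warning("no gene passed the rare-gene filter; empty output")
        res <- list(msps = list(), seeds = list(),
                    abundance = matrix(numeric(), 0L, ncol(M),
                                       dimnames = list(NULL, sampleIds(M))),
                    summary = .mspSummary(list(), NULL), params = params)
        if (!is.null(outdir)) .writeOutputs(res, outdir)
        return(invisible(res))
    }
    seeds <- createSeeds(Mf, params)
    say("seeds: %d non-redundant seeds (>= %d genes)",
        length(seeds), params@minSeedSize)
    cores <- selectCoreSeeds(seeds, params)
    say("core seeds: %d", length(cores))
    msps <- assembleMsps(cores, Mf, params)
    abundance <- quantifyMsps(msps, Mf, topK = params@quantifyTopK)
    say("msps: %d assembled, %d genes classified",
        length(msps), sum(vapply(msps, function(m) nrow(m@members),
                                 integer(1L))))
    res <- list(msps = msps, seeds = seeds, abundance = abundance,
                summary = .mspSummary(msps, abundance), params = params)
    if (!is.null(outdir)) .writeOutputs(res, outdir)
    invisible(res)
}

.mspSummary <- function(msps, abundance) {
    n <- length(msps)
    cnt <- function(msp, cl) sum(msp@members$class == cl)
    data.frame(
        msp_id = vapply(msps, mspId, character(1L)),
        n_core = vapply(msps, cnt, integer(1L), cl = "core"),
        n_accessory = vapply(msps, cnt, integer(1L), cl = "accessory"),
        n_shared_core = vapply(msps, cnt, integer(1L), cl = "shared_core"),
        n_shared_accessory = vapply(msps, cnt, integer(1L),
                                    cl = "shared_accessory"),
        prevalence = if (n) rowMeans(abundance > 0) else numeric(),
        stringsAsFactors = FALSE)
}

#' @importFrom data.table fwrite data.table
#' @importFrom yaml write_yaml
.writeOutputs <- function(res, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (msp in res$msps) {
        mem <- as.data.frame(msp@members)
        mods <- as.data.frame(msp@modules)
        mod <- structure(mods$moduleId, names = mods$geneId)
        tab <- data.table(gene_id = mem$geneId, class = mem$class,
                          module_id = ifelse(mem$geneId %in% names(mod),
                                             mod[mem$geneId], ""),
                          pnr_vs_core = mem$pnr, pr_vs_core = mem$pr)
        fwrite(tab, file.path(outdir, paste0(mspId(msp), ".tsv")),
               sep = "\t", quote = FALSE)
    }
    fwrite(res$summary, file.path(outdir, "msp_summary.tsv"),
           sep = "\t", quote = FALSE)
    ab <- data.table(msp_id = rownames(res$abundance))
    ab <- cbind(ab, as.data.frame(res$abundance))
    fwrite(ab, file.path(outdir, "msp_abundance.tsv"),
           sep = "\t", quote = FALSE)
    write_yaml(.paramsAsList(res$params), file.path(outdir, "params.yaml"))
    invisible(outdir)
}

#' Score a reconstruction against simulation ground truth
#'
#' Compares assembled MSPs with a \linkS4class{PanGenomeTruth}. Per MSP,
#' precision is the fraction of members whose true species matches the MSP's
#' dominant species. Per class, sensitivity (recall) is the fraction of true
#' genes of that class recovered in that class, restricted to genes retained
#' in \code{M} when a matrix is supplied. A confusion matrix of true versus
#' assigned class is included; unassigned retained genes count as
#' \code{"none"}.
#'
#' @param msps list of \linkS4class{Msp} (e.g. from
#'   \code{\link{runPipeline}}).
#' @param truth a \linkS4class{PanGenomeTruth}.
#' @param M optional \linkS4class{GeneCountMatrix} of retained genes used to
#'   restrict the denominator of recall.
#' @return List with \code{perMsp} (data.frame: msp_id, n_members,
#'   dominant_species, precision), \code{perClass} (data.frame: class,
#'   n_true, n_recovered, recall, precision) and \code{confusion} (table).
#' @export
scoreAgainstTruth <- function(msps, truth, M = NULL) {
    stopifnot(is(truth, "PanGenomeTruth"))
    trueGenes <- names(truth@geneClass)
    universe <- if (is.null(M)) trueGenes else
        intersect(trueGenes, geneIds(M))
    memb <- if (length(msps))
        do.call(rbind, lapply(msps, function(m)
            data.frame(geneId = m@members$geneId, class = m@members$class,
                       mspId = m@mspId, stringsAsFactors = FALSE)))
    else data.frame(geneId = character(), class = character(),
                    mspId = character(), stringsAsFactors = FALSE)
    unknown <- setdiff(memb$geneId, trueGenes)
    if (length(unknown))
        stop("validation error: MSP member(s) missing from truth: ",
             paste(unknown[1:3], collapse = ", "))
    perMsp <- do.call(rbind, lapply(msps, function(m) {
        sp <- truth@speciesId[m@members$geneId]
        dom <- names(sort(table(sp), decreasing = TRUE))[1L]
        data.frame(msp_id = m@mspId, n_members = length(sp),
                   dominant_species = dom,
                   precision = mean(sp == dom), stringsAsFactors = FALSE)
    }))
    if (is.null(perMsp))
        perMsp <- data.frame(msp_id = character(), n_members = integer(),
                             dominant_species = character(),
                             precision = numeric(), stringsAsFactors = FALSE)
    assigned <- structure(rep("none", length(universe)), names = universe)
    hit <- memb$geneId[memb$geneId %in% universe]
    assigned[hit] <- memb$class[memb$geneId %in% universe]
    lev <- c("core", "accessory", "shared_core", "shared_accessory", "none")
    confusion <- table(true = factor(truth@geneClass[universe],
                                     levels = c("core", "accessory")),
                       assigned = factor(assigned, levels = lev))
    perClass <- do.call(rbind, lapply(c("core", "accessory"), function(cl) {
        tr <- universe[truth@geneClass[universe] == cl]
        rec <- sum(assigned[tr] == cl)
        claimed <- memb$geneId[memb$class == cl & memb$geneId %in% universe]
        data.frame(class = cl, n_true = length(tr), n_recovered = rec,
                   recall = if (length(tr)) rec / length(tr) else NA_real_,
                   precision = if (length(claimed))
                       mean(truth@geneClass[claimed] == cl) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    list(perMsp = perMsp, perClass = perClass, confusion = confusion)
}
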