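#' @include seeding.R
NULL

#' Select core seeds
#'
#' Among non-redundant seeds, the largest of a group of related seeds is
#' taken to be a species core while the others are modules of accessory or
#' shared genes. Seeds are sorted by decreasing gene count (ties by seed id);
#' the largest remaining seed becomes a core and every remaining seed whose
#' representative has pr strictly above the threshold against it is discarded
#' from the list of potential cores; the procedure iterates until no seed is
#' left.
#'
#' @param seeds merged, size-filtered \linkS4class{GeneSeed} list.
#' @param params an \linkS4class{MspParams}.
#' @return List of core \linkS4class{GeneSeed} in selection order.
#' @export
selectCoreSeeds <- function(seeds, params = MspParams()) {
    p <- .paramsList(params)
    sizes <- vapply(seeds, function(s) length(s@geneIds), integer(1L))
    ids <- vapply(seeds, seedId, character(1L))
    seeds <- seeds[order(-sizes, ids)]
    cores <- list()
    while (length(seeds)) {
        core <- seeds[[1L]]
        seeds <- seeds[-1L]
        cores[[length(cores) + 1L]] <- core
        if (!length(seeds)) break
        cRep <- core@representative
        cWrk <- .workingScale(cRep, p)
        related <- vapply(seeds, function(s) {
            st <- .pairStats(cRep, s@representative, cWrk,
                             .workingScale(s@representative, p), p)
            !is.na(st$pr) && st$pr > p$prThr
        }, logical(1L))
        seeds <- seeds[!related]
    }
    cores
}

## One pass of core representative vs every gene. Returns a data.frame of
## genes passing pr > threshold with their pr, pnr and structural-zero flags.
.coreAssociationScan <- function(core, raw, wrk, p) {
    cRep <- core@representative
    cWrk <- .workingScale(cRep, p)
    n <- nrow(raw)
    pr <- numeric(n); pnr <- numeric(n)
    anySz1 <- logical(n); anySz2 <- logical(n)
    for (i in seq_len(n)) {
        st <- .pairStats(cRep, raw[i, ], cWrk, wrk[i, ], p)
        pr[i] <- st$pr
        pnr[i] <- st$pnr
        anySz1[i] <- any(st$sz1)
        anySz2[i] <- any(st$sz2)
    }
    keep <- !is.na(pr) & pr > p$prThr
    data.frame(geneId = rownames(raw)[keep], pr = pr[keep], pnr = pnr[keep],
               anySz1 = anySz1[keep], anySz2 = anySz2[keep],
               stringsAsFactors = FALSE)
}

## Association tables for all cores with best-core assignment resolved.
.associationTables <- function(cores, M, params) {
    p <- .paramsList(params)
    raw <- counts(M)
    wrk <- .workingScale(raw, p)
    scans <- lapply(cores, .coreAssociationScan, raw = raw, wrk = wrk, p = p)
    sizes <- vapply(cores, function(s) length(s@geneIds), integer(1L))
    ## resolve genes passing against several cores: greatest pr wins, ties
    ## to the larger core, then to the earlier-selected core
    all <- do.call(rbind, lapply(seq_along(scans), function(k) {
        sc <- scans[[k]]
        if (!nrow(sc)) return(NULL)
        sc$coreIdx <- k
        sc$coreSize <- sizes[k]
        sc
    }))
    if (is.null(all) || !nrow(all))
        return(lapply(scans, function(sc) sc[integer(), , drop = FALSE]))
    ord <- order(all$geneId, -all$pr, -all$coreSize, all$coreIdx)
    all <- all[ord, , drop = FALSE]
    best <- all[!duplicated(all$geneId), , drop = FALSE]
    lapply(seq_along(cores), function(k) {
        sc <- best[best$coreIdx == k,
                   c("geneId", "pr", "pnr", "anySz1", "anySz2"),
                   drop = FALSE]
        rownames(sc) <- NULL
        sc
    })
}

#' Associate genes with core seeds
#'
#' Compares the representative of every core seed to all retained genes
#' (seeded or not). A gene with pr strictly above the threshold is associated
#' with the core; a gene passing against several cores is attached to the
#' core with the greatest pr (ties: larger core, then earlier-selected core),
#' so MSPs partition the gene set.
#'
#' @param cores core seeds from \code{\link{selectCoreSeeds}}.
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param params an \linkS4class{MspParams}.
#' @return List (one element per core, in order) of \code{data.frame}s with
#'   columns \code{geneId}, \code{pr}, \code{pnr}.
#' @export
associateGenes <- function(cores, M, params = MspParams()) {
    stopifnot(is(M, "GeneCountMatrix"))
    lapply(.associationTables(cores, M, params),
           function(sc) sc[, c("geneId", "pr", "pnr"), drop = FALSE])
}

#' Classify an associated gene
#'
#' Assigns one of four classes from the structural zeros of the comparison of
#' the core representative (g1) against the gene (g2); undetermined zeros are
#' ignored. \code{core}: no structural zeros on either side (gene present
#' exactly where the species is). \code{accessory}: the gene is confidently
#' absent from some species-positive samples, and never detected outside.
#' \code{shared_core}: the gene is present everywhere the species is, plus
#' detected in samples where the species is absent. \code{shared_accessory}:
#' both patterns. The four conditions are exhaustive and mutually exclusive.
#'
#' @param comparison a \linkS4class{GenePairComparison} of (core
#'   representative, gene).
#' @return One of \code{"core"}, \code{"accessory"}, \code{"shared_core"},
#'   \code{"shared_accessory"}.
#' @export
classifyGene <- function(comparison) {
    stopifnot(is(comparison, "GenePairComparison"))
    .classFromFlags(length(comparison@structuralZeros1) > 0L,
                    length(comparison@structuralZeros2) > 0L)
}

.classFromFlags <- function(anySz1, anySz2) {
    ## sz2: gene absent in species-positive samples; sz1: gene detected in
    ## species-negative samples
    if (anySz2) {
        if (anySz1) "shared_accessory" else "accessory"
    } else {
        if (anySz1) "shared_core" else "core"
    }
}

#' Cluster co-occurring genes of one class into modules
#'
#' Runs the greedy seed procedure on the genes of a single non-core class of
#' an MSP (one bin): admissible pairs are directly proportional with no
#' structural zeros, so a module groups genes that are co-abundant and
#' present in the same samples - interpretable as functional units such as
#' operons. Unclustered genes become singleton modules.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param geneIds genes of one class within one MSP.
#' @param params an \linkS4class{MspParams}.
#' @param idPrefix prefix for module ids.
#' @return \code{data.frame} with columns \code{geneId}, \code{moduleId};
#'   every input gene appears exactly once.
#' @export
clusterModules <- function(M, geneIds, params = MspParams(),
                           idPrefix = "m") {
    if (!length(geneIds))
        return(data.frame(geneId = character(), moduleId = character(),
                          stringsAsFactors = FALSE))
    pl <- buildPairList(M, geneIds, params)
    seeds <- greedySeedBin(pl, params)
    mod <- lapply(seeds, function(s) s@geneIds)
    rest <- sort(setdiff(geneIds, unlist(mod)))
    mod <- c(mod, as.list(rest))
    data.frame(
        geneId = unlist(mod),
        moduleId = rep(sprintf("%s%03d", idPrefix, seq_along(mod)),
                       lengths(mod)),
        stringsAsFactors = FALSE)
}

#' Assemble Metagenomic Species Pan-genomes
#'
#' For each core seed: associate genes, classify them from their structural
#' zeros, order core genes by decreasing pnr against the core representative
#' (most suitable first for taxonomic profiling), and cluster each non-core
#' class into modules. MSP ids are assigned in core selection order.
#'
#' @param cores core seeds from \code{\link{selectCoreSeeds}}.
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param params an \linkS4class{MspParams}.
#' @return List of \linkS4class{Msp}.
#' @export
assembleMsps <- function(cores, M, params = MspParams()) {
    stopifnot(is(M, "GeneCountMatrix"))
    tabs <- .associationTables(cores, M, params)
    lapply(seq_along(cores), function(k) {
        tab <- tabs[[k]]
        cls <- vapply(seq_len(nrow(tab)), function(i)
            .classFromFlags(tab$anySz1[i], tab$anySz2[i]), character(1L))
        members <- DataFrame(geneId = tab$geneId, class = cls,
                             pr = tab$pr, pnr = tab$pnr)
        members <- members[order(match(cls, c("core", "accessory",
                                              "shared_core",
                                              "shared_accessory")),
                                 -members$pnr, members$geneId), ]
        coreGenes <- members$geneId[members$class == "core"]
        ord <- order(-members$pnr[members$class == "core"],
                     members$geneId[members$class == "core"])
        coreOrd <- coreGenes[ord]
        mods <- do.call(rbind, lapply(
            c("accessory", "shared_core", "shared_accessory"),
            function(cl) {
                g <- members$geneId[members$class == cl]
                if (!length(g)) return(NULL)
                df <- clusterModules(M, g, params,
                                     idPrefix = paste0(substr(cl, 1L, 3L),
                                                       "_m"))
                df$class <- cl
                df
            }))
        if (is.null(mods))
            mods <- data.frame(geneId = character(), moduleId = character(),
                               class = character(), stringsAsFactors = FALSE)
        new("Msp",
            mspId = sprintf("msp_%04d", k),
            coreSeed = cores[[k]],
            members = members,
            coreOrder = coreOrd,
            modules = DataFrame(geneId = mods$geneId, class = mods$class,
                                moduleId = mods$moduleId))
    })
}

#' Quantify MSP abundance per sample
#'
#' Aggregates the depth-normalized counts of the first \code{topK} genes of
#' the core order (the core genes most concordant with the representative)
#' by their per-sample median. In a sample where the species is absent more
#' than half of these genes have zero counts, so the abundance is 0.
#' Doubling all counts of a sample leaves its MSP abundances unchanged.
#'
#' @param msps list of \linkS4class{Msp}.
#' @param M the raw-scale \linkS4class{GeneCountMatrix} they were built from.
#' @param topK number of top core genes aggregated (default 30).
#' @return Numeric matrix, MSPs (rows) by samples.
#' @export
quantifyMsps <- function(msps, M, topK = 30L) {
    stopifnot(is(M, "GeneCountMatrix"))
    if (!length(msps)) {
        ab <- matrix(numeric(), 0L, ncol(M),
                     dimnames = list(NULL, sampleIds(M)))
        return(ab)
    }
    norm <- .normalizedCounts(counts(M), sampleDepths(M))
    ab <- t(vapply(msps, function(msp) {
        g <- utils::head(msp@coreOrder, topK)
        if (!length(g)) return(numeric(ncol(M)))
        .colMedians(norm[g, , drop = FALSE])
    }, numeric(ncol(M))))
    rownames(ab) <- vapply(msps, mspId, character(1L))
    colnames(ab) <- sampleIds(M)
    ab
}
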