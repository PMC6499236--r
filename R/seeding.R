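#' @include proportionality.R countMatrix.R
NULL

#' Assign genes to sample bins
#'
#' Split step of seed creation: each gene is binned by the sample where its
#' depth-normalized count is largest, so that related genes tend to land in
#' the same bin and all-pairs comparison is only needed within bins.
#' Normalization by the number of mapped reads per sample avoids a bias
#' toward deeply sequenced samples; this is the only step using normalized
#' counts. Ties go to the first sample in column order.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param depths per-sample totals (default \code{\link{sampleDepths}}).
#' @return Named character vector mapping each gene id to a sample id.
#' @examples
#' m <- matrix(c(10, 18), 1, dimnames = list("g1", c("s1", "s2")))
#' assignBins(GeneCountMatrix(m), depths = c(s1 = 100, s2 = 200))  # "s1"
#' @export
assignBins <- function(M, depths = sampleDepths(M)) {
    stopifnot(is(M, "GeneCountMatrix"))
    norm <- .normalizedCounts(counts(M), depths)
    idx <- max.col(norm, ties.method = "first")
    structure(sampleIds(M)[idx], names = geneIds(M))
}

#' Candidate gene pairs of a bin
#'
#' Apply step, stage 1: evaluates every unordered pair among \code{geneIds}
#' and keeps those that are directly proportional (pnr strictly above the
#' threshold) and fully co-occurring (no structural zero on either side).
#' The list is sorted by decreasing pnr, ties by lexicographic gene-id pair.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param geneIds genes to compare (default: all genes of \code{M}).
#' @param params an \linkS4class{MspParams}.
#' @return \code{data.frame} with columns \code{gene1}, \code{gene2}
#'   (\code{gene1 < gene2}), \code{pnr}.
#' @export
buildPairList <- function(M, geneIds = NULL, params = MspParams()) {
    stopifnot(is(M, "GeneCountMatrix"))
    if (is.null(geneIds)) geneIds <- rownames(M)
    p <- .paramsList(params)
    raw <- counts(M)[geneIds, , drop = FALSE]
    wrk <- .workingScale(raw, p)
    .buildPairListFast(raw, wrk, p)
}

## Internal all-pairs scan on plain matrices (rows = genes).
.buildPairListFast <- function(raw, wrk, p) {
    n <- nrow(raw)
    ids <- rownames(raw)
    g1 <- character(); g2 <- character(); pnr <- numeric()
    if (n >= 2L) {
        res1 <- vector("list", n - 1L)
        for (i in seq_len(n - 1L)) {
            x <- raw[i, ]; xs <- wrk[i, ]
            keepJ <- integer(); keepP <- numeric()
            for (j in (i + 1L):n) {
                st <- .pairStats(x, raw[j, ], xs, wrk[j, ], p, needPr = FALSE)
                if (is.na(st$pnr) || st$pnr <= p$pnrThr) next
                if (any(st$sz1) || any(st$sz2)) next
                keepJ <- c(keepJ, j); keepP <- c(keepP, st$pnr)
            }
            if (length(keepJ))
                res1[[i]] <- list(i = i, j = keepJ, pnr = keepP)
        }
        res1 <- res1[!vapply(res1, is.null, logical(1L))]
        if (length(res1)) {
            ii <- unlist(lapply(res1, function(r) rep(r$i, length(r$j))))
            jj <- unlist(lapply(res1, function(r) r$j))
            pnr <- unlist(lapply(res1, function(r) r$pnr))
            a <- ids[ii]; b <- ids[jj]
            g1 <- pmin(a, b); g2 <- pmax(a, b)
        }
    }
    out <- data.frame(gene1 = g1, gene2 = g2, pnr = pnr,
                      stringsAsFactors = FALSE)
    out[order(-out$pnr, out$gene1, out$gene2), , drop = FALSE]
}

#' Greedy seed construction from a pair list
#'
#' Apply step, stage 2: the pair with the greatest pnr becomes a centroid;
#' every gene related to one of the two centroid genes through a saved pair
#' joins the seed; all pairs touching a seeded gene are removed and the
#' procedure iterates until the list is empty. The partition is fully
#' deterministic for a sorted pair list. Genes participating in no admissible
#' pair yield no seed (they remain candidates for later MSP association).
#'
#' @param pairList sorted pair list from \code{\link{buildPairList}}.
#' @param params an \linkS4class{MspParams}.
#' @param idPrefix prefix for the generated seed ids.
#' @return List of \linkS4class{GeneSeed} (representatives not yet computed),
#'   in creation order.
#' @export
greedySeedBin <- function(pairList, params = MspParams(),
                          idPrefix = "seed") {
    g1 <- pairList$gene1
    g2 <- pairList$gene2
    seeds <- list()
    k <- 0L
    while (length(g1)) {
        cen <- c(g1[1L], g2[1L])
        hit <- g1 %in% cen | g2 %in% cen
        members <- unique(c(cen, g1[hit], g2[hit]))
        k <- k + 1L
        seeds[[k]] <- new("GeneSeed",
                          seedId = sprintf("%s_%04d", idPrefix, k),
                          geneIds = sort(members),
                          representative = numeric())
        drop <- g1 %in% members | g2 %in% members
        g1 <- g1[!drop]
        g2 <- g2[!drop]
    }
    seeds
}

#' Seed representative pseudo-gene
#'
#' Combine step, stage 1: a seed is summarized by a pseudo-gene so that seeds
#' can be compared like genes. First the per-sample median over all seed
#' genes is taken; then each gene is ranked by pnr against that vector; the
#' final representative is the per-sample median of the \code{topN} best
#' genes, which have the highest counts and lowest dispersion. Medians are
#' computed on raw counts, keeping the representative interpretable as a
#' pseudo-gene.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param geneIds the seed's member genes.
#' @param topN number of genes kept for the final median (default 30).
#' @param params an \linkS4class{MspParams}.
#' @return Named numeric per-sample pseudo-count vector.
#' @export
computeRepresentative <- function(M, geneIds, topN = 30L,
                                  params = MspParams()) {
    stopifnot(is(M, "GeneCountMatrix"), length(geneIds) >= 1L)
    raw <- counts(M)[geneIds, , drop = FALSE]
    .representativeFromMatrix(raw, topN, .paramsList(params))
}

.colMedians <- function(m) apply(m, 2L, .med)

.representativeFromMatrix <- function(raw, topN, p) {
    if (nrow(raw) == 1L) return(raw[1L, ])
    stage1 <- .colMedians(raw)
    if (nrow(raw) > topN) {
        wrkRep <- .workingScale(stage1, p)
        wrk <- .workingScale(raw, p)
        pnr <- vapply(seq_len(nrow(raw)), function(i) {
            st <- .pairStats(stage1, raw[i, ], wrkRep, wrk[i, ], p,
                             needPr = FALSE)
            if (is.na(st$pnr)) -Inf else st$pnr
        }, numeric(1L))
        top <- order(-pnr, rownames(raw))[seq_len(topN)]
        raw <- raw[top, , drop = FALSE]
    }
    .colMedians(raw)
}

#' Merge redundant seeds
#'
#' Combine step, stage 2: related genes may have been split across bins when
#' their largest normalized counts fell in different samples, so seeds whose
#' representatives are directly proportional (pnr strictly above the
#' threshold) with no structural zeros are merged. Seeds are processed in
#' decreasing-size order (ties by seed id); an absorbing seed's
#' representative is recomputed after each absorption round until stable.
#' Finally seeds smaller than \code{minSeedSize} genes are discarded.
#'
#' @param seeds list of \linkS4class{GeneSeed} with representatives.
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param params an \linkS4class{MspParams} (\code{minSeedSize},
#'   \code{representativeTopN}, pnr threshold).
#' @return List of merged, size-filtered \linkS4class{GeneSeed}.
#' @export
mergeSeeds <- function(seeds, M, params = MspParams()) {
    p <- .paramsList(params)
    raw <- counts(M)
    wrk <- .workingScale(raw, p)
    topN <- params@representativeTopN
    sizes <- vapply(seeds, function(s) length(s@geneIds), integer(1L))
    ids <- vapply(seeds, seedId, character(1L))
    seeds <- seeds[order(-sizes, ids)]
    done <- list()
    while (length(seeds)) {
        ## re-sort remaining seeds; absorption can change nothing here but a
        ## previous round may have consumed seeds out of order
        sizes <- vapply(seeds, function(s) length(s@geneIds), integer(1L))
        ids <- vapply(seeds, seedId, character(1L))
        seeds <- seeds[order(-sizes, ids)]
        cur <- seeds[[1L]]
        seeds <- seeds[-1L]
        repeat {
            if (!length(seeds)) break
            curRep <- cur@representative
            curWrk <- .workingScale(curRep, p)
            absorb <- vapply(seeds, function(s) {
                st <- .pairStats(curRep, s@representative, curWrk,
                                 .workingScale(s@representative, p), p,
                                 needPr = FALSE)
                !is.na(st$pnr) && st$pnr > p$pnrThr &&
                    !any(st$sz1) && !any(st$sz2)
            }, logical(1L))
            if (!any(absorb)) break
            genes <- unique(c(cur@geneIds,
                              unlist(lapply(seeds[absorb],
                                            function(s) s@geneIds))))
            cur@geneIds <- sort(genes)
            cur@representative <- .representativeFromMatrix(
                raw[cur@geneIds, , drop = FALSE], topN, p)
            seeds <- seeds[!absorb]
        }
        done[[length(done) + 1L]] <- cur
    }
    keep <- vapply(done, function(s) length(s@geneIds), integer(1L)) >=
        params@minSeedSize
    done[keep]
}

#' Create non-redundant seeds from a count matrix
#'
#' Full split-apply-combine seed creation: genes are binned by the sample of
#' their largest depth-normalized count, seeds are built greedily within each
#' bin from the sorted pnr pair list, representatives are computed, and
#' redundant seeds are merged across bins. Entirely deterministic for a given
#' matrix and parameter set.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix} (already filtered).
#' @param params an \linkS4class{MspParams}.
#' @return List of \linkS4class{GeneSeed} with representatives, merged and
#'   size-filtered.
#' @seealso \code{\link{assignBins}}, \code{\link{buildPairList}},
#'   \code{\link{greedySeedBin}}, \code{\link{mergeSeeds}}
#' @export
createSeeds <- function(M, params = MspParams()) {
    stopifnot(is(M, "GeneCountMatrix"))
    p <- .paramsList(params)
    bins <- assignBins(M)
    raw <- counts(M)
    wrk <- .workingScale(raw, p)
    topN <- params@representativeTopN
    seeds <- list()
    k <- 0L
    for (s in sampleIds(M)) {           # canonical bin order: column order
        genes <- names(bins)[bins == s]
        if (length(genes) < 2L) next
        pl <- .buildPairListFast(raw[genes, , drop = FALSE],
                                 wrk[genes, , drop = FALSE], p)
        for (sd in greedySeedBin(pl, params)) {
            k <- k + 1L
            sd@seedId <- sprintf("seed_%05d", k)
            sd@representative <- .representativeFromMatrix(
                raw[sd@geneIds, , drop = FALSE], topN, p)
            seeds[[k]] <- sd
        }
    }
    mergeSeeds(seeds, M, params)
}
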