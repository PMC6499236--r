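#' @include AllClasses.R
NULL

## All simulator randomness goes through a locally seeded RNG that restores
## the caller's state on exit, so fixed seeds give bit-identical output.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

.geneIdsFor <- function(spec) {
    c(sprintf("core_%05d", seq_len(spec@nCore)),
      if (spec@nAccessory > 0L) sprintf("acc_%05d", seq_len(spec@nAccessory)))
}

## Draw the static pan-genome layout (lengths, prevalences, presence) and
## per-sample coverages for a single strain per sample.
.drawPanGenome <- function(spec) {
    genes <- .geneIdsFor(spec)
    samples <- sprintf("sample_%03d", seq_len(spec@nSamples))
    len <- round(stats::runif(length(genes), spec@geneLengthRange[1L],
                              spec@geneLengthRange[2L]))
    names(len) <- genes
    prev <- rep(NA_real_, length(genes))
    names(prev) <- genes
    acc <- spec@nCore + seq_len(spec@nAccessory)
    prev[acc] <- stats::runif(spec@nAccessory, spec@prevalenceRange[1L],
                              spec@prevalenceRange[2L])
    cls <- rep(c("core", "accessory"), c(spec@nCore, spec@nAccessory))
    names(cls) <- genes
    list(genes = genes, samples = samples, len = len, prev = prev, cls = cls)
}

.presenceDraw <- function(pg, spec) {
    pres <- matrix(TRUE, length(pg$genes), spec@nSamples,
                   dimnames = list(pg$genes, pg$samples))
    acc <- which(pg$cls == "accessory")
    if (length(acc)) {
        u <- matrix(stats::runif(length(acc) * spec@nSamples),
                    length(acc), spec@nSamples)
        pres[acc, ] <- u < pg$prev[acc]
    }
    pres
}

#' Simulate a single-species gene count table
#'
#' Generates the abundance table of one virtual species: gene lengths and
#' accessory prevalences are drawn uniformly from their ranges, every sample
#' carries a single strain whose sequencing coverage is uniform on the
#' coverage range, the theoretical count of a present gene is
#' coverage x length / readLength, and the observed count is Poisson with
#' that mean. Absent genes count exactly 0 (structural zeros by
#' construction). The complete ground truth is returned alongside.
#'
#' @param spec a \linkS4class{PanGenomeSpec}.
#' @return List with elements \code{matrix} (a raw
#'   \linkS4class{GeneCountMatrix}) and \code{truth} (a
#'   \linkS4class{PanGenomeTruth}).
#' @examples
#' sim <- simulateCounts(PanGenomeSpec(nCore = 20, nAccessory = 30,
#'                                     nSamples = 10, rngSeed = 7L))
#' sim$matrix
#' sim$truth
#' @export
simulateCounts <- function(spec = PanGenomeSpec()) {
    stopifnot(is(spec, "PanGenomeSpec"))
    .withSeed(spec@rngSeed, {
        pg <- .drawPanGenome(spec)
        cov <- stats::runif(spec@nSamples, spec@coverageRange[1L],
                            spec@coverageRange[2L])
        pres <- .presenceDraw(pg, spec)
        lambda <- pres * outer(pg$len / spec@readLength, cov)
        m <- matrix(stats::rpois(length(lambda), lambda),
                    nrow(lambda), ncol(lambda),
                    dimnames = dimnames(lambda))
        covM <- cbind(strain1 = cov, strain2 = NA_real_)
        rownames(covM) <- pg$samples
        truth <- new("PanGenomeTruth",
                     speciesId = structure(rep("sp1", length(pg$genes)),
                                           names = pg$genes),
                     geneClass = pg$cls, geneLength = pg$len,
                     genePrevalence = pg$prev, strainCoverage = covM,
                     presence = pres,
                     outlierCells = DataFrame(geneId = character(),
                                              sampleId = character(),
                                              factor = numeric()))
        list(matrix = GeneCountMatrix(m), truth = truth)
    })
}

#' Inject multiplicative outliers
#'
#' Corrupts a fraction of each gene's species-positive samples by multiplying
#' the observed count by a factor drawn uniformly from {1/4, 1/3, 2, 3, 4},
#' rounding to the nearest integer so counts stay integral. Emulates samples
#' with inconsistent counts (e.g. strain mixtures or mapping artefacts) used
#' to evaluate the robust measure. Modified cells are recorded in the truth.
#'
#' @param M a raw \linkS4class{GeneCountMatrix} from
#'   \code{\link{simulateCounts}}.
#' @param truth the matching \linkS4class{PanGenomeTruth}.
#' @param fraction proportion of present samples corrupted per gene, in
#'   (0, 1); 0 returns the input unchanged.
#' @param rngSeed integer seed.
#' @return List with updated \code{matrix} and \code{truth}.
#' @export
injectOutliers <- function(M, truth, fraction, rngSeed = 1L) {
    stopifnot(is(M, "GeneCountMatrix"), is(truth, "PanGenomeTruth"))
    if (fraction == 0) return(list(matrix = M, truth = truth))
    if (fraction < 0 || fraction >= 1)
        stop("fraction must lie in [0, 1)")
    factors <- c(1 / 4, 1 / 3, 2, 3, 4)
    .withSeed(rngSeed, {
        m <- counts(M)
        genes <- rownames(m)
        recG <- recS <- list(); recF <- list()
        for (i in seq_along(genes)) {
            present <- which(truth@presence[genes[i], ])
            k <- round(fraction * length(present))
            if (k < 1L) next
            hit <- if (length(present) == 1L) present
                   else sample(present, k)
            f <- factors[sample.int(5L, k, replace = TRUE)]
            m[i, hit] <- round(m[i, hit] * f)
            recG[[length(recG) + 1L]] <- rep(genes[i], k)
            recS[[length(recS) + 1L]] <- colnames(m)[hit]
            recF[[length(recF) + 1L]] <- f
        }
        if (max(m) < .Machine$integer.max) storage.mode(m) <- "integer"
        truth@outlierCells <- DataFrame(
            geneId = as.character(unlist(recG)),
            sampleId = as.character(unlist(recS)),
            factor = as.numeric(unlist(recF)))
        list(matrix = GeneCountMatrix(m), truth = truth)
    })
}

#' Simulate samples carrying two strains
#'
#' Like \code{\link{simulateCounts}}, but a fraction of samples carries two
#' strains of the species: the dominant strain's coverage is drawn as usual
#' and the subdominant strain is 5 to 10 times less abundant (uniform
#' dominance factor). Accessory gene content is drawn independently for each
#' strain from the same prevalence, and the Poisson mean of a gene sums the
#' contributions of the strains carrying it. Core genes are present in both
#' strains.
#'
#' @param spec a \linkS4class{PanGenomeSpec}.
#' @param dominanceRange fold-range of dominant over subdominant coverage
#'   (default \code{c(5, 10)}).
#' @param mixtureFraction proportion of samples with two strains.
#' @param rngSeed integer seed (default: the spec's seed).
#' @return List with \code{matrix} and \code{truth}; the truth's
#'   \code{strainCoverage} has both columns filled for mixed samples and its
#'   \code{presence} marks genes carried by either strain.
#' @export
simulateTwoStrains <- function(spec = PanGenomeSpec(),
                               dominanceRange = c(5, 10),
                               mixtureFraction = 0.5,
                               rngSeed = spec@rngSeed) {
    stopifnot(is(spec, "PanGenomeSpec"),
              mixtureFraction >= 0, mixtureFraction <= 1,
              length(dominanceRange) == 2L, all(dominanceRange >= 1))
    .withSeed(rngSeed, {
        pg <- .drawPanGenome(spec)
        cov1 <- stats::runif(spec@nSamples, spec@coverageRange[1L],
                             spec@coverageRange[2L])
        nMix <- round(mixtureFraction * spec@nSamples)
        mixed <- if (nMix >= 1L) sort(sample.int(spec@nSamples, nMix))
                 else integer()
        dom <- stats::runif(nMix, dominanceRange[1L], dominanceRange[2L])
        cov2 <- rep(NA_real_, spec@nSamples)
        cov2[mixed] <- cov1[mixed] / dom
        pres1 <- .presenceDraw(pg, spec)
        pres2 <- .presenceDraw(pg, spec)
        unmixed <- setdiff(seq_len(spec@nSamples), mixed)
        pres2[, unmixed] <- FALSE
        lenScaled <- pg$len / spec@readLength
        lambda <- pres1 * outer(lenScaled, cov1)
        lambda[, mixed] <- lambda[, mixed] +
            pres2[, mixed, drop = FALSE] *
            outer(lenScaled, cov2[mixed])
        m <- matrix(stats::rpois(length(lambda), lambda),
                    nrow(lambda), ncol(lambda),
                    dimnames = dimnames(lambda))
        covM <- cbind(strain1 = cov1, strain2 = cov2)
        rownames(covM) <- pg$samples
        truth <- new("PanGenomeTruth",
                     speciesId = structure(rep("sp1", length(pg$genes)),
                                           names = pg$genes),
                     geneClass = pg$cls, geneLength = pg$len,
                     genePrevalence = pg$prev, strainCoverage = covM,
                     presence = pres1 | pres2,
                     outlierCells = DataFrame(geneId = character(),
                                              sampleId = character(),
                                              factor = numeric()))
        list(matrix = GeneCountMatrix(m), truth = truth)
    })
}

#' Export / import simulation ground truth
#'
#' Writes (and reads back) the truth as two plain TSV files: a per-gene table
#' (\code{<prefix>_genes.tsv}: geneId, speciesId, class, length, prevalence)
#' and the presence matrix (\code{<prefix>_presence.tsv}, 0/1). The pair is
#' sufficient to score any binning output against the simulation.
#'
#' @param truth a \linkS4class{PanGenomeTruth}.
#' @param prefix path prefix for the two files.
#' @return \code{writePanGenomeTruth}: the two paths, invisibly.
#'   \code{readPanGenomeTruth}: a \linkS4class{PanGenomeTruth} (coverage and
#'   outlier records are not round-tripped; they are not needed for scoring).
#' @importFrom data.table fwrite fread
#' @export
writePanGenomeTruth <- function(truth, prefix) {
    genes <- data.table(geneId = names(truth@geneClass),
                        speciesId = unname(truth@speciesId),
                        class = unname(truth@geneClass),
                        length = unname(truth@geneLength),
                        prevalence = unname(truth@genePrevalence))
    gPath <- paste0(prefix, "_genes.tsv")
    pPath <- paste0(prefix, "_presence.tsv")
    fwrite(genes, gPath, sep = "\t", quote = FALSE)
    pres <- data.table(geneId = rownames(truth@presence))
    pres <- cbind(pres, as.data.frame(truth@presence + 0L))
    fwrite(pres, pPath, sep = "\t", quote = FALSE)
    invisible(c(gPath, pPath))
}

#' @rdname writePanGenomeTruth
#' @export
readPanGenomeTruth <- function(prefix) {
    genes <- fread(paste0(prefix, "_genes.tsv"), sep = "\t",
                   data.table = FALSE)
    pres <- fread(paste0(prefix, "_presence.tsv"), sep = "\t",
                  data.table = FALSE)
    pm <- as.matrix(pres[-1L]) > 0L
    rownames(pm) <- pres[[1L]]
    new("PanGenomeTruth",
        speciesId = structure(genes$speciesId, names = genes$geneId),
        geneClass = structure(genes$class, names = genes$geneId),
        geneLength = structure(genes$length, names = genes$geneId),
        genePrevalence = structure(genes$prevalence, names = genes$geneId),
        strainCoverage = matrix(NA_real_, ncol(pm), 2L,
                                dimnames = list(colnames(pm),
                                                c("strain1", "strain2"))),
        presence = pm,
        outlierCells = DataFrame(geneId = character(),
                                 sampleId = character(),
                                 factor = numeric()))
}
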