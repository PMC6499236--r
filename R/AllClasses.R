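#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

#' Gene count matrix
#'
#' A genes-by-samples matrix of mapped-read counts, stored as a
#' \linkS4class{SummarizedExperiment} with a single \code{"counts"} assay and a
#' scale flag recording whether cells are raw counts or their square roots.
#' All downstream detection thresholds are defined on raw counts, so the raw
#' matrix is the canonical representation; \code{\link{sqrtTransform}} derives
#' the variance-stabilized view used inside the proportionality measures.
#'
#' @slot countScale \code{"raw"} or \code{"sqrt"}.
#' @seealso \code{\link{readCountTable}}, \code{\link{filterRareGenes}}
#' @export
setClass("GeneCountMatrix",
    contains = "SummarizedExperiment",
    slots = c(countScale = "character"),
    prototype = prototype(countScale = "raw"))

setValidity("GeneCountMatrix", function(object) {
    msg <- character()
    if (!identical(length(object@countScale), 1L) ||
        !object@countScale %in% c("raw", "sqrt"))
        msg <- c(msg, "countScale must be \"raw\" or \"sqrt\"")
    if (!"counts" %in% assayNames(object))
        return(c(msg, "assay \"counts\" is required"))
    m <- assay(object, "counts")
    if (is.null(rownames(m)))
        msg <- c(msg, "gene identifiers (rownames) are required")
    else if (anyDuplicated(rownames(m)))
        msg <- c(msg, "duplicated gene identifiers")
    if (is.null(colnames(m)))
        msg <- c(msg, "sample identifiers (colnames) are required")
    else if (anyDuplicated(colnames(m)))
        msg <- c(msg, "duplicated sample identifiers")
    if (anyNA(m))
        msg <- c(msg, "counts contain missing values")
    else if (any(m < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneCountMatrix
#'
#' @param counts numeric matrix, genes as rows (rownames = gene ids), samples
#'   as columns (colnames = sample ids); non-negative, no missing cells.
#' @param scale \code{"raw"} (default) or \code{"sqrt"}.
#' @return A \linkS4class{GeneCountMatrix}.
#' @examples
#' m <- matrix(c(4, 6, 0, 0, 6, 9), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' GeneCountMatrix(m)
#' @export
GeneCountMatrix <- function(counts, scale = c("raw", "sqrt")) {
    scale <- match.arg(scale)
    counts <- as.matrix(counts)
    se <- SummarizedExperiment(assays = list(counts = counts))
    new("GeneCountMatrix", se, countScale = scale)
}

setMethod("show", "GeneCountMatrix", function(object) {
    cat(sprintf("GeneCountMatrix: %d genes x %d samples [%s scale]\n",
                nrow(object), ncol(object), object@countScale))
})

#' Parameters of the MSP reconstruction pipeline
#'
#' Holds every tunable of the pairwise proportionality measures and of the
#' clustering stages, with the published defaults. Alternative readings of
#' ambiguously printed formulas are exposed as toggles so either convention
#' can be reproduced.
#'
#' @slot t base detection threshold on raw counts (default 6).
#' @slot pnrThreshold association cut-off on the non-robust measure (0.8).
#' @slot prThreshold association cut-off on the robust measure (0.8).
#' @slot maxOutlierFraction cap on the tolerated outlier proportion (0.3).
#' @slot minSamples samples required above \code{t} by the rare-gene filter (3).
#' @slot minSeedSize merged seeds below this gene count are discarded (150).
#' @slot representativeTopN genes whose per-sample median forms the seed
#'   representative (30).
#' @slot quantifyTopK top core genes aggregated for MSP abundance (30).
#' @slot workingScale scale of the moments and residuals: \code{"sqrt"}
#'   (variance-stabilized, default) or \code{"raw"}.
#' @slot pnrDenominator \code{"alpha2"} (concordance-consistent, default) or
#'   \code{"alpha1"} (the literally printed variance weight).
#' @slot outlierCapForm \code{"adjusted"}: reject when |O| > 0.3 (|S'| - 5)
#'   (default); \code{"plain"}: reject when |O| > 0.3 |S'|.
#' @export
setClass("MspParams",
    slots = c(
        t = "numeric",
        pnrThreshold = "numeric",
        prThreshold = "numeric",
        maxOutlierFraction = "numeric",
        minSamples = "integer",
        minSeedSize = "integer",
        representativeTopN = "integer",
        quantifyTopK = "integer",
        workingScale = "character",
        pnrDenominator = "character",
        outlierCapForm = "character"))

setValidity("MspParams", function(object) {
    msg <- character()
    if (object@t <= 0) msg <- c(msg, "t must be positive")
    for (s in c("pnrThreshold", "prThreshold"))
        if (slot(object, s) < 0 || slot(object, s) > 1)
            msg <- c(msg, paste(s, "must lie in [0, 1]"))
    if (object@maxOutlierFraction <= 0 || object@maxOutlierFraction >= 1)
        msg <- c(msg, "maxOutlierFraction must lie in (0, 1)")
    for (s in c("minSamples", "minSeedSize", "representativeTopN",
                "quantifyTopK"))
        if (slot(object, s) < 1L)
            msg <- c(msg, paste(s, "must be a positive integer"))
    if (!object@workingScale %in% c("sqrt", "raw"))
        msg <- c(msg, "workingScale must be \"sqrt\" or \"raw\"")
    if (!object@pnrDenominator %in% c("alpha2", "alpha1"))
        msg <- c(msg, "pnrDenominator must be \"alpha2\" or \"alpha1\"")
    if (!object@outlierCapForm %in% c("adjusted", "plain"))
        msg <- c(msg, "outlierCapForm must be \"adjusted\" or \"plain\"")
    if (length(msg)) msg else TRUE
})

#' @rdname MspParams-class
#' @param t,pnrThreshold,prThreshold,maxOutlierFraction,minSamples,minSeedSize,
#'   representativeTopN,quantifyTopK,workingScale,pnrDenominator,outlierCapForm
#'   see the corresponding slots.
#' @return An \code{MspParams} object.
#' @examples
#' MspParams()
#' MspParams(minSeedSize = 50)
#' @export
MspParams <- function(t = 6, pnrThreshold = 0.8, prThreshold = 0.8,
                      maxOutlierFraction = 0.3, minSamples = 3L,
                      minSeedSize = 150L, representativeTopN = 30L,
                      quantifyTopK = 30L,
                      workingScale = c("sqrt", "raw"),
                      pnrDenominator = c("alpha2", "alpha1"),
                      outlierCapForm = c("adjusted", "plain")) {
    new("MspParams",
        t = as.numeric(t),
        pnrThreshold = as.numeric(pnrThreshold),
        prThreshold = as.numeric(prThreshold),
        maxOutlierFraction = as.numeric(maxOutlierFraction),
        minSamples = as.integer(minSamples),
        minSeedSize = as.integer(minSeedSize),
        representativeTopN = as.integer(representativeTopN),
        quantifyTopK = as.integer(quantifyTopK),
        workingScale = match.arg(workingScale),
        pnrDenominator = match.arg(pnrDenominator),
        outlierCapForm = match.arg(outlierCapForm))
}

setMethod("show", "MspParams", function(object) {
    cat("MspParams\n")
    cat(sprintf("  t=%g  pnr>%g  pr>%g  outlier cap %g (%s)\n",
                object@t, object@pnrThreshold, object@prThreshold,
                object@maxOutlierFraction, object@outlierCapForm))
    cat(sprintf("  minSamples=%d  minSeedSize=%d  topN=%d  topK=%d\n",
                object@minSamples, object@minSeedSize,
                object@representativeTopN, object@quantifyTopK))
    cat(sprintf("  working scale=%s  pnr denominator=%s\n",
                object@workingScale, object@pnrDenominator))
})

#' Comparison of two gene count profiles
#'
#' Full record of the pairwise comparison of an ordered gene pair (g1, g2):
#' the proportionality coefficient, the adjusted quantification thresholds,
#' the taxonomy of null counts, both measures of proportionality and the
#' inlier/outlier decomposition. Undefined quantities are \code{NA}.
#'
#' @slot alpha median-of-ratios proportionality coefficient (g2 over g1).
#' @slot t1,t2 quantification thresholds of g1 and g2 (raw count units).
#' @slot structuralZeros1,structuralZeros2 sample ids where g1 (resp. g2) is
#'   confidently absent: its count is zero while the partner gene exceeds its
#'   quantification threshold.
#' @slot undeterminedZeros sample ids with a zero that cannot be called.
#' @slot pnr non-robust proportionality measure on samples where both genes
#'   are detected.
#' @slot pr robust measure, computed on inliers after Tukey-fence rejection.
#' @slot residuals named working-scale residuals of samples above both
#'   quantification thresholds.
#' @slot outliers,inliers sample ids outside/inside the Tukey fences.
#' @seealso \code{\link{compareGeneProfiles}}
#' @export
setClass("GenePairComparison",
    slots = c(
        alpha = "numeric", t1 = "numeric", t2 = "numeric",
        structuralZeros1 = "character", structuralZeros2 = "character",
        undeterminedZeros = "character",
        pnr = "numeric", pr = "numeric",
        residuals = "numeric", outliers = "character",
        inliers = "character"))

setMethod("show", "GenePairComparison", function(object) {
    cat("GenePairComparison\n")
    cat(sprintf("  alpha=%.4g  t1=%.4g  t2=%.4g\n",
                object@alpha, object@t1, object@t2))
    cat(sprintf("  structural zeros: g1=%d g2=%d; undetermined=%d\n",
                length(object@structuralZeros1),
                length(object@structuralZeros2),
                length(object@undeterminedZeros)))
    cat(sprintf("  pnr=%.4g  pr=%.4g  (%d inliers, %d outliers)\n",
                object@pnr, object@pr,
                length(object@inliers), length(object@outliers)))
})

#' Seed of co-abundant, co-occurring genes
#'
#' An intermediate cluster of directly proportional genes, together with a
#' pseudo-gene profile (the representative) standing in for the seed in
#' seed-level comparisons.
#'
#' @slot seedId seed identifier.
#' @slot geneIds member gene identifiers.
#' @slot representative named per-sample raw pseudo-counts; may be empty
#'   before \code{\link{computeRepresentative}} has been run.
#' @export
setClass("GeneSeed",
    slots = c(seedId = "character", geneIds = "character",
              representative = "numeric"))

setValidity("GeneSeed", function(object) {
    if (length(object@geneIds) == 0L) "a seed must contain genes" else TRUE
})

setMethod("show", "GeneSeed", function(object) {
    cat(sprintf("GeneSeed %s: %d genes%s\n", object@seedId,
                length(object@geneIds),
                if (length(object@representative))
                    sprintf(", representative over %d samples",
                            length(object@representative)) else ""))
})

#' Metagenomic Species Pan-genome
#'
#' One reconstructed species: its core seed, all associated genes with their
#' class (core, accessory, shared core, shared accessory) and measures of
#' proportionality against the core representative, the core genes ordered by
#' decreasing pnr, and modules of co-occurring genes within each non-core
#' class.
#'
#' @slot mspId identifier (\code{msp_0001}, ... in core selection order).
#' @slot coreSeed the \linkS4class{GeneSeed} the MSP grew from.
#' @slot members \code{DataFrame} with columns \code{geneId}, \code{class},
#'   \code{pr}, \code{pnr}.
#' @slot coreOrder core-class gene ids sorted by decreasing pnr.
#' @slot modules \code{DataFrame} with columns \code{geneId}, \code{class},
#'   \code{moduleId} covering the non-core members.
#' @export
setClass("Msp",
    slots = c(mspId = "character", coreSeed = "GeneSeed",
              members = "DataFrame", coreOrder = "character",
              modules = "DataFrame"))

setMethod("show", "Msp", function(object) {
    cls <- table(factor(object@members$class,
                        levels = c("core", "accessory", "shared_core",
                                   "shared_accessory")))
    cat(sprintf("Msp %s: %d genes (%s)\n", object@mspId,
                nrow(object@members),
                paste(sprintf("%s=%d", names(cls), as.integer(cls)),
                      collapse = ", ")))
})

#' Specification of a simulated species pan-genome
#'
#' Parameters of the single-species count simulator: pan-genome composition,
#' gene length and accessory prevalence ranges, per-sample strain coverage and
#' read length. Defaults describe a virtual species with 1000 core and 6000
#' accessory genes sequenced across 200 samples.
#'
#' @slot nCore,nAccessory pan-genome composition.
#' @slot geneLengthRange gene length range, bp.
#' @slot prevalenceRange accessory-gene prevalence range (fractions).
#' @slot nSamples number of metagenomic samples.
#' @slot coverageRange per-sample strain sequencing coverage range (fold).
#' @slot readLength read length, bp.
#' @slot rngSeed integer seed driving all draws.
#' @export
setClass("PanGenomeSpec",
    slots = c(nCore = "integer", nAccessory = "integer",
              geneLengthRange = "numeric", prevalenceRange = "numeric",
              nSamples = "integer", coverageRange = "numeric",
              readLength = "numeric", rngSeed = "integer"))

setValidity("PanGenomeSpec", function(object) {
    msg <- character()
    if (object@nCore < 1L || object@nAccessory < 0L || object@nSamples < 1L)
        msg <- c(msg, "gene and sample counts must be positive")
    for (s in c("geneLengthRange", "prevalenceRange", "coverageRange")) {
        r <- slot(object, s)
        if (length(r) != 2L || any(r <= 0) || r[1L] > r[2L])
            msg <- c(msg, paste(s, "must be an ordered positive interval"))
    }
    if (any(object@prevalenceRange > 1))
        msg <- c(msg, "prevalenceRange must lie in (0, 1]")
    if (object@readLength <= 0)
        msg <- c(msg, "readLength must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname PanGenomeSpec-class
#' @param nCore,nAccessory,geneLengthRange,prevalenceRange,nSamples,
#'   coverageRange,readLength,rngSeed see the corresponding slots.
#' @return A \code{PanGenomeSpec}.
#' @examples
#' PanGenomeSpec(nCore = 200, nAccessory = 800, rngSeed = 1L)
#' @export
PanGenomeSpec <- function(nCore = 1000L, nAccessory = 6000L,
                          geneLengthRange = c(100, 5000),
                          prevalenceRange = c(0.025, 0.995),
                          nSamples = 200L, coverageRange = c(0.6, 20),
                          readLength = 100, rngSeed = 1L) {
    new("PanGenomeSpec",
        nCore = as.integer(nCore), nAccessory = as.integer(nAccessory),
        geneLengthRange = as.numeric(geneLengthRange),
        prevalenceRange = as.numeric(prevalenceRange),
        nSamples = as.integer(nSamples),
        coverageRange = as.numeric(coverageRange),
        readLength = as.numeric(readLength),
        rngSeed = as.integer(rngSeed))
}

setMethod("show", "PanGenomeSpec", function(object) {
    cat(sprintf(
        "PanGenomeSpec: %d core + %d accessory genes, %d samples, seed %d\n",
        object@nCore, object@nAccessory, object@nSamples, object@rngSeed))
})

#' Ground truth of a simulated pan-genome
#'
#' Everything needed to score a binning result against the simulation:
#' per-gene class, length and drawn prevalence, per-sample strain coverage,
#' the gene-by-sample presence matrix, and any injected outlier cells.
#'
#' @slot speciesId species label carried by every gene (named character).
#' @slot geneClass named \code{"core"}/\code{"accessory"} per gene.
#' @slot geneLength named gene lengths, bp.
#' @slot genePrevalence named drawn prevalence (NA for core genes).
#' @slot strainCoverage samples-by-strain coverage matrix (second column NA
#'   in samples carrying a single strain).
#' @slot presence logical genes-by-samples matrix (any strain carries gene).
#' @slot outlierCells \code{DataFrame} with columns \code{geneId},
#'   \code{sampleId}, \code{factor} for multiplicatively corrupted cells.
#' @export
setClass("PanGenomeTruth",
    slots = c(speciesId = "character", geneClass = "character",
              geneLength = "numeric", genePrevalence = "numeric",
              strainCoverage = "matrix", presence = "matrix",
              outlierCells = "DataFrame"))

setValidity("PanGenomeTruth", function(object) {
    msg <- character()
    n <- length(object@geneClass)
    if (nrow(object@presence) != n)
        msg <- c(msg, "presence matrix rows must match gene count")
    if (!all(object@geneClass %in% c("core", "accessory")))
        msg <- c(msg, "geneClass values must be core/accessory")
    core <- names(object@geneClass)[object@geneClass == "core"]
    if (length(core) && !all(object@presence[core, , drop = FALSE]))
        msg <- c(msg, "core genes must be present in every sample")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PanGenomeTruth", function(object) {
    cat(sprintf(
        "PanGenomeTruth: %d genes (%d core), %d samples, %d outlier cells\n",
        length(object@geneClass), sum(object@geneClass == "core"),
        ncol(object@presence), nrow(object@outlierCells)))
})
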