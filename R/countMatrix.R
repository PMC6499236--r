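#' @include AllGenerics.R
NULL

#' Read a gene count table
#'
#' Reads a tab-separated matrix of raw mapped-read counts with genes as rows
#' and metagenomic samples as columns. The first row is a header of sample
#' identifiers, the first column holds gene identifiers. Gzipped input is
#' accepted transparently.
#'
#' @param path path to a TSV (optionally gzip-compressed) file.
#' @return A \linkS4class{GeneCountMatrix} on the raw scale, with row and
#'   column order preserved from the file.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t4\t0", "g2\t6\t6"), tsv)
#' readCountTable(tsv)
#' @seealso \code{\link{writeCountTable}}
#' @importFrom data.table fread
#' @export
readCountTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    dt <- tryCatch(
        fread(path, sep = "\t", header = TRUE, fill = FALSE,
              data.table = FALSE, showProgress = FALSE),
        error = function(e) stop("parse error in ", path, ": ",
                                 conditionMessage(e), call. = FALSE),
        warning = function(w) stop("parse error in ", path, ": ",
                                   conditionMessage(w), call. = FALSE))
    if (ncol(dt) < 2L || nrow(dt) < 1L)
        stop("parse error in ", path,
             ": need a gene id column, at least one sample and one gene")
    ids <- as.character(dt[[1L]])
    if (anyDuplicated(ids))
        stop("validation error: duplicated gene id(s): ",
             paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
    vals <- dt[-1L]
    bad <- !vapply(vals, is.numeric, logical(1L))
    if (any(bad))
        stop("validation error: non-numeric counts in column(s) ",
             paste(names(vals)[bad][1:3], collapse = ", "))
    m <- as.matrix(vals)
    if (anyNA(m))
        stop("validation error: missing cells")
    if (any(m < 0))
        stop("validation error: negative counts")
    rownames(m) <- ids
    GeneCountMatrix(m, scale = "raw")
}

#' Write a gene count table
#'
#' Writes the same TSV dialect \code{\link{readCountTable}} reads: header of
#' sample ids, first column \code{gene_id}. A read-write-read round trip is
#' bit-exact for integer counts.
#'
#' @param M a \linkS4class{GeneCountMatrix}.
#' @param path output path (\code{.gz} suffix triggers compression).
#' @return \code{path}, invisibly.
#' @importFrom data.table fwrite data.table
#' @export
writeCountTable <- function(M, path) {
    stopifnot(is(M, "GeneCountMatrix"))
    dt <- data.table(gene_id = geneIds(M))
    dt <- cbind(dt, as.data.frame(counts(M)))
    fwrite(dt, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Discard rarely detected genes
#'
#' Keeps only genes whose raw count exceeds \code{t} (strictly) in at least
#' \code{minSamples} samples; rarer genes do not carry enough quantitative
#' information for profile comparison. The sample set and the relative gene
#' order are unchanged; the operation is idempotent.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @param t count threshold (default 6).
#' @param minSamples minimum number of samples strictly above \code{t}
#'   (default 3).
#' @return The filtered \linkS4class{GeneCountMatrix} (possibly with zero
#'   genes).
#' @examples
#' m <- matrix(c(7, 7, 7, 0, 6, 6, 6, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("kept", "dropped"), paste0("s", 1:4)))
#' geneIds(filterRareGenes(GeneCountMatrix(m)))
#' @export
filterRareGenes <- function(M, t = 6, minSamples = 3L) {
    stopifnot(is(M, "GeneCountMatrix"))
    if (countScale(M) != "raw")
        stop("filterRareGenes expects raw counts")
    keep <- rowSums(counts(M) > t) >= minSamples
    M[keep, ]
}

#' Per-sample sequencing depths
#'
#' Column sums of the raw count matrix, i.e. the number of mapped reads per
#' sample; used to depth-normalize counts before bin assignment and MSP
#' quantification. A zero-depth sample triggers a warning; its normalized
#' counts are defined as 0 downstream.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @return Named numeric vector of per-sample totals.
#' @export
sampleDepths <- function(M) {
    stopifnot(is(M, "GeneCountMatrix"))
    if (countScale(M) != "raw")
        stop("sampleDepths expects raw counts")
    d <- colSums(counts(M))
    if (any(d == 0))
        warning("sample(s) with zero mapped reads: ",
                paste(names(d)[d == 0], collapse = ", "))
    d
}

#' Depth-normalized counts
#'
#' Internal: counts divided by per-sample depth; zero-depth samples yield 0.
#' @noRd
.normalizedCounts <- function(m, depths) {
    d <- ifelse(depths == 0, Inf, depths)
    sweep(m, 2L, d, "/")
}

#' Square-root transform
#'
#' Element-wise square root of the raw counts, stabilizing the variance of
#' Poisson-like count data and reducing skewness. Guarded by the scale flag
#' so it is applied exactly once per pipeline run; all detection and
#' quantification thresholds remain defined on the raw scale.
#'
#' @param M a raw-scale \linkS4class{GeneCountMatrix}.
#' @return A \linkS4class{GeneCountMatrix} with scale \code{"sqrt"}.
#' @examples
#' m <- matrix(c(0, 1, 4, 9), 1, dimnames = list("g1", paste0("s", 1:4)))
#' counts(sqrtTransform(GeneCountMatrix(m)))
#' @export
sqrtTransform <- function(M) {
    stopifnot(is(M, "GeneCountMatrix"))
    if (countScale(M) != "raw")
        stop("sqrtTransform expects raw counts (already transformed?)")
    out <- M
    assay(out, "counts") <- sqrt(counts(M))
    out@countScale <- "sqrt"
    out
}

#' @importFrom SummarizedExperiment assay<-
NULL
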