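#' @include AllClasses.R
NULL

## Fast midpoint median (no NA handling; callers guarantee clean input).
.med <- function(v) {
    n <- length(v)
    if (n == 0L) return(NA_real_)
    v <- sort.int(unname(v), method = "quick")
    h <- n %/% 2L
    if (n %% 2L == 1L) v[h + 1L] else (v[h] + v[h + 1L]) / 2
}

## Lin-type concordance of v against a*u, population moments.
## Returns NA when fewer than 3 points or both profiles are constant.
.pnrFormula <- function(u, v, a, alpha2 = TRUE) {
    n <- length(u)
    if (n < 3L) return(NA_real_)
    mu <- sum(u) / n
    mv <- sum(v) / n
    du <- u - mu
    dv <- v - mv
    vu <- sum(du * du) / n
    vv <- sum(dv * dv) / n
    if (vu == 0 && vv == 0) return(NA_real_)
    cuv <- sum(du * dv) / n
    w <- if (alpha2) a * a else a
    2 * a * cuv / (w * vu + vv + (a * mu - mv)^2)
}

## Tukey fences from hinges (median-of-halves, median shared for odd n);
## stats::fivenum implements exactly this convention.
## A tolerance proportional to the residual magnitude keeps exactly
## proportional pairs (residuals ~ 1e-15 from rounding, IQR = 0) from being
## split by zero-width fences.
#' @importFrom stats fivenum
.tukeyFences <- function(r) {
    f <- fivenum(r)
    iqr <- f[4L] - f[2L]
    eps <- 1e-9 * max(1, abs(r))
    c(f[2L] - 1.5 * iqr - eps, f[4L] + 1.5 * iqr + eps)
}

## Complete pairwise comparison engine on plain vectors.
## x, y: raw counts; xs, ys: working-scale counts; p: list of unpacked params.
## needPr = FALSE stops after pnr/structural zeros (the seeding hot path).
.pairStats <- function(x, y, xs, ys, p, needPr = TRUE) {
    elig <- x >= p$t & y >= p$t
    out <- list(alpha = NA_real_, t1 = NA_real_, t2 = NA_real_,
                sz1 = logical(length(x)), sz2 = logical(length(x)),
                undet = logical(length(x)), sPrime = NULL,
                pnr = NA_real_, residIdx = integer(), resid = numeric(),
                outIdx = integer(), pr = NA_real_)
    if (!any(elig)) return(out)
    alpha <- .med(y[elig] / x[elig])
    if (!is.finite(alpha) || alpha <= 0) return(out)
    t1 <- max(p$t, p$t / alpha)
    t2 <- max(p$t, alpha * p$t)
    sz2 <- y == 0 & x >= t1          # g2 confidently absent
    sz1 <- x == 0 & y >= t2          # g1 confidently absent
    undet <- (x == 0 | y == 0) & !sz1 & !sz2
    sPrime <- x > 0 & y > 0
    out$alpha <- alpha; out$t1 <- t1; out$t2 <- t2
    out$sz1 <- sz1; out$sz2 <- sz2; out$undet <- undet
    out$sPrime <- sPrime
    a <- if (p$sqrtScale) sqrt(alpha) else alpha
    out$pnr <- .pnrFormula(xs[sPrime], ys[sPrime], a, p$alpha2)
    if (!needPr) return(out)
    residIdx <- which(x >= t1 & y >= t2)
    resid <- ys[residIdx] - a * xs[residIdx]
    out$residIdx <- residIdx
    out$resid <- resid
    outIdx <- integer()
    if (length(resid) >= 4L) {
        fen <- .tukeyFences(resid)
        outIdx <- residIdx[resid < fen[1L] | resid > fen[2L]]
    }
    out$outIdx <- outIdx
    nSp <- sum(sPrime)
    cap <- if (p$capAdjusted) p$maxOut * (nSp - 5) else p$maxOut * nSp
    if (length(outIdx) > cap) return(out)     # pr stays NA: too inconsistent
    inl <- sPrime
    inl[outIdx] <- FALSE
    out$pr <- .pnrFormula(xs[inl], ys[inl], a, p$alpha2)
    out
}

## Unpack an MspParams object once for use in tight loops.
.paramsList <- function(params) {
    list(t = params@t,
         pnrThr = params@pnrThreshold,
         prThr = params@prThreshold,
         maxOut = params@maxOutlierFraction,
         sqrtScale = params@workingScale == "sqrt",
         alpha2 = params@pnrDenominator == "alpha2",
         capAdjusted = params@outlierCapForm == "adjusted")
}

.workingScale <- function(x, p) if (p$sqrtScale) sqrt(x) else x

.sampleNames <- function(g) {
    if (is.null(names(g))) as.character(seq_along(g)) else names(g)
}

#' Estimate the coefficient of proportionality
#'
#' Robust median-of-ratios estimate of the scale alpha between two raw count
#' profiles, g2 = alpha * g1. Only samples where both genes reach the
#' detection threshold \code{t} contribute, which discards double zeros,
#' samples where only one gene is present (proportionality may hold in a
#' sample subset only) and low, scattered counts. For two copies of the same
#' genomic entity alpha approximates the gene length ratio.
#'
#' @param g1,g2 aligned raw count vectors.
#' @param t detection threshold (default 6).
#' @return The midpoint-median of the eligible ratios g2/g1, or \code{NA}
#'   when no sample has both counts at or above \code{t} (insufficient joint
#'   signal; the pair must not proceed to pnr/pr).
#' @examples
#' estimateAlpha(c(10, 20, 40, 0, 6), c(20, 40, 80, 12, 0))  # 2
#' @export
estimateAlpha <- function(g1, g2, t = 6) {
    stopifnot(length(g1) == length(g2), t > 0)
    elig <- g1 >= t & g2 >= t
    if (!any(elig)) return(NA_real_)
    .med(g2[elig] / g1[elig])
}

#' Adjusted quantification thresholds
#'
#' When alpha differs from 1 one gene yields systematically higher counts
#' than the other, so each gene gets its own quantification threshold:
#' \code{t1 = max(t, t/alpha)} for g1 and \code{t2 = max(t, alpha*t)} for g2.
#' Both are at least \code{t}, keeping the Poisson zero-misclassification
#' bound exp(-t) valid for structural-zero calls.
#'
#' @param alpha positive proportionality coefficient.
#' @param t base detection threshold (default 6).
#' @return Named numeric vector \code{c(t1 = ..., t2 = ...)}.
#' @examples
#' quantificationThresholds(0.75)  # t1 = 8, t2 = 6
#' @export
quantificationThresholds <- function(alpha, t = 6) {
    if (!is.finite(alpha) || alpha <= 0)
        stop("alpha must be a positive finite number")
    c(t1 = max(t, t / alpha), t2 = max(t, alpha * t))
}

#' Classify null counts
#'
#' A zero can be a true absence or a sampling/technical artefact. A gene's
#' zero in a sample is called a structural zero when the partner gene reaches
#' its quantification threshold there (the expected count was then high
#' enough that a present gene would almost surely have been detected);
#' otherwise the zero is undetermined.
#'
#' @param g1,g2 aligned raw count vectors (named by sample).
#' @param t1,t2 quantification thresholds of g1 and g2.
#' @return List with character vectors \code{structuralZeros1},
#'   \code{structuralZeros2} and \code{undeterminedZeros}; the three sets are
#'   disjoint and cover exactly the samples with at least one zero.
#' @examples
#' classifyZeros(c(s1 = 12, s2 = 0, s3 = 9, s4 = 0),
#'               c(s1 = 0, s2 = 9, s3 = 7, s4 = 3), t1 = 6, t2 = 6)
#' @export
classifyZeros <- function(g1, g2, t1, t2) {
    stopifnot(length(g1) == length(g2))
    nm <- .sampleNames(g1)
    sz2 <- g2 == 0 & g1 >= t1
    sz1 <- g1 == 0 & g2 >= t2
    undet <- (g1 == 0 | g2 == 0) & !sz1 & !sz2
    list(structuralZeros1 = nm[sz1],
         structuralZeros2 = nm[sz2],
         undeterminedZeros = nm[undet])
}

#' Non-robust measure of proportionality
#'
#' A modified Lin's concordance correlation coefficient assessing agreement
#' of g2 with alpha * g1, evaluated only on samples where both genes have
#' non-null counts so that proportionality restricted to a sample subset is
#' still detected. Unlike Pearson correlation a constant shift is penalized
#' through the location term of the denominator. With the default
#' \code{alpha2} denominator the measure equals 1 iff g2 = alpha * g1 exactly
#' on the evaluated samples. Moments are computed on the working scale
#' (square-root by default, with alpha entering as sqrt(alpha)).
#'
#' @param g1,g2 aligned raw count vectors.
#' @param alpha proportionality coefficient from \code{\link{estimateAlpha}}.
#' @param params an \linkS4class{MspParams} (working scale / denominator).
#' @return pnr in [-1, 1], or \code{NA} when fewer than 3 samples have both
#'   genes detected or both restricted profiles are constant.
#' @examples
#' g <- c(10, 25, 40, 80, 120)
#' measurePnr(g, 2 * g, alpha = 2)  # 1
#' @export
measurePnr <- function(g1, g2, alpha, params = MspParams()) {
    stopifnot(length(g1) == length(g2))
    if (!is.finite(alpha) || alpha <= 0) return(NA_real_)
    p <- .paramsList(params)
    sPrime <- g1 > 0 & g2 > 0
    if (sum(sPrime) < 3L) return(NA_real_)
    a <- if (p$sqrtScale) sqrt(alpha) else alpha
    .pnrFormula(.workingScale(g1[sPrime], p), .workingScale(g2[sPrime], p),
                a, p$alpha2)
}

#' Tukey-fence outlier detection on residuals
#'
#' Flags samples whose proportionality residual falls outside
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with quartiles computed as Tukey hinges
#' (median of each half, the median belonging to both halves for odd counts).
#' Residuals exist only for samples above both quantification thresholds;
#' eligible samples without a residual are never outliers. Fewer than 4
#' residuals leave the fences ill-defined and no outlier is called.
#'
#' @param residuals named numeric vector of residuals.
#' @param eligible sample ids allowed to be flagged (the set with both genes
#'   detected); defaults to all residual samples.
#' @return Character vector of outlier sample ids.
#' @examples
#' r <- c(a = -1, b = 0, c = 0, d = 1, e = 10)
#' tukeyOutliers(r)  # "e"
#' @export
tukeyOutliers <- function(residuals, eligible = names(residuals)) {
    if (length(residuals) < 4L) return(character())
    nm <- .sampleNames(residuals)
    fen <- .tukeyFences(as.numeric(residuals))
    out <- nm[residuals < fen[1L] | residuals > fen[2L]]
    if (is.null(eligible)) out else intersect(out, eligible)
}

#' Robust measure of proportionality
#'
#' Runs the full pairwise pipeline: estimate alpha, derive quantification
#' thresholds, compute working-scale residuals on samples above both
#' thresholds, reject Tukey-fence outliers, and evaluate the concordance
#' formula on the remaining inliers with the same alpha. Samples with
#' inconsistent counts (e.g. carrying several strains of a species) are
#' thereby excised. When too many samples are outliers the association is
#' rejected as inconsistent and \code{NA} is returned (default cap:
#' |O| > 0.3 (|S'| - 5)).
#'
#' @param g1,g2 aligned raw count vectors.
#' @param params an \linkS4class{MspParams}.
#' @return pr in [-1, 1], or \code{NA} (alpha not estimable, fewer than 3
#'   usable samples, or outlier cap exceeded).
#' @examples
#' g <- c(10, 25, 40, 80, 120, 30, 55, 70, 90, 15)
#' noisy <- 2 * g; noisy[3] <- noisy[3] * 4
#' measurePr(g, noisy)   # 1: the corrupted sample is excised
#' measurePnr(g, noisy, alpha = 2)  # < 1
#' @export
measurePr <- function(g1, g2, params = MspParams()) {
    stopifnot(length(g1) == length(g2))
    p <- .paramsList(params)
    st <- .pairStats(g1, g2, .workingScale(g1, p), .workingScale(g2, p),
                     p, needPr = TRUE)
    st$pr
}

#' Compare two gene count profiles
#'
#' Runs the complete ordered-pair comparison and returns every intermediate:
#' alpha, thresholds, the zero taxonomy, pnr, residuals, Tukey outliers,
#' inliers and pr, as a \linkS4class{GenePairComparison}.
#'
#' @param g1,g2 aligned raw count vectors, named by sample id.
#' @param params an \linkS4class{MspParams}.
#' @return A \linkS4class{GenePairComparison}.
#' @examples
#' g <- c(10, 25, 40, 80, 120, 0, 55, 70, 90, 15)
#' names(g) <- paste0("s", 1:10)
#' compareGeneProfiles(g, 2 * g)
#' @export
compareGeneProfiles <- function(g1, g2, params = MspParams()) {
    stopifnot(length(g1) == length(g2))
    nm <- .sampleNames(g1)
    p <- .paramsList(params)
    st <- .pairStats(g1, g2, .workingScale(g1, p), .workingScale(g2, p),
                     p, needPr = TRUE)
    resid <- st$resid
    names(resid) <- nm[st$residIdx]
    inliers <- character()
    if (!is.null(st$sPrime)) {
        inl <- st$sPrime
        inl[st$outIdx] <- FALSE
        inliers <- nm[inl]
    }
    new("GenePairComparison",
        alpha = st$alpha, t1 = st$t1, t2 = st$t2,
        structuralZeros1 = nm[st$sz1], structuralZeros2 = nm[st$sz2],
        undeterminedZeros = nm[st$undet],
        pnr = st$pnr, pr = st$pr,
        residuals = resid, outliers = nm[st$outIdx], inliers = inliers)
}
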