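# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity with the most literal,
# loop-based interpretation so they share no code with the package.

oracleMedian <- function(v) {
    s <- sort(v)
    n <- length(s)
    if (n == 0L) return(NA_real_)
    if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# materialize the eligible ratio list, sort it, take the midpoint median
oracleAlpha <- function(x, y, t = 6) {
    r <- numeric()
    for (i in seq_along(x))
        if (x[i] >= t && y[i] >= t) r <- c(r, y[i] / x[i])
    oracleMedian(r)
}

# literal term-by-term evaluation of the concordance formula
oraclePnr <- function(g1, g2, alpha, sqrtScale = TRUE, alpha2 = TRUE) {
    keep <- which(g1 > 0 & g2 > 0)
    if (length(keep) < 3L) return(NA_real_)
    u <- g1[keep]; v <- g2[keep]; a <- alpha
    if (sqrtScale) { u <- sqrt(u); v <- sqrt(v); a <- sqrt(alpha) }
    n <- length(u)
    mu <- 0; mv <- 0
    for (i in seq_len(n)) { mu <- mu + u[i] / n; mv <- mv + v[i] / n }
    vu <- 0; vv <- 0; cv <- 0
    for (i in seq_len(n)) {
        vu <- vu + (u[i] - mu)^2 / n
        vv <- vv + (v[i] - mv)^2 / n
        cv <- cv + (u[i] - mu) * (v[i] - mv) / n
    }
    if (vu == 0 && vv == 0) return(NA_real_)
    w <- if (alpha2) a^2 else a
    2 * a * cv / (w * vu + vv + (a * mu - mv)^2)
}

# quartiles as medians of the lower/upper halves (median shared for odd n),
# strict Tukey fences; returns indices of outliers
oracleTukeyIdx <- function(r) {
    n <- length(r)
    if (n < 4L) return(integer())
    s <- sort(r)
    q1 <- oracleMedian(s[seq_len(ceiling(n / 2))])
    q3 <- oracleMedian(s[(floor(n / 2) + 1L):n])
    iqr <- q3 - q1
    which(r < q1 - 1.5 * iqr | r > q3 + 1.5 * iqr)
}

# literal replay of the greedy centroid procedure on a sorted pair list
oracleGreedy <- function(pairList) {
    seeds <- list()
    pl <- pairList
    while (nrow(pl) > 0L) {
        cen <- c(pl$gene1[1L], pl$gene2[1L])
        rel <- pl$gene1 %in% cen | pl$gene2 %in% cen
        members <- sort(unique(c(cen, pl$gene1[rel], pl$gene2[rel])))
        seeds[[length(seeds) + 1L]] <- members
        keep <- !(pl$gene1 %in% members | pl$gene2 %in% members)
        pl <- pl[keep, , drop = FALSE]
    }
    seeds
}

# independent three-stage representative: overall median, rank by pnr
# against it, median of the topN best genes
oracleRepresentative <- function(m, topN = 30L, sqrtScale = TRUE) {
    stage1 <- apply(m, 2L, oracleMedian)
    if (nrow(m) <= topN) return(apply(m, 2L, oracleMedian))
    pnr <- vapply(seq_len(nrow(m)), function(i) {
        a <- oracleAlpha(stage1, m[i, ])
        if (is.na(a)) -Inf else oraclePnr(stage1, m[i, ], a, sqrtScale)
    }, numeric(1L))
    top <- order(-pnr, rownames(m))[seq_len(topN)]
    apply(m[top, , drop = FALSE], 2L, oracleMedian)
}

# quick GeneCountMatrix from a plain matrix, generating ids when missing
makeGcm <- function(m, genes = NULL, samples = NULL) {
    if (is.null(rownames(m)))
        rownames(m) <- if (is.null(genes))
            sprintf("g%03d", seq_len(nrow(m))) else genes
    if (is.null(colnames(m)))
        colnames(m) <- if (is.null(samples))
            sprintf("s%03d", seq_len(ncol(m))) else samples
    GeneCountMatrix(m)
}

# family of exactly proportional integer profiles (integer multiples of a
# shared base), useful where pnr must be exactly 1
propFamily <- function(ids, base, mult = seq_along(ids)) {
    m <- t(vapply(mult, function(k) k * base, numeric(length(base))))
    rownames(m) <- ids
    colnames(m) <- sprintf("s%03d", seq_along(base))
    m
}

smallParams <- function(...) MspParams(minSeedSize = 2L, ...)
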