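test_that("bin assignment uses depth-normalized counts with a first-sample tie rule", {
    # normalization flips the raw argmax
    m <- matrix(c(10, 18), 1, dimnames = list("g1", c("s1", "s2")))
    expect_equal(assignBins(GeneCountMatrix(m), depths = c(s1 = 100, s2 = 200)),
                 c(g1 = "s1"))
    # equal normalized counts -> first sample in column order
    tie <- matrix(c(5, 10), 1, dimnames = list("g1", c("s1", "s2")))
    expect_equal(assignBins(GeneCountMatrix(tie), depths = c(s1 = 50, s2 = 100)),
                 c(g1 = "s1"))

    withr::with_seed(43, {
        m2 <- matrix(rpois(60 * 8, 20), 60, 8)
        rownames(m2) <- sprintf("g%02d", 1:60)
        colnames(m2) <- sprintf("s%d", 1:8)
    })
    M <- GeneCountMatrix(m2)
    d <- sampleDepths(M)
    bins <- assignBins(M)
    for (i in seq_len(nrow(m2))) {
        norm <- m2[i, ] / d
        best <- which(norm == max(norm))[1L]
        expect_identical(unname(bins[rownames(m2)[i]]), colnames(m2)[best])
    }
})

test_that("the pair list keeps proportional co-occurring pairs, sorted by pnr", {
    base <- c(10, 22, 35, 60, 105, 44, 78, 51, 93, 12)
    m <- propFamily(c("a", "b", "c"), base, mult = c(1, 2, 3))
    pl <- buildPairList(makeGcm(m))
    expect_equal(nrow(pl), 3L)
    expect_true(all(abs(pl$pnr - 1) < 1e-12))
    expect_equal(pl$gene1, c("a", "a", "b"))  # pnr ties broken by gene id
    expect_equal(pl$gene2, c("b", "c", "c"))

    # a structural zero suppresses the pair regardless of pnr
    m2 <- rbind(m, d = 2 * base)
    m2["d", 1] <- 0   # d absent where a,b,c are strong
    pl2 <- buildPairList(makeGcm(m2))
    expect_false(any(pl2$gene1 == "d" | pl2$gene2 == "d"))
})

test_that("the pair list equals a brute-force all-pairs evaluation", {
    sim <- simulateCounts(PanGenomeSpec(nCore = 12, nAccessory = 18,
                                        nSamples = 25, rngSeed = 17L))
    M <- filterRareGenes(sim$matrix)
    pl <- buildPairList(M)
    m <- counts(M)
    ids <- rownames(m)
    got <- list()
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
        x <- m[i, ]; y <- m[j, ]
        a <- oracleAlpha(x, y)
        if (is.na(a)) next
        pnr <- oraclePnr(x, y, a)
        tt <- quantificationThresholds(a)
        sz <- sum(y == 0 & x >= tt["t1"]) + sum(x == 0 & y >= tt["t2"])
        if (!is.na(pnr) && pnr > 0.8 && sz == 0)
            got[[length(got) + 1L]] <- data.frame(
                gene1 = min(ids[i], ids[j]), gene2 = max(ids[i], ids[j]),
                pnr = pnr)
    }
    oracle <- do.call(rbind, got)
    oracle <- oracle[order(-oracle$pnr, oracle$gene1, oracle$gene2), ]
    rownames(oracle) <- rownames(pl) <- NULL
    expect_equal(pl, oracle, tolerance = 1e-12)
})

test_that("greedy seeding partitions paired genes around pnr centroids", {
    pl <- data.frame(gene1 = c("a", "a", "d"), gene2 = c("b", "c", "e"),
                     pnr = c(1.0, 0.9, 0.85), stringsAsFactors = FALSE)
    seeds <- greedySeedBin(pl)
    expect_length(seeds, 2L)
    expect_equal(seedGenes(seeds[[1]]), c("a", "b", "c"))
    expect_equal(seedGenes(seeds[[2]]), c("d", "e"))

    single <- greedySeedBin(data.frame(gene1 = "x", gene2 = "y", pnr = 0.9))
    expect_length(single, 1L)
    expect_equal(seedGenes(single[[1]]), c("x", "y"))
    expect_length(greedySeedBin(pl[0, ]), 0L)

    # procedural oracle on a simulated bin
    sim <- simulateCounts(PanGenomeSpec(nCore = 15, nAccessory = 25,
                                        nSamples = 20, rngSeed = 19L))
    plSim <- buildPairList(filterRareGenes(sim$matrix))
    expect_equal(lapply(greedySeedBin(plSim), seedGenes),
                 oracleGreedy(plSim))
})

test_that("the representative is the staged median pseudo-gene", {
    m <- rbind(a = c(2, 4), b = c(4, 8), c = c(6, 100))
    colnames(m) <- c("s1", "s2")
    expect_equal(computeRepresentative(makeGcm(m), c("a", "b", "c")),
                 c(s1 = 4, s2 = 8))

    # a small exactly proportional seed: representative proportional to all
    base <- c(8, 19, 33, 47, 62, 90, 12, 25, 71, 55)
    fam <- propFamily(sprintf("g%02d", 1:5), base)
    rep5 <- computeRepresentative(makeGcm(fam), rownames(fam))
    expect_equal(unname(rep5 / base), rep(3, length(base)))  # median multiplier

    # 60-gene seed goes through the top-N ranking stage
    withr::with_seed(47, {
        mult <- sample(1:9, 60, replace = TRUE)
        noise <- matrix(rpois(60 * 12, 2), 60, 12)
    })
    big <- propFamily(sprintf("g%02d", 1:60), c(20, 45, 80, 120, 33, 66,
                                                95, 140, 52, 75, 28, 110),
                      mult = mult) + noise
    G <- makeGcm(big)
    expect_equal(computeRepresentative(G, rownames(big), topN = 30),
                 oracleRepresentative(counts(G), topN = 30),
                 tolerance = 1e-12)
})

test_that("merging unifies split proportional seeds and applies the size filter", {
    base <- c(30, 55, 78, 120, 41, 95, 63, 88, 19, 140)
    fam <- propFamily(sprintf("g%02d", 1:8), base)
    G <- makeGcm(fam)
    p <- smallParams()
    mk <- function(id, genes) new("GeneSeed", seedId = id, geneIds = genes,
        representative = computeRepresentative(G, genes, params = p))
    s1 <- mk("seed_a", sprintf("g%02d", 1:4))
    s2 <- mk("seed_b", sprintf("g%02d", 5:8))
    merged <- mergeSeeds(list(s1, s2), G, p)
    expect_length(merged, 1L)
    expect_equal(seedGenes(merged[[1]]), sprintf("g%02d", 1:8))

    # unrelated abundance patterns stay apart
    withr::with_seed(53, other <- matrix(rpois(4 * 10, 40), 4, 10,
        dimnames = list(sprintf("h%02d", 1:4), colnames(fam))))
    G2 <- makeGcm(rbind(fam, other))
    s3 <- new("GeneSeed", seedId = "seed_c",
              geneIds = sprintf("h%02d", 1:4),
              representative = computeRepresentative(G2, sprintf("h%02d", 1:4),
                                                     params = p))
    merged2 <- mergeSeeds(list(mk("seed_a", sprintf("g%02d", 1:8)), s3),
                          G2, p)
    expect_length(merged2, 2L)

    # minSeedSize semantics
    expect_length(mergeSeeds(list(s3), G2, MspParams(minSeedSize = 5L)), 0L)
    expect_length(mergeSeeds(list(s3), G2, MspParams(minSeedSize = 4L)), 1L)
})

test_that("seed creation is deterministic and partitions genes", {
    sim <- simulateCounts(PanGenomeSpec(nCore = 40, nAccessory = 60,
                                        nSamples = 30, rngSeed = 59L))
    M <- filterRareGenes(sim$matrix)
    p <- MspParams(minSeedSize = 5L)
    seeds1 <- createSeeds(M, p)
    seeds2 <- createSeeds(M, p)
    expect_identical(lapply(seeds1, seedGenes), lapply(seeds2, seedGenes))
    expect_identical(lapply(seeds1, representative),
                     lapply(seeds2, representative))
    genes <- unlist(lapply(seeds1, seedGenes))
    expect_equal(anyDuplicated(genes), 0L)
})

test_that("core genes of a single-species simulation concentrate in one seed", {
    # A core gene alone in its bin (its noisy argmax sample attracted no
    # other seedable gene) stays unseeded until MSP association, so the seed
    # holds the large majority of core genes, never a split of them.
    sim <- simulateCounts(PanGenomeSpec(nCore = 60, nAccessory = 90,
                                        nSamples = 40, rngSeed = 61L))
    M <- filterRareGenes(sim$matrix)
    seeds <- createSeeds(M, MspParams(minSeedSize = 10L))
    core <- intersect(names(sim$truth@geneClass)[
        sim$truth@geneClass == "core"], geneIds(M))
    hits <- vapply(seeds, function(s) sum(core %in% seedGenes(s)),
                   integer(1L))
    expect_equal(sum(hits > 0), 1L)              # no splitting across seeds
    expect_gte(max(hits), 0.8 * length(core))    # and most core genes seeded
})
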