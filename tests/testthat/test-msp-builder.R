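# Two independent species across the same samples: simulate each separately
# (independent coverages) and stack the gene rows with species prefixes.
makeTwoSpecies <- function(seedA = 67L, seedB = 71L, nSamples = 35L) {
    specA <- PanGenomeSpec(nCore = 30, nAccessory = 40, nSamples = nSamples,
                           rngSeed = seedA)
    specB <- PanGenomeSpec(nCore = 25, nAccessory = 35, nSamples = nSamples,
                           rngSeed = seedB)
    a <- simulateCounts(specA)
    b <- simulateCounts(specB)
    prefix <- function(sim, sp) {
        m <- counts(sim$matrix)
        rownames(m) <- paste0(sp, "_", rownames(m))
        tr <- sim$truth
        for (s in c("speciesId", "geneClass", "geneLength", "genePrevalence"))
            names(slot(tr, s)) <- rownames(m)
        tr@speciesId[] <- sp
        rownames(tr@presence) <- rownames(m)
        list(m = m, truth = tr)
    }
    A <- prefix(a, "spA"); B <- prefix(b, "spB")
    truth <- new("PanGenomeTruth",
                 speciesId = c(A$truth@speciesId, B$truth@speciesId),
                 geneClass = c(A$truth@geneClass, B$truth@geneClass),
                 geneLength = c(A$truth@geneLength, B$truth@geneLength),
                 genePrevalence = c(A$truth@genePrevalence,
                                    B$truth@genePrevalence),
                 strainCoverage = A$truth@strainCoverage,
                 presence = rbind(A$truth@presence, B$truth@presence),
                 outlierCells = S4Vectors::DataFrame(geneId = character(),
                                                     sampleId = character(),
                                                     factor = numeric()))
    list(matrix = GeneCountMatrix(rbind(A$m, B$m)), truth = truth)
}

test_that("the largest of a group of related seeds becomes the core seed", {
    base <- c(40, 75, 110, 22, 95, 60, 130, 18, 88, 55)
    G <- makeGcm(propFamily(sprintf("g%02d", 1:9), base))
    p <- smallParams()
    mk <- function(id, genes) new("GeneSeed", seedId = id, geneIds = genes,
        representative = computeRepresentative(G, genes, params = p))
    big <- mk("seed_big", sprintf("g%02d", 1:4))
    rel <- mk("seed_rel", sprintf("g%02d", 5:7))    # proportional to big
    cores <- selectCoreSeeds(list(rel, big), p)
    expect_equal(vapply(cores, seedId, ""), "seed_big")

    # mutually unrelated seeds are all cores, in decreasing-size order
    withr::with_seed(73, other <- matrix(rpois(30, 60), 3, 10,
        dimnames = list(c("h1", "h2", "h3"),
                        sprintf("s%03d", 1:10))))
    G2 <- makeGcm(rbind(propFamily(sprintf("g%02d", 1:4), base), other))
    un1 <- mk("seed_a", sprintf("g%02d", 1:4))
    un2 <- new("GeneSeed", seedId = "seed_b", geneIds = c("h1", "h2", "h3"),
               representative = computeRepresentative(G2, c("h1", "h2", "h3"),
                                                      params = p))
    cores2 <- selectCoreSeeds(list(un2, un1), p)
    expect_equal(vapply(cores2, seedId, ""), c("seed_a", "seed_b"))
})

test_that("a two-species matrix yields exactly two cores and clean MSPs", {
    two <- makeTwoSpecies()
    M <- filterRareGenes(two$matrix)
    p <- MspParams(minSeedSize = 10L)
    seeds <- createSeeds(M, p)
    cores <- selectCoreSeeds(seeds, p)
    expect_length(cores, 2L)
    sp <- vapply(cores, function(s)
        unique(two$truth@speciesId[seedGenes(s)]), character(1L))
    expect_setequal(sp, c("spA", "spB"))

    msps <- assembleMsps(cores, M, p)
    expect_length(msps, 2L)
    expect_equal(vapply(msps, mspId, ""), c("msp_0001", "msp_0002"))
    g1 <- mspMembers(msps[[1]])$geneId
    g2 <- mspMembers(msps[[2]])$geneId
    expect_length(intersect(g1, g2), 0L)
    # members are overwhelmingly from one species each
    sc <- scoreAgainstTruth(msps, two$truth, M)
    expect_true(all(sc$perMsp$precision >= 0.95))
    expect_setequal(sc$perMsp$dominant_species, c("spA", "spB"))
})

test_that("genes associate with the core of greatest pr and respect the cap", {
    sim <- simulateCounts(PanGenomeSpec(nCore = 40, nAccessory = 40,
                                        nSamples = 30, rngSeed = 79L))
    M <- filterRareGenes(sim$matrix)
    p <- MspParams(minSeedSize = 10L)
    cores <- selectCoreSeeds(createSeeds(M, p), p)
    expect_length(cores, 1L)
    assoc <- associateGenes(cores, M, p)[[1]]
    # the core's own seed genes associate with pr ~ 1
    own <- intersect(seedGenes(cores[[1]]), assoc$geneId)
    expect_equal(sort(own), sort(seedGenes(cores[[1]])))
    expect_gte(min(assoc$pr[assoc$geneId %in% own]), 0.95)
    expect_true(all(assoc$pr > p@prThreshold))

    # a gene with 40% two-sided corruption has undefined pr -> unassociated
    rep0 <- representative(cores[[1]])
    bad <- round(2 * rep0)
    up <- seq(1, 30, by = 6); dn <- seq(4, 30, by = 6)
    bad[up] <- bad[up] * 4; bad[dn] <- round(bad[dn] / 4)
    expect_true(is.na(measurePr(rep0, bad, p)))
})

test_that("structural-zero patterns drive the four gene classes", {
    mkCmp <- function(g1, g2) {
        names(g1) <- names(g2) <- sprintf("s%02d", seq_along(g1))
        compareGeneProfiles(g1, g2)
    }
    core <- c(50, 80, 120, 40, 95, 60, 150, 70, 110, 55)
    # no structural zeros on either side
    expect_equal(classifyGene(mkCmp(core, 2 * core)), "core")
    # gene absent in some species-positive samples, never outside
    acc <- 2 * core; acc[c(2, 5, 8)] <- 0
    expect_equal(classifyGene(mkCmp(core, acc)), "accessory")
    # gene present everywhere the species is, plus where it is not
    coreGaps <- core; coreGaps[c(3, 7)] <- 0
    shc <- 2 * core
    expect_equal(classifyGene(mkCmp(coreGaps, shc)), "shared_core")
    # both patterns
    sha <- 2 * core; sha[5] <- 0; sha[3] <- 2 * core[3]
    expect_equal(classifyGene(mkCmp(coreGaps, sha)), "shared_accessory")
})

test_that("every associated gene gets exactly one class; core order is by pnr", {
    sim <- simulateCounts(PanGenomeSpec(nCore = 40, nAccessory = 60,
                                        nSamples = 30, rngSeed = 83L))
    M <- filterRareGenes(sim$matrix)
    p <- MspParams(minSeedSize = 10L)
    msps <- runPipeline(M, params = p, verbose = FALSE)$msps
    expect_length(msps, 1L)
    mem <- mspMembers(msps[[1]])
    expect_equal(anyDuplicated(mem$geneId), 0L)
    expect_true(all(mem$class %in% c("core", "accessory", "shared_core",
                                     "shared_accessory")))
    expect_true(all(mem$pr > p@prThreshold))
    ord <- coreOrder(msps[[1]])
    expect_setequal(ord, mem$geneId[mem$class == "core"])
    pnrOrd <- mem$pnr[match(ord, mem$geneId)]
    expect_true(all(diff(pnrOrd) <= 1e-12))
    # the core seed's own top genes are classified core
    top <- utils::head(seedGenes(msps[[1]]@coreSeed), 10)
    expect_true(all(mem$class[match(top, mem$geneId)] == "core"))
})

test_that("sample relabeling permutes the classification, nothing else", {
    sim <- simulateCounts(PanGenomeSpec(nCore = 25, nAccessory = 35,
                                        nSamples = 24, rngSeed = 89L))
    M <- filterRareGenes(sim$matrix)
    p <- MspParams(minSeedSize = 8L)
    res1 <- runPipeline(M, params = p, verbose = FALSE)
    withr::with_seed(97, perm <- sample(ncol(M)))
    Mp <- GeneCountMatrix(counts(M)[, perm])
    res2 <- runPipeline(Mp, params = p, verbose = FALSE)
    cls1 <- with(as.data.frame(mspMembers(res1$msps[[1]])),
                 structure(class, names = geneId))
    cls2 <- with(as.data.frame(mspMembers(res2$msps[[1]])),
                 structure(class, names = geneId))
    expect_identical(cls1[sort(names(cls1))], cls2[sort(names(cls2))])
    expect_equal(res2$abundance[, colnames(res1$abundance), drop = FALSE],
                 res1$abundance)
})

test_that("co-occurring proportional accessory genes cluster into modules", {
    base <- c(60, 95, 140, 75, 120, 88, 47, 105, 66, 130, 52, 99)
    pres1 <- c(1, 1, 1, 0, 0, 1, 1, 0, 1, 1, 0, 1)   # operon block
    pres2 <- c(0, 0, 1, 1, 1, 0, 0, 1, 0, 0, 1, 0)   # disjoint pattern
    m <- rbind(op1 = 2 * base * pres1, op2 = 3 * base * pres1,
               lone1 = 2 * base * pres2, lone2 = 5 * base * pres2)
    # make the two "lone" genes non-proportional to each other
    m["lone2", c(4, 11)] <- m["lone2", c(4, 11)] + c(400, 700)
    G <- makeGcm(m)
    mods <- clusterModules(G, rownames(m), smallParams())
    expect_equal(sort(mods$geneId), sort(rownames(m)))
    byMod <- split(mods$geneId, mods$moduleId)
    sizes <- sort(lengths(byMod), decreasing = TRUE)
    expect_equal(unname(sizes), c(2L, 1L, 1L))
    expect_setequal(byMod[[names(sizes)[1]]], c("op1", "op2"))
})

test_that("MSP abundance tracks strain coverage and normalization", {
    sim <- simulateCounts(PanGenomeSpec(nCore = 40, nAccessory = 60,
                                        nSamples = 30, rngSeed = 101L))
    M <- filterRareGenes(sim$matrix)
    res <- runPipeline(M, params = MspParams(minSeedSize = 10L),
                       verbose = FALSE)
    ab <- res$abundance
    expect_equal(dim(ab), c(1L, 30L))

    # against true coverage: a lone species dominates its own sample depth,
    # so depth-normalized abundance is only informative relative to the rest
    # of the community; emulate that with constant background genes
    bg <- matrix(2e5, 5, ncol(M),
                 dimnames = list(sprintf("bg%d", 1:5), sampleIds(M)))
    Mbg <- GeneCountMatrix(rbind(counts(M), bg))
    abBg <- quantifyMsps(res$msps, Mbg)
    expect_gte(cor(abBg[1, ], sim$truth@strainCoverage[, "strain1"]), 0.95)

    # doubling all counts of one sample leaves its abundance unchanged
    m2 <- counts(M); m2[, 5] <- 2 * m2[, 5]
    ab2 <- quantifyMsps(res$msps, GeneCountMatrix(m2))
    expect_equal(ab2[1, 5], ab[1, 5], tolerance = 1e-12)

    # a sample without the species has abundance zero
    m3 <- counts(M); m3[, 3] <- 0; m3[1, 3] <- 50   # keep nonzero depth
    ab3 <- suppressWarnings(quantifyMsps(res$msps, GeneCountMatrix(m3)))
    expect_equal(unname(ab3[1, 3]), 0)
})
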