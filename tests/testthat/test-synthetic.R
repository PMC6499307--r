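## Desk-scale configs keep these tests fast; the full default conditions are
## exercised in the acceptance suite.

test_that("identical config yields byte-identical outputs", {
    cfg <- syntheticConfig(genomeLength = 1.5e5, islandCount = 4L,
                           nSitesIsland = 8L, nSitesOutside = 16L,
                           nSitesGained = 1L, dmrCount = 4L,
                           fragmentsPerReplicate = 5000L, nTranscripts = 60L,
                           tadWidth = 30000L, seed = 3L)
    a <- generateGenome(cfg); b <- generateGenome(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$sites, b$sites)
    mA <- simulateMethylomes(a, cfg); mB <- simulateMethylomes(b, cfg)
    expect_identical(mcols(methRecords(mA$wt))$ratio,
                     mcols(methRecords(mB$wt))$ratio)
    fA <- simulateNucleosomeFragments(a, cfg, "WT", 1)
    fB <- simulateNucleosomeFragments(b, cfg, "WT", 1)
    expect_identical(fragments(fA), fragments(fB))
    ## and on disk: the written FASTA is byte-identical
    d1 <- tempfile(); d2 <- tempfile()
    simA <- simulateEpigenome(cfg, outdir = d1)
    simB <- simulateEpigenome(cfg, outdir = d2)
    expect_identical(readLines(file.path(d1, "genome.fa")),
                     readLines(file.path(d2, "genome.fa")))
    expect_identical(readLines(file.path(d1, "methylation_dko.tsv")),
                     readLines(file.path(d2, "methylation_dko.tsv")))
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("island CpG rate lands near the requested rate; degenerate configs work", {
    cfg <- syntheticConfig(genomeLength = 1e6, islandCpgRate = 0.10,
                           backgroundCpgRate = 0.01, seed = 2L)
    b <- generateGenome(cfg)
    cgRate <- function(gr) {
        n <- sum(vapply(seq_along(gr), function(i) {
            sq <- as.character(subseq(b$genome[[as.character(seqnames(gr)[i])]],
                                      start(gr)[i], end(gr)[i]))
            lengths(regmatches(sq, gregexpr("CG", sq, fixed = TRUE)))
        }, numeric(1)))
        n / sum(width(gr))
    }
    expect_gt(cgRate(b$islands), 0.08)
    expect_lt(cgRate(b$islands), 0.12)
    ## no islands: background rate only, empty island set
    cfg0 <- syntheticConfig(genomeLength = 1e5, islandCount = 0L,
                            nSitesIsland = 0L, nSitesOutside = 10L, seed = 2L)
    b0 <- generateGenome(cfg0)
    expect_length(b0$islands, 0)
    sq <- as.character(b0$genome[[1]])
    bgRate <- lengths(regmatches(sq, gregexpr("CG", sq, fixed = TRUE))) / nchar(sq)
    expect_lt(abs(bgRate - 0.01), 0.004)
    ## island placement overflow is an explicit error at validation
    expect_error(syntheticConfig(genomeLength = 5e4, islandCount = 25L,
        islandLength = 2000L, seed = 1L), "genomeLength")
})

test_that("methylation spreading follows the exponential decay closed form", {
    cfg <- syntheticConfig(genomeLength = 4e5, islandCount = 0L,
                           nSitesIsland = 0L, nSitesOutside = 40L,
                           nSitesGained = 0L, backgroundCpgRate = 0.02,
                           methBackgroundWt = 0.2, methBackgroundDko = 0.7,
                           spreadingAmplitude = 0.5, spreadingDecayLength = 500,
                           dmrCount = 0L, coverageMean = 200,
                           lossBase = 20, lossDensitySlope = 0, seed = 8L)
    b <- generateGenome(cfg)           # lossBase 20 => every site lost
    expect_true(all(mcols(b$sites)$lost))
    meth <- simulateMethylomes(b, cfg)
    w <- methRecords(meth$wt); d <- methRecords(meth$dko)
    bothSides <- b$sites[mcols(b$sites)$side == "both"]
    ctr <- (start(bothSides) + end(bothSides)) %/% 2
    ## CpGs at ~1 decay length: expected DKO-WT = baseline 0.5 + 0.5/e (clipped
    ## against 1 barely matters at these levels)
    dist <- abs(outer(start(w), ctr, "-"))
    nearest <- apply(dist, 1, min)
    sel <- abs(nearest - 500) < 50
    expDelta <- pmin(0.7 + 0.5 * exp(-nearest[sel] / 500), 1) - 0.2
    obsDelta <- mcols(d)$ratio[sel] - mcols(w)$ratio[sel]
    expect_lt(abs(mean(obsDelta) - mean(expDelta)), 0.03)
    ## spreading amplitude 0 and equal baselines: DMR caller finds nothing
    cfg0 <- syntheticConfig(genomeLength = 4e5, islandCount = 0L,
                            nSitesIsland = 0L, nSitesOutside = 20L,
                            nSitesGained = 0L, backgroundCpgRate = 0.04,
                            methBackgroundWt = 0.2, methBackgroundDko = 0.2,
                            spreadingAmplitude = 0, dmrCount = 0L,
                            coverageMean = 30, seed = 8L)
    b0 <- generateGenome(cfg0)
    m0 <- simulateMethylomes(b0, cfg0)
    expect_length(callDMRs(m0$wt, m0$dko), 0)
    expect_error(syntheticConfig(spreadingDecayLength = 0), "spreadingDecayLength")
})

test_that("the manifest lists exactly the planted DMRs with their deltas", {
    cfg <- syntheticConfig(genomeLength = 3e5, islandCount = 2L,
                           nSitesIsland = 4L, nSitesOutside = 10L,
                           dmrCount = 6L, dmrDelta = 0.4,
                           fragmentsPerReplicate = 1000L, nTranscripts = 50L,
                           tadWidth = 50000L, seed = 9L)
    sim <- simulateEpigenome(cfg)
    dmrs <- plantedDmrs(sim$manifest)
    expect_length(dmrs, 6)
    expect_true(all(width(dmrs) == cfg@dmrLength))
    expect_setequal(unique(abs(mcols(dmrs)$delta)), 0.4)
    expect_identical(dmrs, sim$meth$dmrs)
    ## every lost planted site appears in all WT replicates, no DKO replicate
    lost <- plantedSites(sim$manifest)[mcols(plantedSites(sim$manifest))$lost]
    for (r in seq_along(sim$peaks$wt))
        expect_true(all(countOverlaps(lost, sim$peaks$wt[[r]]) > 0))
    for (r in seq_along(sim$peaks$dko))
        expect_true(all(countOverlaps(lost, sim$peaks$dko[[r]]) == 0))
})

test_that("nucleosome occupancy over lost motifs is restored in DKO", {
    cfg <- syntheticConfig(genomeLength = 3e5, islandCount = 4L,
                           nSitesIsland = 10L, nSitesOutside = 30L,
                           fragmentsPerReplicate = 60000L, seed = 4L)
    b <- generateGenome(cfg)
    wt <- occupancyTrack(simulateNucleosomeFragments(b, cfg, "WT", 1))
    dko <- occupancyTrack(simulateNucleosomeFragments(b, cfg, "DKO", 1))
    lost <- b$sites[mcols(b$sites)$lost]
    wtOcc <- vapply(seq_along(lost), function(i) {
        v <- trackValues(wt)[[as.character(seqnames(lost)[i])]]
        mean(as.numeric(v[start(lost)[i]:end(lost)[i]]))
    }, numeric(1))
    dkoOcc <- vapply(seq_along(lost), function(i) {
        v <- trackValues(dko)[[as.character(seqnames(lost)[i])]]
        mean(as.numeric(v[start(lost)[i]:end(lost)[i]]))
    }, numeric(1))
    expect_gt(mean(dkoOcc), mean(wtOcc))
    ## phasing fraction 0: flat expected occupancy (uniform sampling)
    cfg0 <- syntheticConfig(genomeLength = 2e5, islandCount = 2L,
                            nSitesIsland = 4L, nSitesOutside = 10L,
                            phasedFraction = 0, fragmentsPerReplicate = 60000L,
                            seed = 4L)
    b0 <- generateGenome(cfg0)
    fr0 <- simulateNucleosomeFragments(b0, cfg0, "WT", 1)
    expect_false(estimateNRL(fr0)$periodic)
})

test_that("peak simulation respects the loss model", {
    ## loss probability 0 everywhere -> zero lost sites
    cfgNoLoss <- syntheticConfig(genomeLength = 2e5, islandCount = 2L,
                                 nSitesIsland = 4L, nSitesOutside = 10L,
                                 lossBase = -30, lossWeakBoost = 0,
                                 lossDensitySlope = 0, seed = 6L)
    b <- generateGenome(cfgNoLoss)
    expect_equal(sum(mcols(b$sites)$lost), 0)
    ## density-weighted loss: 1-kb CpG density predicts the lost label
    cfg <- syntheticConfig(genomeLength = 6e5, islandCount = 12L,
                           nSitesIsland = 36L, nSitesOutside = 72L, seed = 6L)
    b2 <- generateGenome(cfg)
    lab <- as.integer(mcols(b2$sites)$lost[!mcols(b2$sites)$gained])
    dens <- mcols(b2$sites)$cpgDensity[!mcols(b2$sites)$gained]
    expect_gt(rocAUC(dens, lab, direction = "<")$auc, 0.5)
})

test_that("transcripts outside TADs never enter TAD categories", {
    cfg <- syntheticConfig(genomeLength = 2.5e5, islandCount = 2L,
                           nSitesIsland = 4L, nSitesOutside = 12L,
                           tadWidth = 100000L, nTranscripts = 80L, seed = 7L)
    b <- generateGenome(cfg)
    ex <- simulateExpression(b, cfg)
    ## TADs tile [1, 200000]; transcripts beyond that are outside
    outside <- ex$transcripts[countOverlaps(ex$transcripts, ex$tads) == 0]
    r <- expressionLinkage(ex$transcripts, ex$tads, ex$loops,
                           b$sites[mcols(b$sites)$lost], ex$promoters)
    expect_equal(r[r$category == "inside_tads", "nTotal"],
                 length(ex$transcripts) - length(outside))
    expect_lte(r[r$category == "inside_lost_tads", "nTotal"],
               r[r$category == "inside_tads", "nTotal"])
})
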