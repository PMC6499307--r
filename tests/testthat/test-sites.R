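## Helper: replicate peak sets around fixed site positions with small jitter.
mkPeaks <- function(centers, seed, half = 150L) {
    set.seed(seed)
    j <- round(rnorm(length(centers), 0, 5))
    GRanges("chr1", IRanges(centers - half + j, centers + half + j))
}

test_that("consensus categories follow the all-replicates rule", {
    common <- c(1000, 5000)
    lostC <- 9000
    gainC <- 13000
    partial <- 17000
    wt <- list(mkPeaks(c(common, lostC, partial), 1),
               mkPeaks(c(common, lostC), 2),
               mkPeaks(c(common, lostC), 3))
    dko <- list(mkPeaks(c(common, gainC, partial), 4),
                mkPeaks(c(common, gainC), 5))
    cs <- consensusSites(wt, dko)
    cat_ <- setNames(as.character(mcols(cs)$category),
                     as.character(round(start(cs) + 150, -2)))
    hit <- function(p) as.character(mcols(cs)$category[
        which.max(countOverlaps(cs, GRanges("chr1", IRanges(p, width = 1))))])
    expect_equal(hit(1000), "common")
    expect_equal(hit(5000), "common")
    expect_equal(hit(9000), "lost")
    expect_equal(hit(13000), "gained")
    expect_equal(hit(17000), "uncategorized")  # in WT1 and DKO1 only
})

test_that("consensus is order-independent and exclusive", {
    wt <- list(mkPeaks(c(1000, 5000, 9000), 1), mkPeaks(c(1000, 9000), 2))
    dko <- list(mkPeaks(c(1000, 5000), 3), mkPeaks(c(1000, 5000), 4))
    a <- consensusSites(wt, dko)
    b <- consensusSites(rev(wt), rev(dko))
    expect_equal(granges(a), granges(b))
    expect_equal(mcols(a)$category, mcols(b)$category)
    expect_error(consensusSites(list(), list(GRanges())), "one replicate")
})

test_that("motif scanning finds planted sites at the right position and strand", {
    m <- testMotif()
    cons <- motifConsensus(m)
    rc <- as.character(reverseComplement(DNAString(cons)))
    s <- paste0(randSeq(300, 31), cons, randSeq(200, 32), rc, randSeq(300, 33))
    genome <- DNAStringSet(s); names(genome) <- "chr1"
    peaks <- GRanges("chr1", IRanges(c(250, 450), c(400, 650)),
                     category = factor(c("common", "lost")))
    hits <- scanMotifs(peaks, genome, m, threshold = 0.8)
    expect_length(hits, 2)
    expect_equal(start(hits), c(301, 520))
    expect_equal(as.character(strand(hits)), c("+", "-"))
    expect_equal(as.character(mcols(hits)$category), c("common", "lost"))
    ## an unreachable threshold yields no motif sites
    expect_length(scanMotifs(peaks, genome, m, threshold = 1.01), 0)
    ## two planted copies in each peak -> mean motifs per peak = 2
    s2 <- paste0(randSeq(100, 41), cons, randSeq(60, 42), cons, randSeq(100, 43))
    genome2 <- DNAStringSet(s2); names(genome2) <- "chr1"
    peaks2 <- GRanges("chr1", IRanges(50, 330), category = factor("common"))
    expect_equal(length(scanMotifs(peaks2, genome2, m)), 2)
})

test_that("log-odds scan agrees with Biostrings matchPWM as a cross-check", {
    m <- testMotif()
    s <- paste0(randSeq(500, 51), motifConsensus(m), randSeq(500, 52))
    genome <- DNAStringSet(s); names(genome) <- "chr1"
    peaks <- GRanges("chr1", IRanges(1, nchar(s)))
    ours <- scanMotifs(peaks, genome, m, threshold = 0.8)
    ## same matrix, forward strand, min.score chosen to the same absolute cutoff
    pwm <- log2(motifProb(m) / 0.25)
    maxS <- sum(apply(pwm, 2, max)); minS <- sum(apply(pwm, 2, min))
    cutFrac <- (0.8 * maxS - minS) / (maxS - minS)
    fwd <- Biostrings::matchPWM(pwm, genome[[1]],
                                min.score = paste0(100 * cutFrac, "%"))
    oursFwd <- ours[strand(ours) == "+"]
    expect_setequal(start(fwd), start(oursFwd))
})

test_that("site composition reports CpG content and clean frequency matrices", {
    m <- testMotif()
    cons <- motifConsensus(m)            # contains one CG
    noCpg <- gsub("CG", "CA", cons)      # CpG-free variant
    s <- paste0(randSeq(2100, 61), cons, randSeq(500, 62), noCpg, randSeq(2100, 63))
    genome <- DNAStringSet(s); names(genome) <- "chr1"
    sites <- GRanges("chr1", IRanges(c(2101, 2620), width = 19), strand = "+",
                     category = factor(c("common", "lost")))
    comp <- siteCpgComposition(sites, genome, flank = 100, profileFlank = 300)
    summ <- comp$summary
    expect_equal(summ$fractionWithCpG[summ$category == "common"], 1)
    expect_equal(summ$fractionWithCpG[summ$category == "lost"], 0)
    for (f in comp$nucleotideFreq) {
        cs <- colSums(f)
        expect_true(all(abs(cs[!is.na(cs)] - 1) < 1e-9))
    }
})

test_that("synthetic common sites carry denser CpG flanks than lost sites", {
    cfg <- syntheticConfig(genomeLength = 4e5, islandCount = 8L,
                           nSitesIsland = 24L, nSitesOutside = 48L,
                           nSitesGained = 0L, seed = 5L)
    b <- generateGenome(cfg)
    pk <- simulateCtcfPeaks(b, cfg)
    cs <- consensusSites(pk$wt, pk$dko)
    ms <- scanMotifs(cs, b$genome, b$motif)
    comp <- siteCpgComposition(ms, b$genome)
    summ <- comp$summary
    expect_gt(summ$meanFlankCpgDensity[summ$category == "common"],
              summ$meanFlankCpgDensity[summ$category == "lost"])
})
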