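test_that("fold enrichment matches the analytic expectation", {
    ## all 100 query elements inside a feature covering 5% -> fold = 20
    feature <- GRanges("chr1", IRanges(1, 50000))       # 5% of 1 Mb
    query <- GRanges("chr1", IRanges(seq(100, 49000, length.out = 100), width = 10))
    r <- foldEnrichment(query, feature, c(chr1 = 1e6))
    expect_equal(r$observed, 100)
    expect_equal(r$expected, 100 * 0.05)
    expect_equal(r$fold, 20)
    expect_equal(r$percentOverlap, 100)
    expect_error(foldEnrichment(query, GRanges("chr1", IRanges(1, 1e6)),
                                c(chr1 = 1e6)), "exceed")
})

test_that("permutation and analytic expectations agree on uniform input", {
    set.seed(3)
    feature <- GRanges("chr1", IRanges(seq(1, 9e5, by = 1e5), width = 1e4))
    query <- GRanges("chr1", IRanges(sample.int(999000, 300), width = 100))
    a <- foldEnrichment(query, feature, c(chr1 = 1e6))
    p <- foldEnrichment(query, feature, c(chr1 = 1e6), method = "permutation",
                        nPerm = 300, seed = 11)
    ## expectations agree within a few Monte-Carlo SEs (the analytic form is a
    ## point approximation; width-100 elements widen it slightly)
    expect_lt(abs(p$expected - a$expected) / length(query), 0.05)
    expect_true(p$pValue > 0.01)  # uniform query is not enriched
})

test_that("AUC equals the Mann-Whitney pairwise probability including ties", {
    expect_equal(rocAUC(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
    expect_equal(rocAUC(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
    expect_equal(rocAUC(c(5, 5, 5, 5), c(0, 1, 0, 1))$auc, 0.5)
    expect_equal(rocAUC(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0.0)
    ## orientation is explicit, not forced above 0.5
    expect_equal(rocAUC(c(1, 2, 3, 4), c(1, 1, 0, 0), direction = "<")$auc, 1.0)
    expect_error(rocAUC(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC matches brute force and the orientation identity on tied data", {
    set.seed(10)
    for (rep in 1:5) {
        n <- 300
        scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
        labels <- rbinom(n, 1, 0.4)
        if (sum(labels) %in% c(0, n)) next
        a <- rocAUC(scores, labels)$auc
        expect_equal(a, bruteAUC(scores, labels), tolerance = 1e-12)
        expect_equal(rocAUC(-scores, labels)$auc, 1 - a, tolerance = 1e-12)
    }
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
    set.seed(2)
    r <- rocAUC(rnorm(100), rbinom(100, 1, 0.5))$roc
    expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("AUC agrees with pROC on continuous scores", {
    skip_if_not_installed("pROC")
    set.seed(6)
    scores <- rnorm(200); labels <- rbinom(200, 1, 0.5)
    ours <- rocAUC(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("predictor table computes flank density and masks missing tracks", {
    m <- testMotif()
    cons <- motifConsensus(m)
    noCpg <- gsub("CG", "CA", cons)
    s <- paste0(strrep("AT", 400), noCpg, strrep("AT", 400))  # CpG-free flanks
    genome <- DNAStringSet(s); names(genome) <- "chr1"
    sites <- GRanges("chr1", IRanges(801, width = 19), strand = "+",
                     score = 30, category = factor("lost", levels = c("common", "lost")))
    occ <- makeTrack(rep(1, nchar(s)), normalization = "per-million")
    meth <- makeMeth(5, 0.5, seqlen = nchar(s))
    tab <- buildPredictorTable(sites, occ, occ, meth, genome)
    expect_equal(tab$flankCpgDensity, 0)
    expect_equal(tab$deltaNucOccupancy, 0)
    expect_equal(tab$label, 1L)
    expect_true(is.na(tab$methylationLevel))  # no CpG near the site -> masked
})

test_that("expression linkage tabulates the eight categories and chi-square", {
    ## toy: genome-wide up=10 down=5; TAD2 loses its far boundary
    tads <- GRanges("chr1", IRanges(c(1, 100001), width = 1e5))
    lostSites <- GRanges("chr1", IRanges(195000, width = 19))  # near TAD2 end only
    pos <- c(seq(20000, 60000, length.out = 5),          # inside TAD1 (far)
             seq(110000, 130000, length.out = 10))       # inside lost TAD2
    sig <- c(rep("up", 3), rep("down", 2),               # TAD1: 3 up 2 down
             rep("up", 7), rep("down", 3))               # TAD2: 7 up 3 down
    tx <- GRanges("chr1", IRanges(pos, width = 1000),
                  id = sprintf("T%02d", seq_along(pos)), signif = sig)
    prom <- GRanges("chr1", IRanges(pos - 500, width = 1000), id = mcols(tx)$id)
    r <- expressionLinkage(tx, tads, NULL, lostSites, prom, dist = 10000)
    expect_equal(nrow(r), 8)
    gw <- r[r$category == "genome_wide", ]
    expect_equal(gw$nUp, 10); expect_equal(gw$nDown, 5)
    inLost <- r[r$category == "inside_lost_tads", ]
    expect_equal(inLost$nUp, 7); expect_equal(inLost$nDown, 3)
    ## chi-square without continuity correction against the genome-wide margin
    man <- suppressWarnings(chisq.test(rbind(c(10, 5), c(7, 3)), correct = FALSE))
    expect_equal(inLost$chisq, unname(man$statistic))
    expect_equal(inLost$pValue, man$p.value)
    ## no lost sites -> lost categories empty
    r0 <- expressionLinkage(tx, tads, NULL, GRanges(), prom, dist = 10000)
    expect_equal(r0[r0$category == "inside_lost_tads", "nTotal"], 0)
    expect_equal(r0[r0$category == "lost_ctcf_at_promoter", "nTotal"], 0)
    ## a transcript outside all TADs never enters TAD categories
    out <- GRanges("chr1", IRanges(250000, width = 1000), id = "OUT", signif = "down")
    r1 <- expressionLinkage(c(tx, out), tads, NULL, lostSites, prom, dist = 10000)
    expect_equal(r1[r1$category == "inside_tads", "nTotal"], length(tx))
})

test_that("toy ratio arithmetic matches the worked example", {
    ## ratios 0.5 and 4.0 with chi-square on [[10,5],[2,8]]
    tads <- GRanges("chr1", IRanges(1, 1e5))
    lostSites <- GRanges("chr1", IRanges(500, width = 19))
    txGw <- GRanges("chr1", IRanges(seq(200000, 400000, length.out = 15), width = 100),
                    id = sprintf("G%02d", 1:15),
                    signif = c(rep("up", 10), rep("down", 5)))
    txIn <- GRanges("chr1", IRanges(seq(2000, 90000, length.out = 10), width = 100),
                    id = sprintf("I%02d", 1:10),
                    signif = c(rep("up", 2), rep("down", 8)))
    tx <- c(txGw, txIn)
    prom <- GRanges("chr1", IRanges(start(tx) - 50, width = 100), id = mcols(tx)$id)
    r <- expressionLinkage(tx, tads, NULL, lostSites, prom)
    gw <- r[r$category == "genome_wide", ]
    expect_equal(gw$downUpRatio, 13 / 12)  # all 25 transcripts genome-wide
    inLost <- r[r$category == "inside_lost_tads", ]
    expect_equal(inLost$downUpRatio, 4.0)
    man <- suppressWarnings(chisq.test(rbind(c(12, 13), c(2, 8)), correct = FALSE))
    expect_equal(inLost$chisq, unname(man$statistic))
})
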