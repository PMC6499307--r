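test_that("CpG classes follow the printed thresholds with strict boundaries", {
    expect_equal(as.character(classifyCpG(0.9, 0.85)), "common_methylated")
    expect_equal(as.character(classifyCpG(0.1, 0.6)), "gained")
    expect_equal(as.character(classifyCpG(0.6, 0.1)), "lost")
    expect_equal(as.character(classifyCpG(0.1, 0.1)), "unmethylated")
    expect_equal(as.character(classifyCpG(0.3, 0.3)), "other")
    ## boundary semantics: 0.8 inclusive, 0.2/0.5 strict
    expect_equal(as.character(classifyCpG(0.8, 0.8)), "common_methylated")
    expect_equal(as.character(classifyCpG(0.2, 0.6)), "other")  # not < 0.2
    expect_equal(as.character(classifyCpG(0.1, 0.5)), "other")  # not > 0.5
    ## missing ratios are unclassified, not an error
    expect_true(is.na(classifyCpG(NA, 0.5)))
})

test_that("CpG classification partitions the unit square", {
    g <- expand.grid(wt = seq(0, 1, by = 0.05), dko = seq(0, 1, by = 0.05))
    cls <- classifyCpG(g$wt, g$dko)
    expect_false(anyNA(cls))
    expect_setequal(levels(cls), c("common_methylated", "gained", "lost",
                                   "unmethylated", "other"))
    ## each pair maps to exactly one class: re-deriving membership agrees
    manual <- ifelse(g$wt >= 0.8 & g$dko >= 0.8, "common_methylated",
              ifelse(g$wt < 0.2 & g$dko > 0.5, "gained",
              ifelse(g$wt > 0.5 & g$dko < 0.2, "lost",
              ifelse(g$wt < 0.2 & g$dko < 0.2, "unmethylated", "other"))))
    expect_equal(as.character(cls), manual)
})

test_that("methylation smoothing averages covered CpGs per window", {
    ## constant track -> constant smoothed value
    tr <- makeMeth(seq(10, 4990, by = 25), 0.4, seqlen = 5000)
    sm <- smoothMethylation(tr, window = 500L, step = 100L)
    expect_true(all(abs(mcols(sm)$score - 0.4) < 1e-12))
    ## two CpGs 0.2/0.8 in one window -> 0.5
    tr2 <- makeMeth(c(100, 200), c(0.2, 0.8), seqlen = 600)
    sm2 <- smoothMethylation(tr2, window = 500L)
    expect_equal(mcols(sm2)$score[1], 0.5)
    ## step block 0 -> 1: brute-force window means agree
    pos <- seq(5, 2995, by = 10)
    ratio <- ifelse(pos < 1500, 0, 1)
    tr3 <- makeMeth(pos, ratio, seqlen = 3000)
    sm3 <- smoothMethylation(tr3, window = 500L, step = 50L)
    brute <- vapply(start(sm3), function(s) {
        sel <- pos >= s & pos <= s + 499
        mean(ratio[sel])
    }, numeric(1))
    expect_equal(mcols(sm3)$score, brute)
    expect_error(smoothMethylation(tr, window = 100L, step = 200L), "window >= step")
})

test_that("DMR calling obeys the strict 10% deviation rule and merges windows", {
    pos <- seq(10, 9990, by = 20)
    wt <- makeMeth(pos, 0.3, coverage = 50, seqlen = 10000, condition = "WT")
    ## identical tracks -> no DMRs
    expect_length(callDMRs(wt, makeMeth(pos, 0.3, coverage = 50, seqlen = 10000,
                                        condition = "DKO")), 0)
    ## delta exactly 0.10 is NOT called (strict inequality)
    dkoEq <- makeMeth(pos, 0.4, coverage = 50, seqlen = 10000, condition = "DKO")
    expect_length(callDMRs(wt, dkoEq, delta = 0.10), 0)
    ## planted 2-kb gain block with delta 0.4 -> exactly one gain DMR
    ratio <- ifelse(pos >= 4000 & pos < 6000, 0.7, 0.3)
    dko <- makeMeth(pos, ratio, coverage = 50, seqlen = 10000, condition = "DKO")
    dmrs <- callDMRs(wt, dko)
    expect_length(dmrs, 1)
    expect_equal(as.character(mcols(dmrs)$direction), "gain")
    ## covers the planted block within one window at each edge
    expect_lte(start(dmrs), 4000)
    expect_gte(end(dmrs), 5999 - 1000)
    expect_lte(abs(start(dmrs) - 4000), 1000)
    expect_lte(abs(end(dmrs) - 5999), 1000)
    ## the merged DMR still satisfies the criterion on recomputation
    expect_gt(abs(mcols(dmrs)$meanDko - mcols(dmrs)$meanWt), 0.10)
    expect_error(callDMRs(wt, dko, window = 100L, step = 500L), "window")
})

test_that("gain and loss windows never merge into one DMR", {
    pos <- seq(10, 11990, by = 20)
    base <- rep(0.4, length(pos))
    up <- ifelse(pos >= 3000 & pos < 5000, 0.8,
          ifelse(pos >= 5000 & pos < 7000, 0.05, 0.4))
    wt <- makeMeth(pos, base, coverage = 50, seqlen = 12000)
    dko <- makeMeth(pos, up, coverage = 50, seqlen = 12000, condition = "DKO")
    dmrs <- callDMRs(wt, dko)
    expect_setequal(as.character(mcols(dmrs)$direction), c("gain", "loss"))
    ## disjoint output intervals
    expect_true(all(countOverlaps(dmrs, dmrs) == 1))
})

test_that("anchor-relative methylation profiles orient and normalise", {
    pos <- seq(1, 2000)
    tr <- makeMeth(pos, 0.5, seqlen = 2100)
    anc <- GRanges("chr1", IRanges(1000, width = 1))
    pAbs <- methylationProfile(tr, anc, flank = 200, mode = "absolute")
    expect_true(all(abs(profileMean(pAbs) - 0.5) < 1e-12))
    pRel <- methylationProfile(tr, anc, flank = 200, mode = "relative")
    expect_true(all(abs(profileMean(pRel) - 1) < 1e-12))
    ## asymmetric track: strand flip mirrors the profile
    tr2 <- makeMeth(pos, ifelse(pos < 1000, 0.2, 0.8), seqlen = 2100)
    fwd <- methylationProfile(tr2, anc, flank = 150)
    ancRev <- anc; strand(ancRev) <- "-"
    rev_ <- methylationProfile(tr2, ancRev, flank = 150)
    expect_equal(profileMean(rev_), rev(profileMean(fwd)))
    expect_error(methylationProfile(tr, GRanges(), flank = 100), "empty")
})
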