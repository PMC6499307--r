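test_that("PFM parsing normalises with pseudocount and validates input", {
    m <- loadPFM(text = c(">toy", "A [ 8 0 ]", "C [ 0 8 ]",
                          "G [ 0 0 ]", "T [ 0 0 ]"))
    expect_equal(motifWidth(m), 2L)
    expect_equal(unname(motifProb(m)["A", 1]), 9 / 12)
    expect_equal(unname(motifProb(m)["C", 1]), 1 / 12)
    expect_equal(unname(motifMaxProb(m)), c(9 / 12, 9 / 12))

    u <- loadPFM(text = c("4 4", "4 4", "4 4", "4 4"))
    expect_true(all(abs(motifProb(u) - 0.25) < 1e-12))
    expect_equal(unname(motifMaxProb(u)), c(0.25, 0.25))

    expect_error(loadPFM(text = c("A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]")),
                 "ragged")
    expect_error(loadPFM(text = c("A [ 1 -2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "T [ 1 2 ]")),
                 "negative")
    expect_error(loadPFM(text = c("A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 x ]", "T [ 1 2 ]")),
                 "non-numeric")
})

test_that("the packaged CTCF-like motif has the canonical 19-bp width", {
    expect_equal(motifWidth(loadCtcfMotif()), 19L)
})

test_that("mismatch energy is a lambda-scaled log-ratio sum", {
    ## two-column toy: p(A) = 9/12, p(C) = 1/12 in each column
    m <- loadPFM(text = c("A [ 8 8 ]", "C [ 0 0 ]", "G [ 0 0 ]", "T [ 0 0 ]"))
    tp <- trapParams(lambda = 1.5)
    expect_equal(mismatchEnergy("AA", m, tp), 0)
    ## one mismatch with ratio 9 -> ln(9)/1.5
    expect_equal(mismatchEnergy("CA", m, tp), log(9) / 1.5, tolerance = 1e-12)
    ## doubling lambda halves any energy
    tp2 <- trapParams(lambda = 3)
    for (win in c("CA", "CC", "GT")) {
        expect_equal(mismatchEnergy(win, m, tp2),
                     mismatchEnergy(win, m, tp) / 2, tolerance = 1e-12)
    }
    ## minus strand scores the reverse complement
    expect_equal(mismatchEnergy("TT", m, tp, strand = "-"),
                 mismatchEnergy("AA", m, tp), tolerance = 1e-12)
    ## ambiguous base -> NA, not an error
    expect_true(is.na(mismatchEnergy("NA", m, tp)))
    expect_error(mismatchEnergy("AAA", m, tp), "width")
})

test_that("TRAP occupancy saturates at consensus and decays with energy", {
    tp <- trapParams(R0 = 1e9, lambda = 1.5)
    expect_equal(windowBindingProb(0, tp), 1e9 / (1e9 + 1), tolerance = 1e-15)
    expect_equal(windowBindingProb(log(1e9), tp), 0.5, tolerance = 1e-12)
    expect_equal(windowBindingProb(25, tp),
                 1e9 * exp(-25) / (1 + 1e9 * exp(-25)), tolerance = 1e-12)
    e <- seq(0, 40, by = 0.5)
    expect_true(all(diff(windowBindingProb(e, tp)) < 0))
})

test_that("affinity profile matches the brute-force oracle", {
    m <- testMotif(); tp <- trapParams()
    for (seed in 1:5) {
        s <- randSeq(200, seed)
        at <- affinityProfile(s, m, tp)
        v <- as.numeric(trackValues(at)[[1]])
        brute <- bruteAffinity(s, motifProb(m))
        expect_equal(v, brute, tolerance = 1e-9)
    }
    ## strand max mode agrees too
    s <- randSeq(200, 99)
    vMax <- as.numeric(trackValues(affinityProfile(s, m, tp, strandMode = "max"))[[1]])
    expect_equal(vMax, bruteAffinity(s, motifProb(m), strandMode = "max"),
                 tolerance = 1e-9)
})

test_that("planted consensus dominates the landscape and edges are masked", {
    m <- testMotif(); tp <- trapParams()
    s <- randSeq(400, 7)
    planted <- paste0(substr(s, 1, 200), motifConsensus(m), substr(s, 201, 400))
    v <- as.numeric(trackValues(affinityProfile(planted, m, tp))[[1]])
    expect_equal(which.max(v), 200 + 1 + motifWidth(m) %/% 2)
    expect_true(all(is.na(v[seq_len(motifWidth(m) %/% 2)])))
    expect_true(all(is.na(tail(v, motifWidth(m) %/% 2))))
    ## N windows are missing, not zero
    withN <- paste0(substr(planted, 1, 100), "N", substr(planted, 102, nchar(planted)))
    vN <- as.numeric(trackValues(affinityProfile(withN, m, tp))[[1]])
    expect_true(all(is.na(vN[(101 - motifWidth(m) %/% 2):(101 + motifWidth(m) %/% 2)])))
})

test_that("a worsening substitution never increases window probability", {
    m <- testMotif(); tp <- trapParams()
    set.seed(11)
    cons <- strsplit(motifConsensus(m), "")[[1]]
    prob <- motifProb(m)
    for (rep in 1:30) {
        win <- sample(BASES, motifWidth(m), replace = TRUE)
        j <- sample.int(motifWidth(m), 1)
        ## substitution strictly reducing the column probability
        worse <- BASES[which.min(prob[, j])]
        if (prob[worse, j] >= prob[win[j], j]) next
        p0 <- windowBindingProb(mismatchEnergy(paste(win, collapse = ""), m, tp), tp)
        win[j] <- worse
        p1 <- windowBindingProb(mismatchEnergy(paste(win, collapse = ""), m, tp), tp)
        expect_lte(p1, p0 + 1e-15)
    }
})

test_that("R0 drives the saturation and linear regimes", {
    m <- testMotif()
    s <- randSeq(100, 3)
    vBig <- as.numeric(trackValues(affinityProfile(s, m, trapParams(R0 = 1e30)))[[1]])
    expect_true(all(vBig[!is.na(vBig)] > 0.999))
    e <- 5
    pSmall <- windowBindingProb(e, trapParams(R0 = 1e-6))
    expect_equal(pSmall, 1e-6 * exp(-e), tolerance = 1e-5)
})

test_that("region affinity is additive and zero on empty regions", {
    m <- testMotif(); tp <- trapParams()
    s <- paste0(randSeq(150, 21), motifConsensus(m), randSeq(150, 22))
    at <- affinityProfile(s, m, tp)
    whole <- regionAffinity(at, GRanges("chr1", IRanges(50, 250)))
    halves <- regionAffinity(at, GRanges("chr1", IRanges(c(50, 151), c(150, 250))))
    expect_equal(whole, sum(halves), tolerance = 1e-12)
    expect_equal(regionAffinity(at, GRanges("chr9", IRanges(1, 10))), 0)
    ## one planted consensus contributes ~1 under strand-sum with cap
    site <- regionAffinity(at, GRanges("chr1", IRanges(150, 170)))
    expect_gt(site, 0.99)
    expect_lt(site, 1.5)
})
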