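## Synthetic two-condition epigenome with planted ground truth.
##
## The generator emulates the statistical structure the analysis assumes: a
## genome with CpG islands and planted CTCF motifs of two affinity tiers;
## WT/DKO methylomes with planted DMR blocks and distance-decaying
## methylation spreading around lost CTCF sites; phased nucleosome fragment
## sets with a configurable repeat length and a depleted region over bound
## motifs; replicate peak sets with condition-dependent site loss; and
## transcripts whose down-regulation probability rises near lost boundaries.
## All parameter defaults are artifact choices (no generative model exists
## for the real data); see the methods vignette.

#' @describeIn SyntheticConfig-class constructor with desk-scale defaults.
#' @param ... slot values overriding the defaults (see slot documentation).
#' @export
syntheticConfig <- function(...) {
    defaults <- list(
        genomeLength = 1e6, nChromosomes = 1L,
        islandCount = 20L, islandLength = 2000L,
        islandCpgRate = 0.10, backgroundCpgRate = 0.01,
        nSitesIsland = 60L, nSitesOutside = 120L, nSitesGained = 4L,
        weakMismatches = 1L,
        methIsland = 0.05, methBackgroundWt = 0.3, methBackgroundDko = 0.3,
        spreadingAmplitude = 0.3, spreadingDecayLength = 500,
        dmrCount = 20L, dmrLength = 2000L, dmrDelta = 0.35,
        coverageMean = 20,
        nrl = 176L, phasingSd = 20, phasedFraction = 0.5,
        fragmentLengthMean = 150, fragmentLengthSd = 10,
        fragmentsPerReplicate = 120000L, replicatesPerCondition = 2L,
        pFn = 0,
        lossBase = 0.2, lossWeakBoost = 1.4, lossDensitySlope = 0.08,
        peakHalfWidth = 150L, peakJitterSd = 10,
        tadWidth = 100000L, nTranscripts = 400L, transcriptLength = 2000L,
        pUp = 0.15, pDown = 0.10, expressionDownregBoost = 0.35,
        boundaryDist = 10000L, promoterFlank = 1000L,
        seed = 1L)
    args <- list(...)
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
    vals <- utils::modifyList(defaults, args)
    intSlots <- names(defaults)[vapply(defaults, is.integer, logical(1))]
    for (nm in intSlots) vals[[nm]] <- as.integer(vals[[nm]])
    do.call(new, c(list("SyntheticConfig"), vals))
}

#' Packaged CTCF-like motif model
#'
#' Loads the 19-bp CTCF-like position frequency matrix shipped with the
#' package (\code{inst/extdata/ctcf_synthetic.pfm}). The matrix is a
#' constructed stand-in with the width and general structure of the CTCF
#' motif (GC-rich, one central CpG), labelled synthetic; it is not the
#' empirical CTCF matrix.
#'
#' @param pseudocount passed to \code{\link{loadPFM}}.
#' @return A \linkS4class{MotifModel} of width 19.
#' @export
loadCtcfMotif <- function(pseudocount = 1) {
    loadPFM(system.file("extdata", "ctcf_synthetic.pfm", package = "methylCTCF"),
            pseudocount = pseudocount)
}

## Place n non-overlapping positions with a minimum gap, within [lo, hi],
## optionally restricted to a logical mask of allowed start positions.
.placePositions <- function(n, lo, hi, minGap, taken = integer(0), allowed = NULL) {
    pos <- integer(0)
    all_ <- c(taken)
    for (iter in seq_len(200L)) {
        if (length(pos) >= n) break
        cand <- as.integer(round(runif(4L * n, lo, hi)))
        if (!is.null(allowed)) cand <- cand[allowed[cand]]
        for (p in cand) {
            if (length(pos) >= n) break
            if (!length(all_) || min(abs(all_ - p)) >= minGap) {
                pos <- c(pos, p); all_ <- c(all_, p)
            }
        }
    }
    if (length(pos) < n)
        stop("cannot place ", n, " elements with gap ", minGap, " in [", lo, ", ", hi, "]")
    sort(pos)
}

.mutateWindow <- function(chars, k) {
    ## substitute k distinct positions by a random different base
    idx <- sample.int(length(chars), k)
    for (i in idx) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
    chars
}

.revCompChars <- function(chars) rev(c(A = "T", C = "G", G = "C", T = "A")[chars])

#' Generate the synthetic genome with islands and planted CTCF motifs
#'
#' Emits a random genome in which every CG dinucleotide is planted
#' deliberately: the base sequence is CpG-free, then CGs are planted at the
#' island rate inside islands and the background rate elsewhere. CTCF motifs
#' of two tiers (strong = exact consensus of \code{motif}; weak =
#' \code{weakMismatches} substitutions) are planted inside and outside
#' islands on random strands, and each site receives a loss flag from the
#' site-loss model: logit(p_loss) = lossBase + lossWeakBoost * [weak] -
#' lossDensitySlope * (local CpG density per kb over +/- 500 bp). Identical
#' config (including seed) gives byte-identical output.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param motif \linkS4class{MotifModel} to plant (default the packaged
#'   CTCF-like motif).
#' @return List with \code{genome} (DNAStringSet), \code{islands} (GRanges),
#'   \code{sites} (GRanges with mcols tier, lost, gained, side, cpgDensity),
#'   \code{motif}, \code{config}.
#' @export
generateGenome <- function(config, motif = loadCtcfMotif()) {
    set.seed(.childSeed(config@seed, 0L))
    w <- motifWidth(motif)
    consensus <- strsplit(motifConsensus(motif), "")[[1]]
    nChrom <- config@nChromosomes
    chromLen <- as.integer(floor(config@genomeLength / nChrom))
    chromNames <- paste0("chr", seq_len(nChrom))
    islPerChrom <- diff(round(seq(0, config@islandCount, length.out = nChrom + 1L)))
    seqs <- vector("list", nChrom)
    islandL <- list(); siteL <- list()
    for (ci in seq_len(nChrom)) {
        L <- chromLen
        s <- sample(.BASES, L, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
        cg <- which(s[-L] == "C" & s[-1L] == "G")
        if (length(cg)) s[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
        ## islands: one per equal segment, random offset (no overlap by design)
        nIsl <- islPerChrom[ci]
        islStart <- integer(0)
        if (nIsl > 0L) {
            segment <- L %/% nIsl
            if (config@islandLength >= segment)
                stop("island placement overflow: islands cannot fit without overlap")
            islStart <- (seq_len(nIsl) - 1L) * segment +
                sample.int(segment - config@islandLength, nIsl, replace = TRUE)
        }
        inIsland <- rep(FALSE, L)
        for (st in islStart) inIsland[st:(st + config@islandLength - 1L)] <- TRUE
        ## CpG planting on the CpG-free backbone
        rate <- ifelse(inIsland[-L], config@islandCpgRate, config@backgroundCpgRate)
        cpg <- which(runif(L - 1L) < rate)
        if (length(cpg) > 1L) cpg <- cpg[c(TRUE, diff(cpg) > 1L)]
        s[cpg] <- "C"; s[cpg + 1L] <- "G"
        ## site placement
        nIslSites <- if (nIsl > 0L) round(config@nSitesIsland / nChrom) else 0L
        nOutSites <- round(config@nSitesOutside / nChrom)
        nGained <- round(config@nSitesGained / nChrom)
        taken <- integer(0)
        islAllowed <- inIsland
        ## keep whole motif inside the island
        for (st in islStart) {
            islAllowed[max(1L, st + config@islandLength - w):(st + config@islandLength - 1L)] <- FALSE
        }
        ## island sites spaced beyond the peak width so replicate peaks of
        ## neighbouring sites never merge
        islGap <- 2L * config@peakHalfWidth + 150L
        islPos <- if (nIslSites > 0L)
            .placePositions(nIslSites, 1L, L - w, minGap = islGap, allowed = islAllowed)
            else integer(0)
        taken <- islPos
        outAllowed <- !inIsland
        outAllowed[seq_len(2500L)] <- FALSE
        outAllowed[(L - 2500L):L] <- FALSE
        outPos <- .placePositions(nOutSites, 1L, L - w, minGap = 2000L,
                                  taken = taken, allowed = outAllowed)
        taken <- c(taken, outPos)
        gainPos <- if (nGained > 0L)
            .placePositions(nGained, 1L, L - w, minGap = 2000L,
                            taken = taken, allowed = outAllowed) else integer(0)
        pos <- c(islPos, outPos, gainPos)
        inIsl <- c(rep(TRUE, length(islPos)), rep(FALSE, length(outPos) + length(gainPos)))
        gained <- c(rep(FALSE, length(islPos) + length(outPos)), rep(TRUE, length(gainPos)))
        tier <- ifelse(gained, "strong",
                       sample(rep(c("strong", "weak"), length.out = length(pos))))
        strand_ <- sample(c("+", "-"), length(pos), replace = TRUE)
        for (i in seq_along(pos)) {
            chars <- consensus
            if (tier[i] == "weak") chars <- .mutateWindow(chars, config@weakMismatches)
            if (strand_[i] == "-") chars <- .revCompChars(chars)
            s[pos[i]:(pos[i] + w - 1L)] <- chars
        }
        seqStr <- paste(s, collapse = "")
        ## local CpG density per kb over +/- 500 bp of the site centre
        dens <- vapply(pos, function(p) {
            ctr <- p + w %/% 2L
            a <- max(1L, ctr - 500L); b <- min(L, ctr + 500L)
            sub <- substr(seqStr, a, b)
            1000 * lengths(regmatches(sub, gregexpr("CG", sub, fixed = TRUE))) / (b - a + 1L)
        }, numeric(1))
        pl <- stats::plogis(config@lossBase +
                            config@lossWeakBoost * (tier == "weak") -
                            config@lossDensitySlope * dens)
        lost <- !gained & (rbinom(length(pos), 1L, pl) == 1L)
        side <- rep(NA_character_, length(pos))
        side[lost] <- sample(c("left", "right", "both"), sum(lost),
                             replace = TRUE, prob = c(0.4, 0.4, 0.2))
        seqs[[ci]] <- seqStr
        if (nIsl > 0L)
            islandL[[ci]] <- GRanges(chromNames[ci],
                IRanges(islStart, width = config@islandLength))
        siteL[[ci]] <- GRanges(chromNames[ci], IRanges(pos, width = w),
            strand = strand_, tier = tier, inIsland = inIsl,
            lost = lost, gained = gained, side = side, cpgDensity = dens)
    }
    genome <- DNAStringSet(unlist(seqs))
    names(genome) <- chromNames
    sl <- setNames(rep(chromLen, nChrom), chromNames)
    islands <- if (length(islandL)) suppressWarnings(do.call(c, islandL)) else GRanges()
    sites <- suppressWarnings(do.call(c, siteL))
    seqlengths(islands) <- sl[seqlevels(islands)]
    seqlengths(sites) <- sl[seqlevels(sites)]
    list(genome = genome, islands = islands, sites = sites, motif = motif,
         config = config)
}

## True (noise-free) methylation levels at given CpG positions for both
## conditions, including planted DMR blocks and spreading around lost sites.
.trueMethylation <- function(cpgPos, chrom, bundle, dmrs) {
    cfg <- bundle$config
    isl <- bundle$islands[seqnames(bundle$islands) == chrom]
    inIsl <- countOverlaps(GRanges(chrom, IRanges(cpgPos, width = 1L)), isl) > 0L
    wt <- ifelse(inIsl, cfg@methIsland, cfg@methBackgroundWt)
    dko <- ifelse(inIsl, cfg@methIsland, cfg@methBackgroundDko)
    if (length(dmrs)) {
        dm <- dmrs[seqnames(dmrs) == chrom]
        for (i in seq_along(dm)) {
            sel <- cpgPos >= start(dm)[i] & cpgPos <= end(dm)[i]
            if (mcols(dm)$direction[i] == "gain") dko[sel] <- dko[sel] + mcols(dm)$delta[i]
            else wt[sel] <- wt[sel] + abs(mcols(dm)$delta[i])
        }
    }
    lostSites <- bundle$sites[mcols(bundle$sites)$lost &
                              seqnames(bundle$sites) == chrom]
    if (length(lostSites) && cfg@spreadingAmplitude > 0) {
        ctr <- .centers(lostSites)
        for (i in seq_along(lostSites)) {
            d <- cpgPos - ctr[i]
            side <- mcols(lostSites)$side[i]
            reach <- 6 * cfg@spreadingDecayLength
            onSide <- switch(side,
                left = d <= 0 & d >= -reach,
                right = d >= 0 & d <= reach,
                both = abs(d) <= reach)
            if (any(onSide))
                dko[onSide] <- dko[onSide] + cfg@spreadingAmplitude *
                    exp(-abs(d[onSide]) / cfg@spreadingDecayLength)
        }
    }
    list(wt = pmin(pmax(wt, 0), 1), dko = pmin(pmax(dko, 0), 1))
}

#' Simulate WT and DKO methylomes over the synthetic genome
#'
#' Island CpGs sit at the island methylation level in both conditions;
#' background CpGs at their per-condition baselines. Planted DMR blocks
#' (placed in background sequence away from islands and CTCF sites) add
#' \code{dmrDelta} to DKO inside "gain" blocks and to WT inside "loss"
#' blocks. Around each lost CTCF site the DKO level additionally rises by
#' spreadingAmplitude * exp(-distance / spreadingDecayLength) on the side(s)
#' recorded in the manifest. Per-CpG observed ratios are
#' Binomial(coverage, true) / coverage with Poisson coverage (floored at 1),
#' modelling bisulfite counting noise; true levels are clipped to [0, 1].
#'
#' @param bundle result of \code{\link{generateGenome}}.
#' @param config the same \linkS4class{SyntheticConfig}.
#' @return List with \code{wt} and \code{dko}
#'   (\linkS4class{MethylationTrack}s) and \code{dmrs} (GRanges of planted
#'   DMRs with direction and delta).
#' @export
simulateMethylomes <- function(bundle, config = bundle$config) {
    set.seed(.childSeed(config@seed, 1L))
    sl <- seqlengths(bundle$sites)
    ## place planted DMR blocks: background only, clear of islands and sites
    dmrL <- list()
    nPer <- diff(round(seq(0, config@dmrCount, length.out = length(sl) + 1L)))
    for (ci in seq_along(sl)) {
        if (nPer[ci] == 0L) next
        ch <- names(sl)[ci]
        L <- as.integer(sl[[ci]])
        allowed <- rep(TRUE, L)
        isl <- bundle$islands[seqnames(bundle$islands) == ch]
        for (i in seq_along(isl)) {
            a <- max(1L, start(isl)[i] - config@dmrLength - 500L)
            allowed[a:min(L, end(isl)[i] + 500L)] <- FALSE
        }
        st <- bundle$sites[seqnames(bundle$sites) == ch]
        margin <- as.integer(3000L + config@dmrLength)
        for (i in seq_along(st)) {
            a <- max(1L, start(st)[i] - margin)
            allowed[a:min(L, end(st)[i] + 3000L)] <- FALSE
        }
        allowed[max(1L, L - config@dmrLength - 2000L):L] <- FALSE
        allowed[seq_len(2000L)] <- FALSE
        pos <- .placePositions(nPer[ci], 1L, L, minGap = config@dmrLength + 5000L,
                               allowed = allowed)
        dirs <- sample(rep(c("gain", "loss"), length.out = length(pos)))
        dmrL[[ci]] <- GRanges(ch, IRanges(pos, width = config@dmrLength),
            direction = dirs,
            delta = ifelse(dirs == "gain", config@dmrDelta, -config@dmrDelta))
    }
    dmrs <- if (length(dmrL)) sort(suppressWarnings(do.call(c, dmrL))) else
        GRanges(direction = character(), delta = numeric())
    ## emit per-CpG records
    hitsW <- list(); hitsD <- list()
    for (ch in names(bundle$genome)) {
        cpgPos <- start(vmatchPattern("CG", DNAStringSet(bundle$genome[ch]))[[1]])
        if (!length(cpgPos)) next
        tm <- .trueMethylation(cpgPos, ch, bundle, dmrs)
        covW <- pmax(rpois(length(cpgPos), config@coverageMean), 1L)
        covD <- pmax(rpois(length(cpgPos), config@coverageMean), 1L)
        hitsW[[ch]] <- GRanges(ch, IRanges(cpgPos, width = 1L),
            ratio = rbinom(length(cpgPos), covW, tm$wt) / covW, coverage = covW)
        hitsD[[ch]] <- GRanges(ch, IRanges(cpgPos, width = 1L),
            ratio = rbinom(length(cpgPos), covD, tm$dko) / covD, coverage = covD)
    }
    grW <- suppressWarnings(do.call(c, unname(hitsW)))
    grD <- suppressWarnings(do.call(c, unname(hitsD)))
    sl2 <- sl[seqlevels(grW)]
    seqlengths(grW) <- sl2; seqlengths(grD) <- sl2
    list(wt = methylationTrack(grW, "WT"), dko = methylationTrack(grD, "DKO"),
         dmrs = dmrs)
}

#' Simulate phased nucleosome fragments for one replicate
#'
#' A fraction \code{phasedFraction} of fragments is drawn from phased arrays
#' around planted CTCF sites: dyads at site centre + k * NRL + Gaussian
#' jitter (SD \code{phasingSd}), with k in {-5..-1, 1..5} when the site is
#' bound in this condition (nucleosome-depleted region over the motif) and k
#' in {-5..5} when it is not (depletion filled in; occupancy over the motif
#' restored). The remainder is uniform background. Fragment lengths are
#' Normal(mean, sd) truncated to [100, 200] bp.
#'
#' @param bundle result of \code{\link{generateGenome}}.
#' @param config the \linkS4class{SyntheticConfig}.
#' @param condition "WT" or "DKO".
#' @param replicate replicate number (seeds differ per replicate/condition).
#' @return A \linkS4class{FragmentSet} (empty when
#'   \code{fragmentsPerReplicate} is 0).
#' @export
simulateNucleosomeFragments <- function(bundle, config = bundle$config,
                                        condition = c("WT", "DKO"),
                                        replicate = 1L) {
    condition <- match.arg(condition)
    set.seed(.childSeed(config@seed, 10L + replicate + 20L * (condition == "DKO")))
    n <- config@fragmentsPerReplicate
    sl <- seqlengths(bundle$sites)
    if (n == 0L)
        return(fragmentSet(GRanges(), paste0(condition, replicate), condition))
    sites <- bundle$sites
    bound <- if (condition == "WT") !mcols(sites)$gained else !mcols(sites)$lost
    nPhased <- round(config@phasedFraction * n)
    dyad <- numeric(0); chs <- character(0)
    if (nPhased > 0L && length(sites)) {
        si <- sample.int(length(sites), nPhased, replace = TRUE)
        kBound <- c(-5:-1, 1:5)
        kOpen <- -5:5
        k <- vapply(si, function(i)
            sample(if (bound[i]) kBound else kOpen, 1L), integer(1))
        dyad <- .centers(sites)[si] + k * config@nrl +
            rnorm(nPhased, 0, config@phasingSd)
        chs <- as.character(seqnames(sites))[si]
    }
    nBg <- n - length(dyad)
    if (nBg > 0L) {
        ci <- sample.int(length(sl), nBg, replace = TRUE, prob = as.numeric(sl))
        dyad <- c(dyad, runif(nBg, 1, as.numeric(sl)[ci]))
        chs <- c(chs, names(sl)[ci])
    }
    len <- pmin(pmax(round(rnorm(length(dyad), config@fragmentLengthMean,
                                 config@fragmentLengthSd)), 100L), 200L)
    st <- round(dyad - len / 2)
    en <- st + len - 1L
    lim <- as.numeric(sl[chs])
    st <- pmax(1, pmin(st, lim)); en <- pmax(1, pmin(en, lim))
    gr <- GRanges(chs, IRanges(as.integer(st), as.integer(en)))
    seqlengths(gr) <- sl[seqlevels(gr)]
    fragmentSet(sort(gr), paste0(condition, replicate), condition)
}

#' Simulate replicate CTCF peak sets
#'
#' Every planted site bound in a condition appears as a peak (centre +/-
#' \code{peakHalfWidth}, edges jittered per replicate) in each replicate of
#' that condition, except for false negatives dropped with probability
#' \code{pFn}. Lost sites are bound in WT only; gained sites in DKO only;
#' all other sites in both — so with pFn = 0 the replicate-consensus rule
#' recovers the planted partition exactly.
#'
#' @param bundle result of \code{\link{generateGenome}}.
#' @param config the \linkS4class{SyntheticConfig}.
#' @return List with \code{wt} and \code{dko}, each a list of GRanges (one
#'   per replicate).
#' @export
simulateCtcfPeaks <- function(bundle, config = bundle$config) {
    set.seed(.childSeed(config@seed, 3L))
    sites <- bundle$sites
    ctr <- .centers(sites)
    sl <- seqlengths(sites)
    mkRep <- function(boundIdx) {
        keep <- boundIdx[runif(length(boundIdx)) >= config@pFn]
        j1 <- round(rnorm(length(keep), 0, config@peakJitterSd))
        j2 <- round(rnorm(length(keep), 0, config@peakJitterSd))
        st <- pmax(1L, as.integer(ctr[keep] - config@peakHalfWidth + j1))
        en <- as.integer(ctr[keep] + config@peakHalfWidth + j2)
        en <- pmax(en, st + 50L)
        gr <- GRanges(as.character(seqnames(sites))[keep], IRanges(st, en))
        seqlengths(gr) <- sl[seqlevels(gr)]
        sort(gr)
    }
    wtBound <- which(!mcols(sites)$gained)
    dkoBound <- which(!mcols(sites)$lost)
    list(wt = lapply(seq_len(config@replicatesPerCondition), function(r) mkRep(wtBound)),
         dko = lapply(seq_len(config@replicatesPerCondition), function(r) mkRep(dkoBound)))
}

#' Simulate transcripts, TADs and loops with boundary-linked down-regulation
#'
#' TADs tile each chromosome; a TAD boundary is "lost" when a lost planted
#' CTCF site lies within \code{boundaryDist} of it. Chromatin loops connect
#' random pairs of TAD boundaries. Transcripts receive baseline up/down
#' probabilities; transcripts inside TADs with a lost boundary get their
#' down-regulation probability boosted by expressionDownregBoost scaled by
#' proximity to the lost boundary, and transcripts with a lost CTCF site in
#' their promoter get the full boost.
#'
#' @param bundle result of \code{\link{generateGenome}}.
#' @param config the \linkS4class{SyntheticConfig}.
#' @return List with \code{transcripts} (GRanges; mcols id, log2FC, signif),
#'   \code{tads}, \code{loops} (GRanges of loop anchors; mcols loopId,
#'   anchor), \code{promoters} (GRanges; mcol id), \code{boundaries} and
#'   \code{loopBoundaries} (GRanges; mcol lost), \code{downregulatedIds}.
#' @export
simulateExpression <- function(bundle, config = bundle$config) {
    set.seed(.childSeed(config@seed, 4L))
    sl <- seqlengths(bundle$sites)
    lostSites <- bundle$sites[mcols(bundle$sites)$lost]
    tadL <- list(); loopL <- list()
    for (ch in names(sl)) {
        k <- as.integer(sl[[ch]]) %/% config@tadWidth
        if (k < 1L) next
        st <- (seq_len(k) - 1L) * config@tadWidth + 1L
        tadL[[ch]] <- GRanges(ch, IRanges(st, width = config@tadWidth))
        bnd <- c(st, st[k] + config@tadWidth - 1L)
        nLoop <- max(1L, k %/% 2L)
        for (l in seq_len(nLoop)) {
            pair <- sort(sample(bnd, 2L))
            if (diff(pair) < config@tadWidth) next
            loopL[[length(loopL) + 1L]] <- GRanges(ch, IRanges(pair, width = 1L),
                loopId = paste0(ch, "_L", l), anchor = 1:2)
        }
    }
    tads <- suppressWarnings(do.call(c, unname(tadL)))
    loops <- if (length(loopL)) suppressWarnings(do.call(c, unname(loopL))) else
        GRanges(loopId = character(), anchor = integer())
    bndPts <- suppressWarnings(c(
        GRanges(seqnames(tads), IRanges(start(tads), width = 1L)),
        GRanges(seqnames(tads), IRanges(end(tads), width = 1L))))
    bndPts <- unique(bndPts)
    lostB <- countOverlaps(bndPts + config@boundaryDist, lostSites) > 0L
    mcols(bndPts)$lost <- lostB
    loopPts <- granges(loops)
    mcols(loopPts)$lost <- if (length(loopPts))
        countOverlaps(loopPts + config@boundaryDist, lostSites) > 0L else logical(0)
    ## transcripts
    n <- config@nTranscripts
    ci <- sample.int(length(sl), n, replace = TRUE, prob = as.numeric(sl))
    st <- vapply(ci, function(i)
        sample.int(as.integer(sl[[i]]) - config@transcriptLength, 1L), integer(1))
    strand_ <- sample(c("+", "-"), n, replace = TRUE)
    tx <- GRanges(names(sl)[ci], IRanges(st, width = config@transcriptLength),
                  strand = strand_, id = sprintf("T%04d", seq_len(n)))
    tss <- ifelse(strand_ == "+", start(tx), end(tx))
    promoters <- GRanges(seqnames(tx),
        IRanges(pmax(1L, tss - config@promoterFlank), tss + config@promoterFlank),
        id = mcols(tx)$id)
    ## down-regulation probability with boundary-proximity boost
    pDown <- rep(config@pDown, n)
    lostBnd <- bndPts[mcols(bndPts)$lost]
    lostTads <- tads[countOverlaps(tads + config@boundaryDist, lostSites) > 0L]
    inLost <- countOverlaps(tx, lostTads) > 0L
    if (any(inLost) && length(lostBnd)) {
        dB <- rep(NA_real_, n)
        nearest <- GenomicRanges::distanceToNearest(tx, lostBnd)
        dB[queryHits(nearest)] <- mcols(nearest)$distance
        w <- pmax(0, 1 - dB / (2 * config@boundaryDist))
        pDown[inLost] <- pDown[inLost] +
            config@expressionDownregBoost * (0.2 + 0.8 * w[inLost])
    }
    promLost <- countOverlaps(promoters, lostSites) > 0L
    pDown[promLost] <- config@pDown + config@expressionDownregBoost
    boosted <- inLost | promLost
    pDown <- pmin(pDown, 1 - config@pUp)
    u <- runif(n)
    signif <- ifelse(u < pDown, "down", ifelse(u < pDown + config@pUp, "up", "ns"))
    log2fc <- numeric(n)
    log2fc[signif == "down"] <- -runif(sum(signif == "down"), 0.5, 3)
    log2fc[signif == "up"] <- runif(sum(signif == "up"), 0.5, 3)
    log2fc[signif == "ns"] <- rnorm(sum(signif == "ns"), 0, 0.2)
    mcols(tx)$log2FC <- round(log2fc, 3)
    mcols(tx)$signif <- signif
    list(transcripts = tx, tads = tads, loops = loops, promoters = promoters,
         boundaries = bndPts, loopBoundaries = loopPts,
         downregulatedIds = mcols(tx)$id[boosted & config@expressionDownregBoost > 0])
}

#' Simulate the full synthetic epigenome
#'
#' Runs genome, methylome, nucleosome, peak and expression simulation in a
#' fixed order with per-step seeds derived from \code{config@seed}, and
#' assembles the \linkS4class{TruthManifest}. When \code{outdir} is given,
#' all analysis inputs are written as plain-text files (FASTA, BED, BEDPE,
#' TSV) plus the manifest as JSON — the ground truth is never encoded in the
#' analysis inputs themselves.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param motif \linkS4class{MotifModel} to plant.
#' @param outdir optional output directory.
#' @return List with \code{bundle}, \code{meth} (wt/dko/dmrs),
#'   \code{fragments} (list wt/dko of per-replicate FragmentSets),
#'   \code{peaks} (wt/dko replicate GRanges lists), \code{expression},
#'   \code{manifest} (\linkS4class{TruthManifest}).
#' @export
simulateEpigenome <- function(config = syntheticConfig(), motif = loadCtcfMotif(),
                              outdir = NULL) {
    bundle <- generateGenome(config, motif)
    meth <- simulateMethylomes(bundle, config)
    frags <- list(
        wt = lapply(seq_len(config@replicatesPerCondition), function(r)
            simulateNucleosomeFragments(bundle, config, "WT", r)),
        dko = lapply(seq_len(config@replicatesPerCondition), function(r)
            simulateNucleosomeFragments(bundle, config, "DKO", r)))
    peaks <- simulateCtcfPeaks(bundle, config)
    expr <- simulateExpression(bundle, config)
    manifest <- new("TruthManifest", sites = bundle$sites, dmrs = meth$dmrs,
                    nrlTrue = as.numeric(config@nrl),
                    boundaries = expr$boundaries,
                    loopBoundaries = expr$loopBoundaries,
                    downregulated = as.character(expr$downregulatedIds))
    out <- list(bundle = bundle, meth = meth, fragments = frags, peaks = peaks,
                expression = expr, manifest = manifest)
    if (!is.null(outdir)) writeEpigenome(out, outdir)
    out
}
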