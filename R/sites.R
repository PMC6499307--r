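## Replicate-consensus CTCF site categories, motif scanning within peaks and
## motif/flank CpG composition.

## Reciprocal overlap fraction between interval pairs given as vectors.
.reciprocalOverlap <- function(s1, e1, s2, e2) {
    inter <- pmin(e1, e2) - pmax(s1, s2) + 1L
    pmax(inter, 0L) / pmax(e1 - s1 + 1L, e2 - s2 + 1L)
}

#' Replicate-consensus common/lost/gained CTCF sites
#'
#' A site is "common" when a peak is present (reciprocal overlap at least
#' \code{minOverlap} with the site's core interval) in every WT and every DKO
#' replicate; "lost" when present in all WT replicates and absent from every
#' DKO replicate; "gained" when present in all DKO and absent from every WT
#' replicate. Peaks matching neither rule are "uncategorized". The reported
#' interval is the intersection of the matched replicate peaks. The result is
#' independent of the order in which replicates are supplied.
#'
#' @param wtReplicates,dkoReplicates lists of GRanges, one peak set per
#'   replicate.
#' @param minOverlap reciprocal overlap fraction for peak matching across
#'   replicates (default 0.5).
#' @return GRanges of candidate sites with mcols \code{category} (factor:
#'   common/lost/gained/uncategorized) and per-condition presence counts
#'   \code{nWt}, \code{nDko}.
#' @export
consensusSites <- function(wtReplicates, dkoReplicates, minOverlap = 0.5) {
    if (!length(wtReplicates) || !length(dkoReplicates))
        stop("need at least one replicate per condition")
    if (length(wtReplicates) < 2L || length(dkoReplicates) < 2L)
        warning("fewer than 2 replicates in a condition: consensus is weak")
    reps <- c(wtReplicates, dkoReplicates)
    isWt <- rep(c(TRUE, FALSE), c(length(wtReplicates), length(dkoReplicates)))
    pool <- suppressWarnings(do.call(c, unname(lapply(reps, granges))))
    if (!length(pool)) stop("all replicate peak sets are empty")
    cand <- reduce(pool)
    nCand <- length(cand)
    ## per replicate: the member peak with max overlap of each candidate
    memS <- matrix(NA_integer_, nCand, length(reps))
    memE <- matrix(NA_integer_, nCand, length(reps))
    for (r in seq_along(reps)) {
        hits <- findOverlaps(cand, reps[[r]])
        if (!length(hits)) next
        q <- queryHits(hits); s <- subjectHits(hits)
        ov <- pmin(end(cand)[q], end(reps[[r]])[s]) -
              pmax(start(cand)[q], start(reps[[r]])[s]) + 1L
        ord <- order(q, -ov)
        first <- !duplicated(q[ord])
        memS[q[ord][first], r] <- start(reps[[r]])[s[ord][first]]
        memE[q[ord][first], r] <- end(reps[[r]])[s[ord][first]]
    }
    ## core = intersection of matched peaks (symmetric in replicate order)
    coreS <- suppressWarnings(apply(memS, 1L, function(x)
        if (all(is.na(x))) NA_integer_ else max(x, na.rm = TRUE)))
    coreE <- suppressWarnings(apply(memE, 1L, function(x)
        if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE)))
    present <- matrix(FALSE, nCand, length(reps))
    okCore <- !is.na(coreS) & !is.na(coreE) & coreS <= coreE
    for (r in seq_along(reps)) {
        has <- !is.na(memS[, r]) & okCore
        f <- rep(0, nCand)
        f[has] <- .reciprocalOverlap(memS[has, r], memE[has, r],
                                     coreS[has], coreE[has])
        present[, r] <- has & f >= minOverlap
    }
    allWt <- rowSums(present[, isWt, drop = FALSE]) == sum(isWt)
    anyWt <- rowSums(present[, isWt, drop = FALSE]) > 0L
    allDko <- rowSums(present[, !isWt, drop = FALSE]) == sum(!isWt)
    anyDko <- rowSums(present[, !isWt, drop = FALSE]) > 0L
    category <- rep("uncategorized", nCand)
    category[allWt & allDko] <- "common"
    category[allWt & !anyDko] <- "lost"
    category[allDko & !anyWt] <- "gained"
    outS <- ifelse(okCore, coreS, start(cand))
    outE <- ifelse(okCore, coreE, end(cand))
    GRanges(seqnames(cand), IRanges(outS, outE),
            category = factor(category,
                levels = c("common", "lost", "gained", "uncategorized")),
            nWt = as.integer(rowSums(present[, isWt, drop = FALSE])),
            nDko = as.integer(rowSums(present[, !isWt, drop = FALSE])))
}

## Log-odds scores of all windows on one strand (uniform 0.25 background).
.logOddsScores <- function(code, motif) {
    L2 <- log2(motifProb(motif) / 0.25)
    w <- ncol(L2)
    nw <- length(code) - w + 1L
    if (nw < 1L) return(numeric(0))
    L2rc <- L2[4:1, w:1, drop = FALSE]
    sP <- numeric(nw); sM <- numeric(nw); bad <- logical(nw)
    for (j in seq_len(w)) {
        cj <- code[j:(j + nw - 1L)]
        nas <- is.na(cj)
        if (any(nas)) { bad <- bad | nas; cj[nas] <- 1L }
        sP <- sP + L2[cbind(cj, j)]
        sM <- sM + L2rc[cbind(cj, j)]
    }
    sP[bad] <- -Inf; sM[bad] <- -Inf
    list(plus = sP, minus = sM)
}

#' Scan peaks for motif matches
#'
#' Scores every window of motif width on both strands inside each peak with a
#' log-odds score against a uniform background and reports windows scoring at
#' least \code{threshold} times the maximum attainable score. Each match is
#' reported on the strand of its better-scoring orientation (ties to "+") and
#' inherits its parent peak's category.
#'
#' @param peaks GRanges of peaks (with optional mcol \code{category}).
#' @param genome DNAStringSet.
#' @param motif a \linkS4class{MotifModel}.
#' @param threshold fraction of the maximum attainable log-odds score
#'   (default 0.8); matches require score >= threshold * maxScore.
#' @return GRanges of motif-width sites with mcols \code{score},
#'   \code{category}, \code{peak} (index of the parent peak).
#' @export
scanMotifs <- function(peaks, genome, motif, threshold = 0.8) {
    w <- motifWidth(motif)
    L2 <- log2(motifProb(motif) / 0.25)
    maxScore <- sum(apply(L2, 2L, max))
    cut <- threshold * maxScore
    cat_ <- if ("category" %in% colnames(mcols(peaks)))
        as.character(mcols(peaks)$category) else rep(NA_character_, length(peaks))
    out <- list()
    for (i in seq_along(peaks)) {
        ch <- as.character(seqnames(peaks)[i])
        if (!ch %in% names(genome)) next
        s <- max(1L, start(peaks)[i]); e <- min(length(genome[[ch]]), end(peaks)[i])
        if (e - s + 1L < w) next
        code <- .seqToCode(subseq(genome[[ch]], s, e))
        sc <- .logOddsScores(code, motif)
        best <- pmax(sc$plus, sc$minus)
        hit <- which(best >= cut)
        if (!length(hit)) next
        out[[length(out) + 1L]] <- GRanges(ch,
            IRanges(s + hit - 1L, width = w),
            strand = ifelse(sc$plus[hit] >= sc$minus[hit], "+", "-"),
            score = best[hit], category = cat_[i], peak = i)
    }
    if (!length(out))
        return(GRanges(score = numeric(), category = character(), peak = integer()))
    res <- do.call(c, out)
    mcols(res)$category <- factor(mcols(res)$category,
        levels = c("common", "lost", "gained", "uncategorized"))
    res
}

#' CpG and nucleotide composition of motif sites and their flanks
#'
#' Per category of motif-level sites: the fraction of motifs containing at
#' least one CG dinucleotide, the CpG density (CpGs per kb) in the
#' \code{flank}-bp flanks on both sides, and the strand-oriented per-position
#' A/C/G/T frequency matrix over +/- \code{profileFlank} bp around motif
#' centres. Sites at contig edges contribute truncated (masked) flanks.
#'
#' @param sites GRanges of motif sites with mcols \code{category} and strand.
#' @param genome DNAStringSet.
#' @param flank flank size for CpG density (bp, each side; default 500).
#' @param profileFlank half-width of the nucleotide frequency profile
#'   (default 2000).
#' @return List with \code{summary} (data.frame: category, n, fractionWithCpG,
#'   meanFlankCpgDensity) and \code{nucleotideFreq} (list per category of
#'   4 x (2*profileFlank+1) frequency matrices; columns sum to 1 where data
#'   exist).
#' @export
siteCpgComposition <- function(sites, genome, flank = 500L, profileFlank = 2000L) {
    cats <- levels(droplevels(factor(mcols(sites)$category)))
    summ <- list(); freq <- list()
    for (cat_ in cats) {
        sel <- sites[which(mcols(sites)$category == cat_)]
        if (!length(sel)) next
        hasCpg <- logical(length(sel))
        dens <- numeric(length(sel))
        counts <- matrix(0, 4L, 2L * profileFlank + 1L,
                         dimnames = list(.BASES, NULL))
        for (i in seq_along(sel)) {
            ch <- as.character(seqnames(sel)[i])
            chromSeq <- genome[[ch]]
            s <- start(sel)[i]; e <- end(sel)[i]
            motifSeq <- as.character(subseq(chromSeq, max(1L, s), min(length(chromSeq), e)))
            hasCpg[i] <- grepl("CG", motifSeq, fixed = TRUE)
            fs <- max(1L, s - flank); fe <- min(length(chromSeq), e + flank)
            flankSeq <- as.character(subseq(chromSeq, fs, fe))
            nCpg <- lengths(regmatches(flankSeq, gregexpr("CG", flankSeq, fixed = TRUE)))
            dens[i] <- 1000 * nCpg / (fe - fs + 1L)
            ctr <- (s + e) %/% 2L
            ps <- max(1L, ctr - profileFlank); pe <- min(length(chromSeq), ctr + profileFlank)
            code <- .seqToCode(subseq(chromSeq, ps, pe))
            offs <- (ps:pe) - ctr
            if (as.character(strand(sel)[i]) == "-") { offs <- -offs; code <- 5L - code }
            cols <- offs + profileFlank + 1L
            ok <- !is.na(code)
            idx <- cbind(code[ok], cols[ok])
            counts[idx] <- counts[idx] + 1L
        }
        colSumsC <- colSums(counts)
        fmat <- sweep(counts, 2L, pmax(colSumsC, 1), "/")
        fmat[, colSumsC == 0] <- NA_real_
        summ[[cat_]] <- data.frame(category = cat_, n = length(sel),
            fractionWithCpG = mean(hasCpg), meanFlankCpgDensity = mean(dens))
        freq[[cat_]] <- fmat
    }
    list(summary = do.call(rbind, summ), nucleotideFreq = freq)
}
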