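## Feature fold enrichment, predictors of CTCF loss with ROC/AUC, and
## expression-change linkage to lost boundaries.

#' Fold enrichment of query elements at a genomic feature
#'
#' Counts query elements overlapping the feature by at least 1 bp. The
#' analytic expectation places each query element at a uniformly random
#' position: expected = n_query x (feature bp / genome size). The permutation
#' method instead re-places the query elements uniformly at random
#' (length-preserving, chromosome-matched) \code{nPerm} times and reports the
#' empirical expectation and a two-sided-safe upper p-value for enrichment.
#'
#' @param query,feature GRanges on the same genome.
#' @param seqlens named chromosome lengths (required for permutation and to
#'   compute the genome size; for \code{method = "analytic"} a single total
#'   genome size may be given).
#' @param method "analytic" or "permutation".
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed for permutation placement.
#' @return List: \code{observed}, \code{expected}, \code{fold},
#'   \code{percentOverlap} (observed / n_query x 100), \code{pValue}
#'   (permutation only).
#' @export
foldEnrichment <- function(query, feature, seqlens,
                           method = c("analytic", "permutation"),
                           nPerm = 1000L, seed = 1L) {
    method <- match.arg(method)
    genomeSize <- sum(as.numeric(seqlens))
    featBp <- sum(as.numeric(width(reduce(feature))))
    if (genomeSize <= featBp)
        stop("genome size must exceed feature coverage")
    nQ <- length(query)
    observed <- sum(countOverlaps(query, feature) > 0L)
    if (method == "analytic") {
        expected <- nQ * featBp / genomeSize
        pValue <- NA_real_
    } else {
        if (is.null(names(seqlens)))
            stop("permutation method needs named chromosome lengths")
        old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
        set.seed(seed)
        chs <- as.character(seqnames(query))
        wq <- width(query)
        counts <- vapply(seq_len(nPerm), function(b) {
            newStart <- vapply(seq_len(nQ), function(i) {
                L <- as.integer(seqlens[[chs[i]]])
                sample.int(max(1L, L - wq[i] + 1L), 1L)
            }, integer(1))
            rnd <- GRanges(chs, IRanges(newStart, width = wq))
            sum(countOverlaps(rnd, feature) > 0L)
        }, integer(1))
        if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
        expected <- mean(counts)
        pValue <- (1 + sum(counts >= observed)) / (nPerm + 1L)
    }
    if (expected == 0) expected <- NA_real_
    list(observed = observed, expected = expected,
         fold = observed / expected,
         percentOverlap = if (nQ > 0) 100 * observed / nQ else NA_real_,
         pValue = pValue)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the Mann-Whitney U statistic divided by n1*n0, with tied
#' scores counted half — identical to the probability that a random positive
#' outscores a random negative (ties split). The orientation is explicit:
#' \code{direction = ">"} treats higher scores as evidence for label 1,
#' \code{"<"} the opposite. No AUC >= 0.5 convention is forced; the value is
#' reported as-is.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical); both classes must be present.
#' @param direction ">" (higher score = positive, default) or "<".
#' @return List with \code{auc} and \code{roc}, a data.frame of (fpr, tpr)
#'   points ordered along the curve.
#' @examples
#' rocAUC(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
rocAUC <- function(scores, labels, direction = c(">", "<")) {
    direction <- match.arg(direction)
    labels <- as.integer(as.logical(labels))
    keep <- !is.na(scores) & !is.na(labels)
    scores <- scores[keep]; labels <- labels[keep]
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    s <- if (direction == ">") scores else -scores
    r <- rank(s, ties.method = "average")
    auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(labels[ord] == 1L); fp <- cumsum(labels[ord] == 0L)
    ## collapse tied thresholds
    lastOfTie <- c(diff(s[ord]) != 0, TRUE)
    roc <- data.frame(fpr = c(0, fp[lastOfTie] / n0), tpr = c(0, tp[lastOfTie] / n1))
    list(auc = auc, roc = roc)
}

#' Per-site predictor table for CTCF loss
#'
#' One row per motif site with the four predictors compared in the study:
#' the motif log-odds score, the change of nucleosome occupancy (DKO - WT
#' mean over the site +/- \code{occWindow}), the WT methylation level (mean
#' ratio over the site +/- \code{methWindow}), and the flank CpG density
#' (CpGs per kb over the 1000-bp region centred on the site, i.e. +/- 500 bp),
#' plus the binary label (lost = 1, common = 0). Sites of other categories
#' are dropped; predictors that cannot be computed are NA (masked).
#'
#' @param sites motif-level GRanges from \code{\link{scanMotifs}} (mcols
#'   \code{score}, \code{category}).
#' @param occupancyWt,occupancyDko \linkS4class{SignalTrack}s.
#' @param methWt a \linkS4class{MethylationTrack}.
#' @param genome DNAStringSet.
#' @param occWindow half-width for occupancy change (default 100 bp).
#' @param methWindow half-width for methylation level (default 100 bp).
#' @param cpgFlank half-width for flank CpG density (default 500 bp).
#' @return data.frame with columns motifScore, deltaNucOccupancy,
#'   methylationLevel, flankCpgDensity, label.
#' @export
buildPredictorTable <- function(sites, occupancyWt, occupancyDko, methWt,
                                genome, occWindow = 100L, methWindow = 100L,
                                cpgFlank = 500L) {
    sel <- mcols(sites)$category %in% c("common", "lost")
    sites <- sites[sel]
    if (!length(sites)) stop("no common/lost sites in input")
    ctr <- .centers(sites)
    chs <- as.character(seqnames(sites))
    meanOver <- function(track, half) {
        vals <- trackValues(track)
        vapply(seq_along(sites), function(i) {
            if (!chs[i] %in% names(vals)) return(NA_real_)
            v <- vals[[chs[i]]]
            s <- max(1L, ctr[i] - half); e <- min(length(v), ctr[i] + half)
            if (e < s) return(NA_real_)
            mean(as.numeric(v[s:e]), na.rm = TRUE)
        }, numeric(1))
    }
    dOcc <- meanOver(occupancyDko, occWindow) - meanOver(occupancyWt, occWindow)
    mgr <- methRecords(methWt)
    methLevel <- vapply(seq_along(sites), function(i) {
        win <- GRanges(chs[i], IRanges(max(1L, ctr[i] - methWindow), ctr[i] + methWindow))
        hits <- findOverlaps(win, mgr)
        if (!length(hits)) return(NA_real_)
        mean(mcols(mgr)$ratio[subjectHits(hits)], na.rm = TRUE)
    }, numeric(1))
    cpgDens <- vapply(seq_along(sites), function(i) {
        chromSeq <- genome[[chs[i]]]
        if (is.null(chromSeq)) return(NA_real_)
        s <- max(1L, ctr[i] - cpgFlank); e <- min(length(chromSeq), ctr[i] + cpgFlank)
        sq <- as.character(subseq(chromSeq, s, e))
        1000 * lengths(regmatches(sq, gregexpr("CG", sq, fixed = TRUE))) / (e - s + 1L)
    }, numeric(1))
    data.frame(motifScore = mcols(sites)$score,
               deltaNucOccupancy = dOcc,
               methylationLevel = methLevel,
               flankCpgDensity = cpgDens,
               label = as.integer(mcols(sites)$category == "lost"))
}

#' Expression change by CTCF/boundary category
#'
#' Assigns every transcript to each of the eight (overlapping) categories —
#' genome-wide; inside TADs; within \code{dist} of any loop boundary; within
#' \code{dist} of any TAD boundary; inside TADs that lost a boundary (a
#' boundary is lost when a lost CTCF site lies within \code{dist} of it);
#' within \code{dist} of a lost loop boundary; within \code{dist} of a lost
#' TAD boundary; lost CTCF site in the promoter — and tabulates up- and
#' down-regulated transcripts per category, the down/up ratio, and a 2x2
#' chi-square (no continuity correction) of (up, down) against the
#' genome-wide category.
#'
#' @param transcripts GRanges with mcols \code{id} and \code{signif} (factor
#'   or character: "up", "down", "ns").
#' @param tads GRanges of TADs (boundaries = TAD endpoints).
#' @param loops GRanges of loop anchors (both anchors of each loop, e.g. from
#'   \code{\link{readBedpe}}), or NULL.
#' @param lostSites GRanges of lost CTCF sites.
#' @param promoters GRanges of promoter windows, named by transcript id
#'   (mcol \code{id}); a transcript is in the last category when a lost site
#'   overlaps its own promoter.
#' @param dist boundary distance in bp (default 10000).
#' @return data.frame, one row per category: category, nTotal, nUp, nDown,
#'   downUpRatio, chisq, pValue.
#' @export
expressionLinkage <- function(transcripts, tads, loops, lostSites, promoters,
                              dist = 10000L) {
    sig <- as.character(mcols(transcripts)$signif)
    boundaryPoints <- function(doms) {
        if (is.null(doms) || !length(doms)) return(GRanges())
        suppressWarnings(c(GRanges(seqnames(doms), IRanges(start(doms), width = 1L)),
                           GRanges(seqnames(doms), IRanges(end(doms), width = 1L))))
    }
    lostFlag <- function(bnd) {
        if (!length(bnd)) return(logical(0))
        countOverlaps(bnd + dist, lostSites) > 0L
    }
    tadBnd <- boundaryPoints(tads)
    tadBndLost <- lostFlag(tadBnd)
    loopBnd <- if (is.null(loops) || !length(loops)) GRanges() else
        GRanges(seqnames(loops), IRanges(.centers(loops), width = 1L))
    loopBndLost <- lostFlag(loopBnd)
    near <- function(bnd) {
        if (!length(bnd)) return(rep(FALSE, length(transcripts)))
        countOverlaps(transcripts, bnd + dist) > 0L
    }
    inTads <- countOverlaps(transcripts, tads) > 0L
    lostTads <- tads[unique(queryHits(findOverlaps(tads,
        if (length(tadBnd)) tadBnd[tadBndLost] else GRanges())))]
    inLostTads <- countOverlaps(transcripts, lostTads) > 0L
    lostProm <- if (length(promoters))
        mcols(promoters)$id[countOverlaps(promoters, lostSites) > 0L] else character(0)
    promoterLost <- mcols(transcripts)$id %in% lostProm
    members <- list(
        genome_wide = rep(TRUE, length(transcripts)),
        inside_tads = inTads,
        near_loop_boundary = near(loopBnd),
        near_tad_boundary = near(tadBnd),
        inside_lost_tads = inLostTads,
        near_lost_loop_boundary = near(if (length(loopBnd)) loopBnd[loopBndLost] else GRanges()),
        near_lost_tad_boundary = near(if (length(tadBnd)) tadBnd[tadBndLost] else GRanges()),
        lost_ctcf_at_promoter = promoterLost)
    gwUp <- sum(sig == "up"); gwDown <- sum(sig == "down")
    rows <- lapply(names(members), function(nm) {
        m <- members[[nm]]
        nUp <- sum(sig[m] == "up"); nDown <- sum(sig[m] == "down")
        if (nm == "genome_wide" || (nUp + nDown) == 0L || (gwUp + gwDown) == 0L) {
            chi <- NA_real_; p <- NA_real_
        } else {
            tab <- rbind(c(gwUp, gwDown), c(nUp, nDown))
            ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
            chi <- unname(ct$statistic); p <- ct$p.value
        }
        data.frame(category = nm, nTotal = sum(m), nUp = nUp, nDown = nDown,
                   downUpRatio = if (nUp > 0) nDown / nUp else NA_real_,
                   chisq = chi, pValue = p)
    })
    do.call(rbind, rows)
}
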