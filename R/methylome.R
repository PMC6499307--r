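## Per-CpG methylation: class assignment, landscape smoothing, DMR calling
## and anchor-relative methylation profiles.

#' Classify CpGs by their methylation change between two conditions
#'
#' Thresholds follow the standard WT/DKO class definitions:
#' \itemize{
#'   \item common_methylated: ratio >= 0.8 in both conditions;
#'   \item gained: < 0.2 in WT and > 0.5 in DKO;
#'   \item lost: > 0.5 in WT and < 0.2 in DKO;
#'   \item unmethylated: < 0.2 in both;
#'   \item other: any remaining combination.
#' }
#' Boundary semantics are as printed: the 0.8 threshold is inclusive, the
#' 0.2/0.5 thresholds strict. Pairs with a missing ratio return \code{NA}
#' (unclassified), not an error.
#'
#' @param mWt,mDko methylation ratios in WT and DKO (vectorised).
#' @param tLow,tMid,tHighCommon class thresholds (defaults 0.2, 0.5, 0.8).
#' @return Factor with levels common_methylated, gained, lost, unmethylated,
#'   other.
#' @examples
#' classifyCpG(c(0.9, 0.1, 0.6, 0.1, 0.3), c(0.85, 0.6, 0.1, 0.1, 0.3))
#' @export
classifyCpG <- function(mWt, mDko, tLow = 0.2, tMid = 0.5, tHighCommon = 0.8) {
    stopifnot(length(mWt) == length(mDko))
    lev <- c("common_methylated", "gained", "lost", "unmethylated", "other")
    out <- rep(NA_character_, length(mWt))
    ok <- !is.na(mWt) & !is.na(mDko)
    out[ok & mWt >= tHighCommon & mDko >= tHighCommon] <- "common_methylated"
    rest <- ok & is.na(out)
    out[rest & mWt < tLow & mDko > tMid] <- "gained"
    rest <- ok & is.na(out)
    out[rest & mWt > tMid & mDko < tLow] <- "lost"
    rest <- ok & is.na(out)
    out[rest & mWt < tLow & mDko < tLow] <- "unmethylated"
    out[ok & is.na(out)] <- "other"
    factor(out, levels = lev)
}

## Window machinery shared by smoothing and DMR calling: cumulative sums of
## per-CpG ratios over sliding windows, O(n log n) per chromosome.
.windowStats <- function(pos, ratio, starts, window) {
    o <- order(pos)
    pos <- pos[o]; ratio <- ratio[o]
    cs <- c(0, cumsum(ratio))
    cn <- c(0, seq_along(ratio))
    i0 <- findInterval(starts - 1L, pos)          # last CpG before window
    i1 <- findInterval(starts + window - 1L, pos) # last CpG inside window
    n <- cn[i1 + 1L] - cn[i0 + 1L]
    s <- cs[i1 + 1L] - cs[i0 + 1L]
    list(n = n, mean = ifelse(n > 0, s / n, NA_real_))
}

.trackChromLen <- function(track) {
    gr <- methRecords(track)
    sl <- seqlengths(gr)
    lens <- lapply(seqlevels(gr), function(ch) {
        if (!is.na(sl[ch])) return(as.integer(sl[ch]))
        p <- end(gr[seqnames(gr) == ch])
        if (length(p)) max(p) else 0L
    })
    setNames(as.integer(lens), seqlevels(gr))
}

#' Smooth a methylation track with a sliding window
#'
#' Per-window unweighted mean of the methylation ratios of covered CpGs;
#' windows containing no covered CpG are dropped (missing). Used to draw the
#' 500-bp smoothed methylation landscapes on which bifurcation points are
#' visible.
#'
#' @param track a \linkS4class{MethylationTrack}.
#' @param window window size in bp (default 500).
#' @param step window step in bp (default \code{window}, i.e. tiling; must be
#'   <= window and >= 1).
#' @param minCov minimum coverage for a CpG to count (default 1).
#' @return GRanges of windows with mcols \code{score} (mean ratio) and
#'   \code{nCpgs}.
#' @export
smoothMethylation <- function(track, window = 500L, step = window, minCov = 1L) {
    if (step < 1L || window < step) stop("require window >= step >= 1")
    gr <- methRecords(track)
    gr <- gr[mcols(gr)$coverage >= minCov]
    lens <- .trackChromLen(track)
    res <- lapply(names(lens), function(ch) {
        if (lens[[ch]] < window) return(GRanges())
        sel <- as.vector(seqnames(gr) == ch)
        starts <- seq.int(1L, lens[[ch]] - window + 1L, by = step)
        st <- .windowStats(start(gr)[sel], mcols(gr)$ratio[sel], starts, window)
        keep <- st$n > 0
        if (!any(keep)) return(GRanges())
        GRanges(ch, IRanges(starts[keep], width = window),
                score = st$mean[keep], nCpgs = st$n[keep])
    })
    out <- suppressWarnings(do.call(c, res))
    out
}

#' Call differentially methylated regions between two conditions
#'
#' Slides a window along each chromosome; a window qualifies when it contains
#' at least \code{minCpgs} CpGs covered at \code{minCov} or more in both
#' conditions and its mean methylation deviates between the conditions by
#' strictly more than \code{delta}. Overlapping or adjacent qualified windows
#' of the same direction are merged; the merged interval's means are
#' recomputed and the deviation criterion re-verified.
#'
#' Only CpGs covered adequately in both conditions enter the window means, so
#' the two conditions are compared over the same positions.
#'
#' @param wt,dko \linkS4class{MethylationTrack}s on the same genome.
#' @param window window size in bp (default 1000).
#' @param step window step in bp (default 100; must be <= window).
#' @param delta minimum absolute methylation difference (strict; default 0.10).
#' @param minCpgs minimum qualifying CpGs per window (default 4).
#' @param minCov minimum per-CpG coverage in each condition (default 4).
#' @return GRanges of DMRs with mcols \code{direction} ("gain" = higher in
#'   DKO, "loss"), \code{meanWt}, \code{meanDko}, \code{nCpgs}, \code{delta}.
#' @export
callDMRs <- function(wt, dko, window = 1000L, step = 100L, delta = 0.10,
                     minCpgs = 4L, minCov = 4L) {
    if (window < step) stop("window must be >= step")
    grW <- methRecords(wt); grD <- methRecords(dko)
    lens <- .trackChromLen(wt)
    out <- list()
    for (ch in names(lens)) {
        if (lens[[ch]] < window) next
        w <- grW[seqnames(grW) == ch & mcols(grW)$coverage >= minCov]
        d <- grD[seqnames(grD) == ch & mcols(grD)$coverage >= minCov]
        common <- intersect(start(w), start(d))
        if (length(common) < minCpgs) next
        rw <- mcols(w)$ratio[match(common, start(w))]
        rd <- mcols(d)$ratio[match(common, start(d))]
        o <- order(common); common <- common[o]; rw <- rw[o]; rd <- rd[o]
        starts <- seq.int(1L, lens[[ch]] - window + 1L, by = step)
        sw <- .windowStats(common, rw, starts, window)
        sd_ <- .windowStats(common, rd, starts, window)
        diff <- sd_$mean - sw$mean
        ## strict "> delta" with a float guard so a deviation of exactly
        ## delta is never called
        eps <- 1e-9
        qual <- sw$n >= minCpgs & !is.na(diff) & abs(diff) > delta + eps
        if (!any(qual)) next
        cand <- list()
        for (dir in c("gain", "loss")) {
            sel <- qual & (if (dir == "gain") diff > 0 else diff < 0)
            if (!any(sel)) next
            merged <- reduce(IRanges(starts[sel], width = window), min.gapwidth = 1L)
            cand[[dir]] <- merged
        }
        ## opposite-direction regions may touch across a sharp transition;
        ## split the overlap at its midpoint so DMRs stay disjoint
        if (length(cand) == 2L) {
            og <- findOverlaps(cand$gain, cand$loss)
            for (h in seq_along(og)) {
                i <- queryHits(og)[h]; j <- subjectHits(og)[h]
                mid <- (max(start(cand$gain)[i], start(cand$loss)[j]) +
                        min(end(cand$gain)[i], end(cand$loss)[j])) %/% 2L
                if (start(cand$gain)[i] <= start(cand$loss)[j]) {
                    end(cand$gain)[i] <- mid
                    start(cand$loss)[j] <- mid + 1L
                } else {
                    end(cand$loss)[j] <- mid
                    start(cand$gain)[i] <- mid + 1L
                }
            }
        }
        ## recompute means over final intervals and re-verify the criterion
        for (dir in names(cand)) {
            merged <- cand[[dir]]
            for (k in seq_along(merged)) {
                s <- start(merged)[k]; e <- end(merged)[k]
                idx <- common >= s & common <= e
                mW <- mean(rw[idx]); mD <- mean(rd[idx])
                if (sum(idx) >= minCpgs && abs(mD - mW) > delta + eps &&
                    sign(mD - mW) == (if (dir == "gain") 1 else -1)) {
                    out[[length(out) + 1L]] <- GRanges(ch, IRanges(s, e),
                        direction = dir, meanWt = mW, meanDko = mD,
                        nCpgs = sum(idx), delta = mD - mW)
                }
            }
        }
    }
    if (!length(out))
        return(GRanges(direction = character(), meanWt = numeric(),
                       meanDko = numeric(), nCpgs = integer(), delta = numeric()))
    sort(do.call(c, out))
}

#' Average methylation as a function of distance from anchors
#'
#' For each relative offset d in [-flank, flank], the mean methylation ratio
#' over all covered CpGs found at that offset from an anchor centre, across
#' all anchors. Minus-strand anchors contribute with mirrored offsets. In
#' \code{mode = "relative"} the profile is divided by its own mean over the
#' full window, so two conditions plotted together are normalised in the same
#' way.
#'
#' @param tracks a \linkS4class{MethylationTrack} or named list of them.
#' @param anchors GRanges of anchors (centres used; strand respected).
#' @param flank half-width of the window (bp).
#' @param mode "absolute" or "relative".
#' @param minCov minimum CpG coverage (default 1).
#' @return A \linkS4class{Profile} (or named list, one per input track).
#' @export
methylationProfile <- function(tracks, anchors, flank = 1000L,
                               mode = c("absolute", "relative"), minCov = 1L) {
    mode <- match.arg(mode)
    if (length(anchors) == 0L) stop("anchor set is empty")
    single <- is(tracks, "MethylationTrack")
    if (single) tracks <- list(track = tracks)
    res <- lapply(names(tracks), function(nm) {
        gr <- methRecords(tracks[[nm]])
        gr <- gr[mcols(gr)$coverage >= minCov]
        ctr <- .centers(anchors)
        win <- GRanges(seqnames(anchors), IRanges(pmax(1L, ctr - flank), ctr + flank))
        hits <- findOverlaps(win, gr)
        d <- start(gr)[subjectHits(hits)] - ctr[queryHits(hits)]
        neg <- as.vector(strand(anchors) == "-")[queryHits(hits)]
        d[neg] <- -d[neg]
        keep <- abs(d) <= flank
        d <- d[keep]
        r <- mcols(gr)$ratio[subjectHits(hits)][keep]
        idx <- d + flank + 1L
        np <- 2L * flank + 1L
        sums <- rowsum(r, idx)
        cnts <- rowsum(rep(1, length(idx)), idx)
        mean_ <- rep(NA_real_, np)
        mean_[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
        if (mode == "relative") {
            g <- mean(mean_, na.rm = TRUE)
            if (!is.finite(g) || g == 0) stop("cannot normalise a flat-zero profile")
            mean_ <- mean_ / g
        }
        new("Profile", positions = seq.int(-flank, flank),
            repMeans = matrix(mean_, ncol = 1), mean = mean_,
            sd = rep(0, np), nAnchors = length(anchors),
            signalLabel = paste0("methylation[", condition(tracks[[nm]]), "]"),
            anchorLabel = "anchors")
    })
    names(res) <- names(tracks)
    if (single) res[[1]] else res
}
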