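## Nucleosome occupancy from paired-end mononucleosome fragments, differential
## occupancy regions and fragment-overlap shift classes.

#' Per-bp nucleosome occupancy from fragments
#'
#' value(x) = number of fragments covering position x, optionally scaled.
#' Multiple replicates are merged additively before scaling, so two identical
#' replicates give the same per-million track as one.
#'
#' @param frags a \linkS4class{FragmentSet} or list of them (replicates).
#' @param normalization "per-million" (default; per 1e6 fragments), "raw"
#'   (fragment counts), or "mean-scaled" (divided by the genome-wide mean).
#' @param seqlengths optional named chromosome lengths; defaults to those of
#'   the fragments (or max end).
#' @return A \linkS4class{SignalTrack}.
#' @export
occupancyTrack <- function(frags, normalization = c("per-million", "raw", "mean-scaled"),
                           seqlengths = NULL) {
    normalization <- match.arg(normalization)
    if (is(frags, "FragmentSet")) frags <- list(frags)
    gr <- suppressWarnings(do.call(c, unname(lapply(frags, fragments))))
    n <- length(gr)
    if (n == 0L) {
        warning("empty fragment set: returning zero track")
        lens <- if (is.null(seqlengths)) c(chr = 0L) else seqlengths
        vals <- as(lapply(lens, function(l) Rle(0, l)), "RleList")
        return(new("SignalTrack", values = vals, normalization = normalization))
    }
    if (is.null(seqlengths)) {
        sl <- seqlengths(gr)
        if (anyNA(sl)) {
            sl <- vapply(split(end(gr), as.character(seqnames(gr))), max, 0)
        }
        seqlengths <- sl
    }
    cov <- lapply(names(seqlengths), function(ch) {
        ir <- IRanges(start(gr)[as.vector(seqnames(gr) == ch)],
                      end(gr)[as.vector(seqnames(gr) == ch)])
        ir <- restrict(ir, start = 1L, end = as.integer(seqlengths[[ch]]))
        coverage(ir, width = as.integer(seqlengths[[ch]]))
    })
    names(cov) <- names(seqlengths)
    scale <- switch(normalization,
        "raw" = 1,
        "per-million" = 1e6 / n,
        "mean-scaled" = {
            tot <- sum(as.numeric(vapply(cov, function(v) sum(as.numeric(v)), 0)))
            len <- sum(as.numeric(vapply(cov, length, 0L)))
            if (tot == 0) 1 else len / tot
        })
    vals <- as(lapply(cov, function(v) v * scale), "RleList")
    new("SignalTrack", values = vals, normalization = normalization)
}

#' Differential nucleosome occupancy between two conditions
#'
#' Tiles each chromosome with windows (default 100 bp, non-overlapping),
#' computes mean WT and DKO occupancy per window, and calls windows with
#' sufficient signal and an absolute log2 ratio of at least
#' \code{log2Threshold} as "gained" (higher in DKO) or "lost". Adjacent
#' same-direction windows are merged; each region's means are recomputed over
#' the merged interval. Swapping the two inputs swaps the gained/lost labels.
#'
#' The signal floor and the log2 threshold are tunable because no canonical
#' values exist for them; defaults are a 2-fold change with at least half the
#' genome-mean occupancy in the higher condition.
#'
#' @param wt,dko \linkS4class{SignalTrack}s with identical normalization.
#' @param window window size in bp (default 100).
#' @param step window step (default \code{window}: non-overlapping tiles).
#' @param minSignal minimum of max(meanWT, meanDKO) for a window to be
#'   considered; default 0.5 x the pooled genome-mean occupancy.
#' @param log2Threshold minimum |log2(DKO/WT)| (default 1).
#' @return GRanges of change regions with mcols \code{direction} ("gained" or
#'   "lost"), \code{wtMean}, \code{dkoMean}.
#' @export
differentialOccupancy <- function(wt, dko, window = 100L, step = window,
                                  minSignal = NULL, log2Threshold = 1) {
    if (wt@normalization != dko@normalization)
        stop("tracks have different normalizations: ", wt@normalization,
             " vs ", dko@normalization)
    vw <- trackValues(wt); vd <- trackValues(dko)
    chroms <- intersect(names(vw), names(vd))
    if (is.null(minSignal)) {
        pooled <- mean(c(vapply(vw[chroms], function(v) mean(as.numeric(v)), 0),
                         vapply(vd[chroms], function(v) mean(as.numeric(v)), 0)))
        minSignal <- 0.5 * pooled
    }
    out <- list()
    for (ch in chroms) {
        n <- min(length(vw[[ch]]), length(vd[[ch]]))
        if (n < window) next
        starts <- seq.int(1L, n - window + 1L, by = step)
        csW <- c(0, cumsum(as.numeric(vw[[ch]][1:n])))
        csD <- c(0, cumsum(as.numeric(vd[[ch]][1:n])))
        mW <- (csW[starts + window] - csW[starts]) / window
        mD <- (csD[starts + window] - csD[starts]) / window
        elig <- pmax(mW, mD) >= minSignal
        lr <- log2(mD / mW)  # Inf when one side is 0
        gained <- elig & (mD > mW) & (mW == 0 | lr >= log2Threshold)
        lost <- elig & (mD < mW) & (mD == 0 | lr <= -log2Threshold)
        for (dir in c("gained", "lost")) {
            sel <- if (dir == "gained") gained else lost
            if (!any(sel)) next
            merged <- reduce(IRanges(starts[sel], width = window), min.gapwidth = 1L)
            s <- start(merged); e <- end(merged)
            wtMean <- (csW[e + 1L] - csW[s]) / (e - s + 1L)
            dkoMean <- (csD[e + 1L] - csD[s]) / (e - s + 1L)
            out[[length(out) + 1L]] <- GRanges(ch, merged, direction = dir,
                                               wtMean = wtMean, dkoMean = dkoMean)
        }
    }
    if (!length(out))
        return(GRanges(direction = character(), wtMean = numeric(), dkoMean = numeric()))
    sort(do.call(c, out))
}

#' Classify WT nucleosome fragments by overlap with their DKO partner
#'
#' For each WT fragment, the DKO fragment maximising the reciprocal overlap
#' fraction f = |intersection| / max(length(WT), length(partner)) is taken as
#' its partner. Classes follow the published overlap cut-offs: "stable_95"
#' (f > 0.95), "shifted_5" (f < 0.95, i.e. boundaries changed by > 5%),
#' "shifted_30" (additionally f < 0.70), and "unmatched" (no overlapping DKO
#' fragment). The logical columns \code{shifted5}/\code{shifted30} expose the
#' nesting (every shifted_30 fragment is also shifted by > 5%).
#'
#' @param wtFrags,dkoFrags \linkS4class{FragmentSet}s.
#' @return DataFrame with one row per WT fragment: \code{partner} (index into
#'   the DKO set or NA), \code{overlap} (f), \code{class},
#'   \code{shifted5}, \code{shifted30}.
#' @export
classifyFragmentShift <- function(wtFrags, dkoFrags) {
    w <- fragments(wtFrags); d <- fragments(dkoFrags)
    nW <- length(w)
    partner <- rep(NA_integer_, nW)
    f <- rep(NA_real_, nW)
    if (nW && length(d)) {
        hits <- findOverlaps(w, d)
        if (length(hits)) {
            q <- queryHits(hits); s <- subjectHits(hits)
            inter <- pmin(end(w)[q], end(d)[s]) - pmax(start(w)[q], start(d)[s]) + 1L
            frac <- inter / pmax(width(w)[q], width(d)[s])
            ord <- order(q, -frac)
            first <- !duplicated(q[ord])
            partner[q[ord][first]] <- s[ord][first]
            f[q[ord][first]] <- frac[ord][first]
        }
    }
    cls <- rep("unmatched", nW)
    cls[!is.na(f) & f > 0.95] <- "stable_95"
    cls[!is.na(f) & f < 0.95 & f >= 0.70] <- "shifted_5"
    cls[!is.na(f) & f == 0.95] <- "shifted_5"
    cls[!is.na(f) & f < 0.70] <- "shifted_30"
    DataFrame(partner = partner, overlap = f,
              class = factor(cls, levels = c("stable_95", "shifted_5",
                                             "shifted_30", "unmatched")),
              shifted5 = !is.na(f) & f < 0.95,
              shifted30 = !is.na(f) & f < 0.70)
}
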