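## Anchor-centred average profiles, cross-condition normalization and
## profile clustering with asymmetry scoring.

.extractWindows <- function(values, anchors, flank) {
    ## rows = anchors, cols = offsets -flank..flank; NA outside contigs
    np <- 2L * flank + 1L
    out <- matrix(NA_real_, length(anchors), np)
    ctr <- .centers(anchors)
    chs <- as.character(seqnames(anchors))
    for (ch in unique(chs)) {
        if (!ch %in% names(values)) next
        v <- as.numeric(values[[ch]])
        idx <- which(chs == ch)
        for (i in idx) {
            s <- ctr[i] - flank; e <- ctr[i] + flank
            ss <- max(1L, s); ee <- min(length(v), e)
            if (ee < ss) next
            out[i, (ss - s + 1L):(ss - s + ee - ss + 1L)] <- v[ss:ee]
        }
    }
    neg <- as.vector(strand(anchors) == "-")
    if (any(neg)) out[neg, ] <- out[neg, np:1, drop = FALSE]
    out
}

#' Average signal around anchors, with replicate averaging
#'
#' Computes the mean signal at each offset in [-flank, flank] from the anchor
#' centres, independently for each replicate, then reports the
#' cross-replicate mean and sample standard deviation (n-1 denominator) of
#' those replicate profiles. Minus-strand anchors are mirrored so profiles
#' are orientation-aware.
#'
#' @param signal a \linkS4class{SignalTrack}, \linkS4class{AffinityTrack} or
#'   \linkS4class{MethylationTrack}, or a list of them (replicates).
#' @param anchors GRanges (non-empty).
#' @param flank half-width in bp (> 0).
#' @param signalLabel,anchorLabel labels stored in the result.
#' @return A \linkS4class{Profile}.
#' @export
anchorProfile <- function(signal, anchors, flank = 2000L,
                          signalLabel = "signal", anchorLabel = "anchors") {
    if (flank <= 0L) stop("flank must be > 0")
    if (length(anchors) == 0L) stop("anchor set is empty")
    if (!is.list(signal)) signal <- list(signal)
    repMeans <- vapply(signal, function(trk) {
        if (is(trk, "MethylationTrack")) {
            profileMean(methylationProfile(trk, anchors, flank, mode = "absolute"))
        } else {
            m <- .extractWindows(trackValues(trk), anchors, flank)
            colMeans(m, na.rm = TRUE)
        }
    }, numeric(2L * flank + 1L))
    repMeans[is.nan(repMeans)] <- NA_real_
    mu <- rowMeans(repMeans, na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    new("Profile", positions = seq.int(-flank, flank), repMeans = repMeans,
        mean = mu, sd = .rowSdAcross(repMeans), nAnchors = length(anchors),
        signalLabel = signalLabel, anchorLabel = anchorLabel)
}

#' Scale DKO profiles to equal occupancy at common sites
#'
#' Multiplies both DKO profiles by the scalar s = mean(WT common) /
#' mean(DKO common), so that after scaling the common-site profiles of the
#' two conditions have exactly equal means while the lost-site contrast is
#' preserved. WT profiles are unchanged; applying the operation twice is a
#' no-op.
#'
#' @param profiles named list with elements \code{wtCommon}, \code{wtLost},
#'   \code{dkoCommon}, \code{dkoLost} (\linkS4class{Profile}s on identical
#'   positions).
#' @return The list with the DKO profiles rescaled; attribute
#'   \code{scaleFactor} carries s.
#' @export
normalizeToCommon <- function(profiles) {
    need <- c("wtCommon", "wtLost", "dkoCommon", "dkoLost")
    if (!all(need %in% names(profiles)))
        stop("profiles must contain: ", paste(need, collapse = ", "))
    pos <- lapply(profiles[need], profilePositions)
    if (!all(vapply(pos[-1], identical, logical(1), pos[[1]])))
        stop("all four profiles must share positions")
    mWt <- mean(profileMean(profiles$wtCommon), na.rm = TRUE)
    mDko <- mean(profileMean(profiles$dkoCommon), na.rm = TRUE)
    if (!is.finite(mDko) || mDko == 0) stop("DKO common reference has zero mean")
    s <- mWt / mDko
    scaleProfile <- function(p, s) {
        p@repMeans <- p@repMeans * s
        p@mean <- p@mean * s
        p@sd <- p@sd * abs(s)
        p
    }
    profiles$dkoCommon <- scaleProfile(profiles$dkoCommon, s)
    profiles$dkoLost <- scaleProfile(profiles$dkoLost, s)
    attr(profiles, "scaleFactor") <- s
    profiles
}

#' k-means clustering of per-anchor profiles with asymmetry scores
#'
#' Clusters per-anchor (log-)affinity profiles by k-means after optional
#' subsampling to \code{sampleCap} rows, and scores the left/right asymmetry
#' of each cluster as |mean(left flank) - mean(right flank)| divided by the
#' pooled SD of the members' flank means. When a control matrix (e.g.
#' profiles of random genomic regions) is supplied it is clustered with
#' identical settings for comparison.
#'
#' @param mat numeric matrix, one profile per row (odd column count; the
#'   centre column separates the flanks).
#' @param k number of clusters (>= 2, <= rows).
#' @param sampleCap maximum rows clustered (default 200000).
#' @param seed RNG seed (sampling and k-means are deterministic given it).
#' @param control optional matrix clustered with the same settings.
#' @return List with \code{centers}, \code{cluster} (assignment per sampled
#'   row), \code{rows} (sampled row indices), \code{asymmetry} (per cluster),
#'   \code{size}, and \code{control} (same structure) when supplied.
#' @export
clusterProfiles <- function(mat, k = 6L, sampleCap = 200000L, seed = 1L,
                            control = NULL) {
    if (k < 2L) stop("k must be >= 2")
    runOne <- function(m) {
        if (k > nrow(m)) stop("k exceeds number of profiles")
        rows <- seq_len(nrow(m))
        if (nrow(m) > sampleCap) rows <- sort(sample.int(nrow(m), sampleCap))
        m <- m[rows, , drop = FALSE]
        km <- kmeans(m, centers = k, nstart = 5L, iter.max = 100L)
        half <- (ncol(m) - 1L) %/% 2L
        lIdx <- seq_len(half); rIdx <- (ncol(m) - half + 1L):ncol(m)
        asym <- vapply(seq_len(k), function(c_) {
            mem <- m[km$cluster == c_, , drop = FALSE]
            l <- rowMeans(mem[, lIdx, drop = FALSE], na.rm = TRUE)
            r <- rowMeans(mem[, rIdx, drop = FALSE], na.rm = TRUE)
            sp <- sqrt((stats::var(l) + stats::var(r)) / 2)
            d <- abs(mean(l) - mean(r))
            if (!is.finite(sp) || sp == 0) { if (d == 0) 0 else Inf } else d / sp
        }, numeric(1))
        list(centers = km$centers, cluster = km$cluster, rows = rows,
             asymmetry = asym, size = km$size)
    }
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    res <- runOne(mat)
    if (!is.null(control)) {
        set.seed(seed)
        res$control <- runOne(control)
    }
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    res
}
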