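## Periodicity estimation shared by nucleosome repeat length (NRL) detection
## and affinity-landscape oscillation analysis.

## Autocovariance of a numeric vector via FFT, lags 0..maxLag.
.autocov <- function(x, maxLag) {
    x <- x - mean(x)
    n <- length(x)
    m <- 2^ceiling(log2(2L * n))
    z <- fft(c(x, rep(0, m - n)))
    ac <- Re(fft(Mod(z)^2, inverse = TRUE)) / m / n
    ac[seq_len(maxLag + 1L)]
}

## NA-tolerant running mean (centred window).
.runningMean <- function(y, window) {
    half <- window %/% 2L
    v <- ifelse(is.na(y), 0, y)
    cnt <- as.numeric(!is.na(y))
    k <- rep(1, 2L * half + 1L)
    s <- stats::filter(v, k, sides = 2)
    n <- stats::filter(cnt, k, sides = 2)
    out <- as.numeric(s / pmax(n, 1))
    out[is.na(out)] <- mean(y, na.rm = TRUE)
    out
}

## Least-squares sine fit R^2 at one period (NA positions dropped).
.sineR2 <- function(t, y, period) {
    s <- sin(2 * pi * t / period); c_ <- cos(2 * pi * t / period)
    f <- stats::lm.fit(cbind(1, s, c_), y)
    amp <- sqrt(sum(f$coefficients[2:3]^2))
    tss <- sum((y - mean(y))^2)
    list(r2 = 1 - sum(f$residuals^2) / tss, amplitude = amp)
}

#' Estimate the nucleosome repeat length from dyad positions
#'
#' Builds a per-bp dyad density, computes its autocorrelation by FFT, and
#' takes the dominant local maximum within the candidate lag range, refined
#' to sub-bp resolution by parabolic interpolation around the peak. When no
#' lag stands out from the autocorrelation noise floor (peak less than
#' \code{minZ} robust SDs above the median over the range), the result is an
#' explicit "no periodicity" answer (\code{periodic = FALSE}, \code{nrl =
#' NA}), not a number.
#'
#' @param dyads numeric vector of dyad (fragment midpoint) positions, or a
#'   \linkS4class{FragmentSet} (midpoints are used).
#' @param range candidate NRL range in bp (default c(100, 400)).
#' @param minZ robust z-score a peak must reach to count as periodic
#'   (default 5).
#' @return List with \code{nrl} (bp), \code{uncertainty} (bp, from peak
#'   curvature), \code{periodic} (logical), \code{peakZ}.
#' @examples
#' set.seed(1)
#' d <- rep(seq(0, 10 * 176, 176), each = 40) + rnorm(4400, sd = 15)
#' estimateNRL(d)$nrl  # ~176
#' @export
estimateNRL <- function(dyads, range = c(100L, 400L), minZ = 5) {
    if (is(dyads, "FragmentSet")) dyads <- .centers(fragments(dyads))
    dyads <- dyads[!is.na(dyads)]
    if (length(dyads) < 100L) stop("need at least 100 dyad positions")
    pos <- as.integer(round(dyads - min(dyads))) + 1L
    counts <- tabulate(pos, nbins = max(pos))
    maxLag <- as.integer(range[2] + 5L)
    if (length(counts) < 3L * maxLag)
        stop("dyad span must cover at least 3x the maximum candidate period")
    ac <- .autocov(counts, maxLag)
    lags <- seq.int(range[1], range[2])
    v <- ac[lags + 1L]
    ## noise floor from the local roughness of the autocorrelation, so a
    ## genuine smooth oscillation is not counted as its own noise
    noise <- mad(diff(v)) / sqrt(2)
    if (noise == 0) return(list(nrl = NA_real_, uncertainty = NA_real_,
                                periodic = FALSE, peakZ = 0))
    ## dominant interior local maximum; a featureless acf has no periodicity
    iLoc <- which(diff(sign(diff(v))) == -2) + 1L
    if (!length(iLoc))
        return(list(nrl = NA_real_, uncertainty = NA_real_,
                    periodic = FALSE, peakZ = 0))
    i <- iLoc[which.max(v[iLoc])]
    peakZ <- (v[i] - median(v)) / noise
    if (peakZ < minZ)
        return(list(nrl = NA_real_, uncertainty = NA_real_,
                    periodic = FALSE, peakZ = peakZ))
    ## vertex from a local quadratic fit with a linear baseline term, which
    ## removes the bias a sloping acf baseline puts on 3-point interpolation
    win <- 12L
    sel <- max(1L, i - win):min(length(v), i + win)
    x <- lags[sel] - lags[i]
    fit <- stats::lm.fit(cbind(1, x, x^2), v[sel])
    b1 <- fit$coefficients[2]; b2 <- fit$coefficients[3]
    delta <- if (is.finite(b2) && b2 < 0) -b1 / (2 * b2) else 0
    if (!is.finite(delta) || abs(delta) > win) delta <- 0
    resSd <- sqrt(sum(fit$residuals^2) / max(1, length(sel) - 3L))
    unc <- if (is.finite(b2) && b2 < 0)
        max(0.5, sqrt(resSd / abs(b2))) else NA_real_
    list(nrl = lags[i] + delta, uncertainty = unc, periodic = TRUE,
         peakZ = peakZ)
}

#' Dominant oscillation period of an anchor-centred profile
#'
#' Detrends the profile by subtracting a running mean, scans a fine grid of
#' candidate periods with a least-squares sine fit (missing positions are
#' ignored, so masked contig edges are handled), and reports the period of
#' maximum variance explained. Significance is assessed by a permutation
#' test: the profile values are shuffled \code{nPerm} times and the observed
#' peak R-squared (over a coarse period grid) is compared with the permuted
#' maxima. A flat or aperiodic profile yields \code{periodic = FALSE}.
#'
#' @param profile a \linkS4class{Profile} or numeric vector of profile values
#'   (1-bp spacing assumed for a bare vector).
#' @param dRange candidate period range in bp (default c(100, 400); must span
#'   at least 3 periods of data).
#' @param detrendWindow running-mean window used for detrending (bp; default
#'   2x the upper period bound).
#' @param gridStep fine period grid step (bp, default 0.25).
#' @param nPerm permutations for the significance test (default 199).
#' @param alpha significance level (default 0.01).
#' @param seed RNG seed for the permutation test.
#' @return List with \code{period} (bp), \code{uncertainty} (bp, half-width
#'   of the R-squared peak), \code{amplitude} (fitted sine amplitude, signal
#'   units), \code{r2}, \code{pValue}, \code{periodic}.
#' @export
estimateProfilePeriodicity <- function(profile, dRange = c(100, 400),
                                       detrendWindow = 2 * dRange[2],
                                       gridStep = 0.25, nPerm = 199L,
                                       alpha = 0.01, seed = 1L) {
    y <- if (is(profile, "Profile")) profileMean(profile) else as.numeric(profile)
    n <- length(y)
    if (n < 3 * dRange[2]) stop("profile must span at least 3x the maximum period")
    yd <- y - .runningMean(y, as.integer(detrendWindow))
    ok <- !is.na(yd)
    t <- seq_len(n)[ok]; yv <- yd[ok]
    if (length(yv) < 50L || stats::var(yv) < .Machine$double.eps)
        return(list(period = NA_real_, uncertainty = NA_real_, amplitude = 0,
                    r2 = 0, pValue = 1, periodic = FALSE))
    yv <- yv - mean(yv)
    fine <- seq(dRange[1], dRange[2], by = gridStep)
    r2 <- vapply(fine, function(p) .sineR2(t, yv, p)$r2, numeric(1))
    i <- which.max(r2)
    best <- fine[i]
    fit <- .sineR2(t, yv, best)
    ## permutation null of the peak R^2 over a coarse grid
    coarse <- seq(dRange[1], dRange[2], by = max(2, 8 * gridStep))
    obsCoarse <- max(vapply(coarse, function(p) .sineR2(t, yv, p)$r2, numeric(1)),
                     fit$r2)
    Sc <- do.call(cbind, lapply(coarse, function(p)
        cbind(sin(2 * pi * t / p), cos(2 * pi * t / p))))
    Sc <- scale(Sc, center = TRUE, scale = FALSE)
    grams <- lapply(seq_along(coarse), function(k) {
        B <- Sc[, c(2 * k - 1, 2 * k)]
        solve(crossprod(B))
    })
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    permMax <- vapply(seq_len(nPerm), function(b) {
        yp <- sample(yv)
        tss <- sum(yp^2)
        q <- crossprod(Sc, yp)
        max(vapply(seq_along(coarse), function(k) {
            qq <- q[c(2 * k - 1, 2 * k), 1]
            drop(t(qq) %*% grams[[k]] %*% qq) / tss
        }, numeric(1)))
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    pValue <- (1 + sum(permMax >= obsCoarse)) / (nPerm + 1L)
    ## analytic peak width: half-width at half prominence of the R^2 curve
    medR2 <- median(r2)
    halfLevel <- medR2 + 0.5 * (r2[i] - medR2)
    above <- r2 >= halfLevel
    lo <- i; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < length(r2) && above[hi + 1L]) hi <- hi + 1L
    unc <- max(gridStep, (fine[hi] - fine[lo]) / 2)
    list(period = best, uncertainty = unc, amplitude = fit$amplitude,
         r2 = fit$r2, pValue = pValue, periodic = pValue <= alpha)
}
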