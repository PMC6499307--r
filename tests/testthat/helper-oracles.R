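## Independent brute-force oracles (explicit loops, no shared code with the
## package implementations) and small fixture builders.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(Biostrings)
})

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

## Brute-force TRAP affinity landscape: explicit per-window, per-column loops.
bruteAffinity <- function(seqChar, prob, R0 = 1e9, lambda = 1.5,
                          strandMode = "sum") {
    chars <- strsplit(seqChar, "")[[1]]
    w <- ncol(prob)
    n <- length(chars)
    pmaxcol <- numeric(w)
    for (j in seq_len(w)) pmaxcol[j] <- max(prob[, j])
    out <- rep(NA_real_, n)
    for (startPos in seq_len(n - w + 1)) {
        win <- chars[startPos:(startPos + w - 1)]
        if (any(!win %in% BASES)) next
        ePlus <- 0; eMinus <- 0
        rcWin <- rev(unname(COMP[win]))
        for (j in seq_len(w)) {
            ePlus <- ePlus + log(pmaxcol[j] / prob[win[j], j])
            eMinus <- eMinus + log(pmaxcol[j] / prob[rcWin[j], j])
        }
        ePlus <- ePlus / lambda; eMinus <- eMinus / lambda
        pP <- R0 * exp(-ePlus) / (1 + R0 * exp(-ePlus))
        pM <- R0 * exp(-eMinus) / (1 + R0 * exp(-eMinus))
        p <- if (strandMode == "sum") min(pP + pM, 1) else max(pP, pM)
        out[startPos + floor(w / 2)] <- p
    }
    out
}

## Brute-force AUC: all positive/negative pairs, ties counted half.
bruteAUC <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
    tot / (length(pos) * length(neg))
}

## Tiny deterministic random sequence.
randSeq <- function(n, seed) {
    set.seed(seed)
    paste(sample(BASES, n, replace = TRUE), collapse = "")
}

## MethylationTrack from bare vectors.
makeMeth <- function(pos, ratio, coverage = 30L, chrom = "chr1",
                     condition = "WT", seqlen = NULL) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L),
                  ratio = ratio, coverage = rep(coverage, length.out = length(pos)))
    if (!is.null(seqlen)) seqlengths(gr) <- setNames(seqlen, chrom)
    methylationTrack(gr, condition)
}

## SignalTrack with one chromosome from a numeric vector.
makeTrack <- function(values, chrom = "chr1", normalization = "raw") {
    v <- list(Rle(values)); names(v) <- chrom
    new("SignalTrack", values = as(v, "RleList"), normalization = normalization)
}

## Small motif for fast tests: the packaged CTCF-like model.
testMotif <- function() loadCtcfMotif()
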