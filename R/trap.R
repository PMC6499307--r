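## TRAP-style biophysical prediction of TF binding affinity from sequence.
##
## The model scores each motif-width window by its mismatch energy relative to
## the per-column-best consensus,
##     beta*E(S) = (1/lambda) * sum_j log( p(j, b_max) / p(j, S_j) ),
## and converts it to a binding probability with a concentration-like constant
##     p = R0 * exp(-beta*E) / (1 + R0 * exp(-beta*E)).
## With the defaults (R0 = 1e9, lambda = 1.5) a consensus window saturates at
## p ~= 1 and each additional mismatch multiplies the Boltzmann weight by the
## corresponding probability ratio raised to 1/lambda.

#' Read a position frequency matrix (JASPAR PFM dialect)
#'
#' Accepts the JASPAR text dialect: an optional \code{>} header line followed
#' by four base rows, either bracketed (\code{A [ 3 10 ... ]}) or bare
#' whitespace-separated counts in A, C, G, T order. Counts are normalised
#' per column after adding \code{pseudocount} to every cell, so all
#' probabilities are strictly positive and mismatch energies stay finite.
#'
#' @param path path to a PFM file, or a character vector of its lines via
#'   \code{text}.
#' @param text optional character vector of lines (overrides \code{path}).
#' @param pseudocount count added to each cell before normalisation (default 1).
#' @param name motif name; defaults to the header word if present.
#' @return A \linkS4class{MotifModel}.
#' @examples
#' m <- loadPFM(text = c(">toy", "A [ 8 0 ]", "C [ 0 8 ]",
#'                       "G [ 0 0 ]", "T [ 0 0 ]"))
#' motifProb(m)["A", 1]  # (8+1)/(8+4) = 0.75
#' @export
loadPFM <- function(path = NULL, text = NULL, pseudocount = 1, name = NULL) {
    lines <- if (!is.null(text)) text else readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && startsWith(trimws(lines[1]), ">")) {
        hdr <- sub("^>\\s*", "", trimws(lines[1]))
        if (is.null(name)) name <- strsplit(hdr, "\\s+")[[1]][1]
        lines <- lines[-1]
    }
    if (is.null(name)) name <- "motif"
    if (length(lines) != 4L)
        stop("PFM must have exactly 4 base rows, found ", length(lines))
    rows <- vector("list", 4L)
    rowBase <- character(4L)
    for (i in seq_len(4L)) {
        ln <- trimws(lines[i])
        m <- regmatches(ln, regexec("^([ACGTacgt])\\s*\\[(.*)\\]\\s*$", ln))[[1]]
        if (length(m) == 3L) {
            rowBase[i] <- toupper(m[2])
            numtxt <- m[3]
        } else {
            if (grepl("[][]|^[ACGTacgt]\\s", ln))
                stop("cannot parse PFM row ", i, ": '", lines[i], "'")
            rowBase[i] <- .BASES[i]
            numtxt <- ln
        }
        vals <- suppressWarnings(as.numeric(strsplit(trimws(numtxt), "\\s+")[[1]]))
        if (anyNA(vals)) stop("non-numeric count in PFM row ", i, ": '", lines[i], "'")
        if (any(vals < 0)) stop("negative count in PFM row ", i)
        rows[[i]] <- vals
    }
    if (!setequal(rowBase, .BASES))
        stop("PFM rows must cover bases A, C, G, T; got ", paste(rowBase, collapse = ","))
    w <- unique(lengths(rows))
    if (length(w) != 1L)
        stop("ragged PFM: row lengths ", paste(lengths(rows), collapse = ", "))
    counts <- do.call(rbind, rows[match(.BASES, rowBase)])
    rownames(counts) <- .BASES
    prob <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
    new("MotifModel", name = name, prob = prob, pseudocount = pseudocount)
}

#' Mismatch energy of a sequence window under a motif model
#'
#' Dimensionless energy \eqn{\beta E = (1/\lambda)\sum_j \ln(p(j,b_{max}) /
#' p(j,S_j))}; zero exactly when the window is the per-column-maximum
#' consensus. On the minus strand the window is reverse-complemented before
#' scoring. Windows containing non-ACGT bases return \code{NA}.
#'
#' @param window character string (or DNAString) of length equal to the motif
#'   width.
#' @param motif a \linkS4class{MotifModel}.
#' @param params a \linkS4class{TrapParams}.
#' @param strand "+" or "-".
#' @return Non-negative numeric energy (NA for ambiguous bases).
#' @export
mismatchEnergy <- function(window, motif, params = trapParams(), strand = "+") {
    w <- motifWidth(motif)
    code <- .seqToCode(window)
    if (length(code) != w)
        stop("window length ", length(code), " != motif width ", w)
    if (strand == "-") code <- rev(5L - code)
    else if (strand != "+") stop("strand must be '+' or '-'")
    if (anyNA(code)) return(NA_real_)
    p <- motifProb(motif)
    sum(log(motifMaxProb(motif) / p[cbind(code, seq_len(w))])) / params@lambda
}

#' TRAP binding probability of a window from its mismatch energy
#'
#' \eqn{p = R_0 e^{-\beta E} / (1 + R_0 e^{-\beta E})}; strictly decreasing in
#' the energy, saturating at 1 for the consensus when \eqn{R_0} is large.
#'
#' @param energy non-negative energy (vectorised).
#' @param params a \linkS4class{TrapParams}.
#' @return Binding probability in (0, 1).
#' @export
windowBindingProb <- function(energy, params = trapParams()) {
    x <- params@R0 * exp(-energy)
    x / (1 + x)
}

## Vectorised per-window log-probability sums on both strands.
## Returns list(plus, minus) of length n - w + 1 (NA where window has non-ACGT).
.windowLogProbs <- function(code, motif) {
    p <- motifProb(motif)
    L <- log(p)
    w <- ncol(L)
    n <- length(code)
    nw <- n - w + 1L
    if (nw < 1L) stop("sequence shorter than motif width")
    ## reverse-complement scoring matrix: base b at window offset j scores as
    ## complement(b) at motif column w+1-j
    Lrc <- L[4:1, w:1, drop = FALSE]
    sPlus <- numeric(nw)
    sMinus <- numeric(nw)
    bad <- logical(nw)
    for (j in seq_len(w)) {
        cj <- code[j:(j + nw - 1L)]
        nas <- is.na(cj)
        if (any(nas)) {
            bad <- bad | nas
            cj[nas] <- 1L
        }
        sPlus <- sPlus + L[cbind(cj, j)]
        sMinus <- sMinus + Lrc[cbind(cj, j)]
    }
    sPlus[bad] <- NA_real_
    sMinus[bad] <- NA_real_
    list(plus = sPlus, minus = sMinus)
}

#' Sequence-wide binding affinity landscape
#'
#' Slides the motif over every position of each chromosome, computes the TRAP
#' binding probability on both strands, combines strands (sum capped at 1 by
#' default, or max), and assigns each window's value to its centre position
#' \code{floor(start + width/2)} (0-based convention; the corresponding
#' 1-based coordinate internally). Positions within half a motif width of the
#' contig ends, and windows containing non-ACGT bases, are missing (NA).
#'
#' @param genome DNAStringSet (or single DNAString / character string).
#' @param motif a \linkS4class{MotifModel}.
#' @param params a \linkS4class{TrapParams}.
#' @param strandMode "sum" (sum of strand probabilities, capped at 1) or
#'   "max" (better-scoring strand only).
#' @return An \linkS4class{AffinityTrack}.
#' @export
affinityProfile <- function(genome, motif, params = trapParams(),
                            strandMode = c("sum", "max")) {
    strandMode <- match.arg(strandMode)
    if (is.character(genome)) genome <- DNAStringSet(genome)
    if (is(genome, "DNAString")) genome <- DNAStringSet(list(chr = genome))
    if (is.null(names(genome)))
        names(genome) <- paste0("chr", seq_along(genome))
    w <- motifWidth(motif)
    Emax <- sum(log(motifMaxProb(motif))) # max attainable log-prob sum
    vals <- lapply(seq_along(genome), function(i) {
        code <- .seqToCode(genome[[i]])
        n <- length(code)
        if (n < w) stop("sequence '", names(genome)[i], "' shorter than motif")
        lp <- .windowLogProbs(code, motif)
        ePlus <- (Emax - lp$plus) / params@lambda
        eMinus <- (Emax - lp$minus) / params@lambda
        pPlus <- windowBindingProb(ePlus, params)
        pMinus <- windowBindingProb(eMinus, params)
        p <- if (strandMode == "sum") pmin(pPlus + pMinus, 1) else pmax(pPlus, pMinus)
        out <- rep(NA_real_, n)
        centers <- seq_len(n - w + 1L) + w %/% 2L  # 1-based centre of each window
        out[centers] <- p
        Rle(out)
    })
    names(vals) <- names(genome)
    new("AffinityTrack", values = as(vals, "RleList"), motifName = motif@name,
        motifWidth = as.integer(w), params = params, strandMode = strandMode)
}

#' Summed binding affinity over genomic regions
#'
#' Sum of per-position window binding probabilities over each region (missing
#' positions contribute 0), the region-level affinity used to compare e.g.
#' common versus lost binding sites. Additive over disjoint sub-regions.
#'
#' @param track an \linkS4class{AffinityTrack} (or SignalTrack).
#' @param regions GRanges.
#' @return Numeric vector, one value per region (0 for empty regions).
#' @export
regionAffinity <- function(track, regions) {
    values <- trackValues(track)
    vapply(seq_along(regions), function(i) {
        chrom <- as.character(seqnames(regions)[i])
        if (!chrom %in% names(values)) return(0)
        v <- values[[chrom]]
        s <- max(1L, start(regions)[i]); e <- min(length(v), end(regions)[i])
        if (e < s) return(0)
        sum(as.numeric(v[s:e]), na.rm = TRUE)
    }, numeric(1))
}
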