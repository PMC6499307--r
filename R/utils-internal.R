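## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

## DNA string -> integer codes 1..4 (A,C,G,T); anything else -> NA.
.seqToCode <- function(x) {
    s <- utf8ToInt(toupper(as.character(x)))
    code <- rep(NA_integer_, length(s))
    code[s == 65L] <- 1L  # A
    code[s == 67L] <- 2L  # C
    code[s == 71L] <- 3L  # G
    code[s == 84L] <- 4L  # T
    code
}

## Value lookup in an RleList track at (chrom, pos); NA outside.
.trackAt <- function(values, chrom, pos) {
    out <- rep(NA_real_, length(pos))
    if (!chrom %in% names(values)) return(out)
    v <- values[[chrom]]
    ok <- pos >= 1L & pos <= length(v)
    if (any(ok)) out[ok] <- as.numeric(v[pos[ok]])
    out
}

.chromLengths <- function(values) vapply(values, length, integer(1))

## Sample SD across columns of a matrix (n-1); 0 for a single column.
.rowSdAcross <- function(m) {
    if (ncol(m) < 2L) return(rep(0, nrow(m)))
    mu <- rowMeans(m, na.rm = TRUE)
    sqrt(rowSums((m - mu)^2, na.rm = TRUE) / (ncol(m) - 1L))
}

## GRanges helper: integer midpoints.
.centers <- function(gr) (start(gr) + end(gr)) %/% 2L

## Deterministic child seed derived from a master seed (kept < 2^31).
.childSeed <- function(seed, k) (as.integer(seed) + 1000L * as.integer(k)) %% 2147483647L
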