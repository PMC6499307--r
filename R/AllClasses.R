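#' @import methods
#' @importFrom S4Vectors Rle RleList runValue runLength mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom IRanges IRanges Views viewMeans coverage findOverlaps countOverlaps pintersect width start end resize shift restrict
#' @importFrom GenomicRanges GRanges granges seqnames strand strand<- reduce gaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames<-
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement letterFrequency vmatchPattern readDNAStringSet writeXStringSet subseq
#' @importFrom stats rbinom rnorm runif rpois setNames sd fft mad median quantile chisq.test complete.cases p.adjust kmeans
#' @importFrom utils read.table write.table head tail
NULL

## Central S4 classes. Containers follow Bioconductor conventions: intervals are
## GRanges (1-based, closed), per-bp signal is an RleList keyed by chromosome,
## sequence is a DNAStringSet.

#' MotifModel: position probability matrix for a DNA binding motif
#'
#' Holds the per-column base probabilities \eqn{p(j,b)} of a motif of width
#' \eqn{w}, normalised from a position frequency matrix (PFM) after adding a
#' pseudocount to every cell. The per-column maxima \eqn{p(j,b_{max})} define
#' the mismatch energy of the TRAP binding model (see
#' \code{\link{mismatchEnergy}}).
#'
#' @slot name motif label.
#' @slot prob 4 x width numeric matrix, rows A/C/G/T, columns summing to 1.
#' @slot pseudocount count added to each PFM cell before normalisation.
#' @export
setClass("MotifModel",
    representation(name = "character", prob = "matrix", pseudocount = "numeric"))

setValidity("MotifModel", function(object) {
    p <- object@prob
    if (!is.numeric(p) || nrow(p) != 4L)
        return("prob must be a numeric matrix with 4 rows (A, C, G, T)")
    if (!identical(rownames(p), c("A", "C", "G", "T")))
        return("prob rows must be named A, C, G, T")
    if (ncol(p) < 1L) return("motif width must be >= 1")
    if (any(p <= 0)) return("all probabilities must be > 0 (use a pseudocount)")
    if (any(abs(colSums(p) - 1) > 1e-9))
        return("each column of prob must sum to 1")
    TRUE
})

#' TrapParams: parameters of the TRAP binding probability model
#'
#' @slot R0 dimensionless concentration-like constant (default 1e9).
#' @slot lambda energy mismatch scale (default 1.5).
#' @export
setClass("TrapParams", representation(R0 = "numeric", lambda = "numeric"))

setValidity("TrapParams", function(object) {
    if (length(object@R0) != 1L || object@R0 <= 0) return("R0 must be a single value > 0")
    if (length(object@lambda) != 1L || object@lambda <= 0) return("lambda must be a single value > 0")
    TRUE
})

#' @describeIn TrapParams-class constructor.
#' @param R0,lambda model parameters.
#' @export
trapParams <- function(R0 = 1e9, lambda = 1.5) new("TrapParams", R0 = R0, lambda = lambda)

#' SignalTrack: per-base-pair genomic signal
#'
#' @slot values RleList, one numeric Rle per chromosome (NA = missing).
#' @slot normalization one of "raw", "per-million", "mean-scaled", "affinity",
#'   "methylation-mean".
#' @export
setClass("SignalTrack", representation(values = "RleList", normalization = "character"))

setValidity("SignalTrack", function(object) {
    if (length(object@normalization) != 1L) return("normalization must be a single string")
    TRUE
})

#' AffinityTrack: sequence-predicted binding probability landscape
#'
#' Per-position TRAP binding probability (strand-handled per
#' \code{\link{affinityProfile}}), with the model parameters that produced it.
#' Values lie in (0, 1]; positions closer than half the motif width to a
#' contig end are NA.
#'
#' @slot values RleList of binding probabilities per chromosome.
#' @slot motifName name of the motif used.
#' @slot motifWidth motif width in bp.
#' @slot params TrapParams used.
#' @slot strandMode "sum" (default) or "max" strand combination.
#' @export
setClass("AffinityTrack",
    representation(values = "RleList", motifName = "character",
                   motifWidth = "integer", params = "TrapParams",
                   strandMode = "character"))

#' MethylationTrack: per-CpG methylation ratios for one condition
#'
#' One record per CpG dinucleotide (strand-collapsed), with methylation ratio
#' in [0, 1] and read coverage.
#'
#' @slot gr GRanges of CpG positions with mcols \code{ratio} and \code{coverage}.
#' @slot condition condition label, e.g. "WT" or "DKO".
#' @export
setClass("MethylationTrack", representation(gr = "GRanges", condition = "character"))

setValidity("MethylationTrack", function(object) {
    m <- mcols(object@gr)
    if (!all(c("ratio", "coverage") %in% colnames(m)))
        return("gr must carry mcols 'ratio' and 'coverage'")
    r <- m$ratio[m$coverage > 0]
    if (length(r) && (any(r < 0 | r > 1, na.rm = TRUE)))
        return("ratios must lie in [0, 1] where coverage > 0")
    if (length(object@condition) != 1L) return("condition must be a single string")
    TRUE
})

#' @describeIn MethylationTrack-class constructor; sorts records.
#' @param gr GRanges with mcols ratio, coverage.
#' @param condition condition label.
#' @export
methylationTrack <- function(gr, condition = "WT") {
    new("MethylationTrack", gr = sort(gr), condition = condition)
}

#' FragmentSet: paired-end mononucleosome fragments
#'
#' @slot gr GRanges of fragment intervals.
#' @slot replicate replicate identifier.
#' @slot condition condition label.
#' @export
setClass("FragmentSet", representation(gr = "GRanges", replicate = "character",
                                       condition = "character"))

#' @describeIn FragmentSet-class constructor; warns when fragment lengths fall
#'   outside the typical mononucleosome range (100-200 bp).
#' @param gr GRanges of fragments.
#' @param replicate,condition labels.
#' @export
fragmentSet <- function(gr, replicate = "rep1", condition = "WT") {
    if (length(gr)) {
        w <- width(gr)
        frac <- mean(w < 100 | w > 200)
        if (frac > 0.05)
            warning(sprintf("%.1f%% of fragments outside typical 100-200 bp length", 100 * frac))
    }
    new("FragmentSet", gr = gr, replicate = replicate, condition = condition)
}

#' Profile: anchor-relative average signal
#'
#' Mean signal as a function of distance from a set of anchors, computed per
#' replicate and then averaged across replicates; the SD slot holds the sample
#' standard deviation (n-1) of the replicate means at each position.
#'
#' @slot positions integer offsets relative to anchor centres.
#' @slot repMeans positions x replicates matrix of per-replicate means.
#' @slot mean cross-replicate mean per position.
#' @slot sd cross-replicate sample SD per position (0 when one replicate).
#' @slot nAnchors number of anchors contributing.
#' @slot signalLabel,anchorLabel free-text labels.
#' @export
setClass("Profile",
    representation(positions = "integer", repMeans = "matrix", mean = "numeric",
                   sd = "numeric", nAnchors = "integer",
                   signalLabel = "character", anchorLabel = "character"))

setValidity("Profile", function(object) {
    n <- length(object@positions)
    if (nrow(object@repMeans) != n) return("repMeans rows must match positions")
    if (length(object@mean) != n || length(object@sd) != n)
        return("mean/sd length must match positions")
    if (any(object@sd < 0, na.rm = TRUE)) return("sd must be >= 0")
    TRUE
})

#' TruthManifest: planted ground truth of the synthetic epigenome
#'
#' @slot sites planted CTCF sites (GRanges; mcols tier, lost, side, gained).
#' @slot dmrs planted differentially methylated regions (mcols direction, delta).
#' @slot nrlTrue planted nucleosome repeat length (bp).
#' @slot boundaries TAD boundaries (mcols lost).
#' @slot loopBoundaries chromatin loop boundaries (mcols lost).
#' @slot downregulated ids of transcripts whose down-regulation probability was
#'   boosted by boundary loss.
#' @export
setClass("TruthManifest",
    representation(sites = "GRanges", dmrs = "GRanges", nrlTrue = "numeric",
                   boundaries = "GRanges", loopBoundaries = "GRanges",
                   downregulated = "character"))

#' SyntheticConfig: parameters of the synthetic epigenome generator
#'
#' All values are artifact choices of the generator (the study it emulates
#' defines no generative model); defaults give a desk-scale genome on which
#' every analysis step of the package runs in seconds to minutes. See the
#' methods vignette for the rationale behind each default.
#'
#' @slot genomeLength total genome length (bp).
#' @slot nChromosomes number of chromosomes (genomeLength is split evenly).
#' @slot islandCount,islandLength,islandCpgRate,backgroundCpgRate CpG island
#'   layout: count, length (bp) and CpG per-bp rates inside/outside islands.
#' @slot nSitesIsland,nSitesOutside,nSitesGained planted CTCF site counts
#'   (inside islands, outside, and DKO-only "gained" sites).
#' @slot weakMismatches number of consensus mismatches defining the weak motif tier.
#' @slot methIsland,methBackgroundWt,methBackgroundDko mean methylation of
#'   island CpGs (both conditions) and background CpGs per condition.
#' @slot spreadingAmplitude,spreadingDecayLength methylation-spreading gain at a
#'   lost CTCF site and its exponential decay length (bp).
#' @slot dmrCount,dmrLength,dmrDelta planted DMR blocks: count, length (bp) and
#'   methylation difference (DKO - WT; sign drawn per block).
#' @slot coverageMean mean per-CpG bisulfite coverage (Poisson, floored at 1).
#' @slot nrl planted nucleosome repeat length (bp, >= 147).
#' @slot phasingSd SD (bp) of nucleosome positions around the phased array.
#' @slot phasedFraction fraction of fragments drawn from phased arrays.
#' @slot fragmentLengthMean,fragmentLengthSd fragment length distribution
#'   (truncated to [100, 200] bp).
#' @slot fragmentsPerReplicate nucleosome fragments per replicate.
#' @slot replicatesPerCondition replicates per condition (>= 2).
#' @slot pFn per-replicate peak false-negative probability.
#' @slot lossBase,lossWeakBoost,lossDensitySlope site-loss model: logit-scale
#'   intercept, weak-tier increment, and per-(CpG/kb) density decrement.
#' @slot peakHalfWidth,peakJitterSd ChIP peak half-width and replicate jitter (bp).
#' @slot tadWidth TAD width (bp; TADs tile each chromosome).
#' @slot nTranscripts,transcriptLength transcript count and length (bp).
#' @slot pUp,pDown baseline up-/down-regulation probabilities.
#' @slot expressionDownregBoost added down-regulation probability at lost
#'   boundaries (scaled by proximity; maximal at lost promoters).
#' @slot boundaryDist distance (bp) defining "near a boundary" (default 10 kb).
#' @slot promoterFlank promoter half-width around the TSS (bp).
#' @slot seed master random seed.
#' @export
setClass("SyntheticConfig",
    representation(
        genomeLength = "numeric", nChromosomes = "integer",
        islandCount = "integer", islandLength = "integer",
        islandCpgRate = "numeric", backgroundCpgRate = "numeric",
        nSitesIsland = "integer", nSitesOutside = "integer", nSitesGained = "integer",
        weakMismatches = "integer",
        methIsland = "numeric", methBackgroundWt = "numeric", methBackgroundDko = "numeric",
        spreadingAmplitude = "numeric", spreadingDecayLength = "numeric",
        dmrCount = "integer", dmrLength = "integer", dmrDelta = "numeric",
        coverageMean = "numeric",
        nrl = "integer", phasingSd = "numeric", phasedFraction = "numeric",
        fragmentLengthMean = "numeric", fragmentLengthSd = "numeric",
        fragmentsPerReplicate = "integer", replicatesPerCondition = "integer",
        pFn = "numeric",
        lossBase = "numeric", lossWeakBoost = "numeric", lossDensitySlope = "numeric",
        peakHalfWidth = "integer", peakJitterSd = "numeric",
        tadWidth = "integer", nTranscripts = "integer", transcriptLength = "integer",
        pUp = "numeric", pDown = "numeric", expressionDownregBoost = "numeric",
        boundaryDist = "integer", promoterFlank = "integer",
        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    probs <- c(object@islandCpgRate, object@backgroundCpgRate, object@methIsland,
               object@methBackgroundWt, object@methBackgroundDko,
               object@spreadingAmplitude, object@phasedFraction, object@pFn,
               object@pUp, object@pDown, object@expressionDownregBoost)
    if (any(probs < 0 | probs > 1)) return("all rates/probabilities must lie in [0, 1]")
    if (object@islandLength * object@islandCount >= object@genomeLength)
        return("islandLength * islandCount must be < genomeLength")
    if (object@nrl < 147L) return("nrl must be >= 147 bp")
    if (object@spreadingDecayLength <= 0) return("spreadingDecayLength must be > 0")
    if (object@dmrDelta < 0 || object@dmrDelta > 1) return("dmrDelta must lie in [0, 1]")
    if (object@replicatesPerCondition < 1L) return("replicatesPerCondition must be >= 1")
    if (object@pUp + object@pDown > 1) return("pUp + pDown must be <= 1")
    TRUE
})
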