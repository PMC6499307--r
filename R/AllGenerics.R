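## Accessors and show methods.

#' @rdname MotifModel-class
#' @param object a MotifModel.
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))

#' @rdname MotifModel-class
#' @export
setMethod("motifWidth", "MotifModel", function(object) ncol(object@prob))

#' @rdname MotifModel-class
#' @export
setGeneric("motifProb", function(object) standardGeneric("motifProb"))

#' @rdname MotifModel-class
#' @export
setMethod("motifProb", "MotifModel", function(object) object@prob)

#' @rdname MotifModel-class
#' @export
setGeneric("motifMaxProb", function(object) standardGeneric("motifMaxProb"))

#' @rdname MotifModel-class
#' @export
setMethod("motifMaxProb", "MotifModel", function(object) apply(object@prob, 2L, max))

#' @rdname MotifModel-class
#' @export
setGeneric("motifConsensus", function(object) standardGeneric("motifConsensus"))

#' @rdname MotifModel-class
#' @export
setMethod("motifConsensus", "MotifModel", function(object) {
    paste(rownames(object@prob)[apply(object@prob, 2L, which.max)], collapse = "")
})

setMethod("show", "MotifModel", function(object) {
    cat("MotifModel '", object@name, "': width ", motifWidth(object),
        ", consensus ", motifConsensus(object),
        " (pseudocount ", object@pseudocount, ")\n", sep = "")
})

setMethod("show", "TrapParams", function(object) {
    cat(sprintf("TrapParams: R0 = %g, lambda = %g\n", object@R0, object@lambda))
})

#' @rdname SignalTrack-class
#' @param object a SignalTrack (or AffinityTrack).
#' @export
setGeneric("trackValues", function(object) standardGeneric("trackValues"))

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(object) object@values)

#' @rdname AffinityTrack-class
#' @param object an AffinityTrack.
#' @export
setMethod("trackValues", "AffinityTrack", function(object) object@values)

setMethod("show", "SignalTrack", function(object) {
    cat("SignalTrack (", object@normalization, "): ",
        length(object@values), " chromosome(s), total length ",
        sum(as.numeric(vapply(object@values, length, 0))), " bp\n", sep = "")
})

setMethod("show", "AffinityTrack", function(object) {
    cat("AffinityTrack: motif '", object@motifName, "' (width ", object@motifWidth,
        "), strand mode '", object@strandMode, "', ",
        length(object@values), " chromosome(s)\n", sep = "")
    show(object@params)
})

#' @rdname MethylationTrack-class
#' @param object a MethylationTrack.
#' @export
setGeneric("methRecords", function(object) standardGeneric("methRecords"))

#' @rdname MethylationTrack-class
#' @export
setMethod("methRecords", "MethylationTrack", function(object) object@gr)

#' @rdname MethylationTrack-class
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname MethylationTrack-class
#' @export
setMethod("condition", "MethylationTrack", function(object) object@condition)

#' @rdname FragmentSet-class
#' @export
setMethod("condition", "FragmentSet", function(object) object@condition)

setMethod("length", "MethylationTrack", function(x) length(x@gr))

setMethod("show", "MethylationTrack", function(object) {
    cat("MethylationTrack [", object@condition, "]: ", length(object@gr),
        " CpGs, mean ratio ", round(mean(mcols(object@gr)$ratio, na.rm = TRUE), 3),
        "\n", sep = "")
})

#' @rdname FragmentSet-class
#' @param object a FragmentSet.
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(object) object@gr)

setMethod("length", "FragmentSet", function(x) length(x@gr))

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet [", object@condition, "/", object@replicate, "]: ",
        length(object@gr), " fragments, median length ",
        if (length(object@gr)) median(width(object@gr)) else NA, " bp\n", sep = "")
})

#' @rdname Profile-class
#' @param object a Profile.
#' @export
setGeneric("profilePositions", function(object) standardGeneric("profilePositions"))

#' @rdname Profile-class
#' @export
setMethod("profilePositions", "Profile", function(object) object@positions)

#' @rdname Profile-class
#' @export
setGeneric("profileMean", function(object) standardGeneric("profileMean"))

#' @rdname Profile-class
#' @export
setMethod("profileMean", "Profile", function(object) object@mean)

#' @rdname Profile-class
#' @export
setGeneric("profileSd", function(object) standardGeneric("profileSd"))

#' @rdname Profile-class
#' @export
setMethod("profileSd", "Profile", function(object) object@sd)

setMethod("show", "Profile", function(object) {
    cat("Profile of '", object@signalLabel, "' around '", object@anchorLabel,
        "': offsets [", min(object@positions), ", ", max(object@positions),
        "], ", ncol(object@repMeans), " replicate(s), ", object@nAnchors,
        " anchors\n", sep = "")
})

#' @rdname TruthManifest-class
#' @param object a TruthManifest.
#' @export
setGeneric("plantedSites", function(object) standardGeneric("plantedSites"))

#' @rdname TruthManifest-class
#' @export
setMethod("plantedSites", "TruthManifest", function(object) object@sites)

#' @rdname TruthManifest-class
#' @export
setGeneric("plantedDmrs", function(object) standardGeneric("plantedDmrs"))

#' @rdname TruthManifest-class
#' @export
setMethod("plantedDmrs", "TruthManifest", function(object) object@dmrs)

#' @rdname TruthManifest-class
#' @export
setGeneric("trueNrl", function(object) standardGeneric("trueNrl"))

#' @rdname TruthManifest-class
#' @export
setMethod("trueNrl", "TruthManifest", function(object) object@nrlTrue)

setMethod("show", "TruthManifest", function(object) {
    cat("TruthManifest: ", length(object@sites), " planted sites (",
        sum(mcols(object@sites)$lost), " lost, ",
        sum(mcols(object@sites)$gained), " gained), ",
        length(object@dmrs), " planted DMRs, NRL ", object@nrlTrue, " bp, ",
        sum(mcols(object@boundaries)$lost), "/", length(object@boundaries),
        " TAD boundaries lost\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig: ", object@genomeLength, " bp genome (",
        object@nChromosomes, " chromosome(s)), ", object@islandCount,
        " CpG islands, ", object@nSitesIsland + object@nSitesOutside,
        " planted CTCF sites, NRL ", object@nrl, " bp, seed ", object@seed,
        "\n", sep = "")
})
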