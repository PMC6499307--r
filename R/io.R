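## Readers and writers for all touched plain-text formats. Internal
## containers follow the Bioconductor convention (GRanges, 1-based closed);
## BED/bedGraph conversion to 0-based half-open is delegated to rtracklayer,
## and 1-based TSV dialects are converted explicitly here.

#' Read genomic intervals (BED3/6)
#'
#' @param path BED file (0-based half-open; converted to GRanges convention).
#' @return GRanges; strand defaults to "*" where absent.
#' @export
readBed <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("malformed BED '", path, "': ",
                                            conditionMessage(e)))
    gr
}

#' Write genomic intervals as BED
#'
#' @param gr GRanges; mcols \code{name} and \code{score} are written if
#'   present (a \code{category}/\code{direction} mcol is used as name when
#'   no name exists).
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
    m <- mcols(gr)
    if (!"name" %in% colnames(m)) {
        nm <- if ("category" %in% colnames(m)) as.character(m$category)
              else if ("direction" %in% colnames(m)) as.character(m$direction)
              else NULL
        if (!is.null(nm)) mcols(gr)$name <- nm
    }
    keep <- intersect(c("name", "score"), colnames(mcols(gr)))
    mcols(gr) <- mcols(gr)[, keep, drop = FALSE]
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read paired anchors from a BEDPE file
#'
#' @param path BEDPE (0-based half-open anchor pairs).
#' @return GRanges of anchors with mcols \code{loopId} (one per input line)
#'   and \code{anchor} (1 or 2).
#' @export
readBedpe <- function(path) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 6L) stop("BEDPE '", path, "' needs >= 6 columns")
    n <- nrow(tab)
    ids <- if (ncol(tab) >= 7L) as.character(tab[[7]]) else paste0("loop", seq_len(n))
    suppressWarnings(c(
        GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]), loopId = ids, anchor = 1L),
        GRanges(tab[[4]], IRanges(tab[[5]] + 1L, tab[[6]]), loopId = ids, anchor = 2L)))
}

#' Write paired anchors as BEDPE
#'
#' @param loops GRanges of anchors with mcols \code{loopId}, \code{anchor}.
#' @param path output path.
#' @export
writeBedpe <- function(loops, path) {
    ids <- unique(mcols(loops)$loopId)
    a1 <- loops[mcols(loops)$anchor == 1L][match(ids, mcols(loops)$loopId[mcols(loops)$anchor == 1L])]
    a2 <- loops[mcols(loops)$anchor == 2L][match(ids, mcols(loops)$loopId[mcols(loops)$anchor == 2L])]
    tab <- data.frame(as.character(seqnames(a1)), start(a1) - 1L, end(a1),
                      as.character(seqnames(a2)), start(a2) - 1L, end(a2), ids)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a methylation track (methratio-style TSV)
#'
#' Expects a header and the columns of the \code{colMap} (chrom, 1-based
#' position, strand, context, ratio in [0, 1], coverage). Non-CpG contexts
#' are dropped (with a message); CpGs measured on both strands are collapsed
#' coverage-weighted into one dinucleotide record at the C position of the
#' plus strand.
#'
#' @param path TSV path.
#' @param condition condition label for the track.
#' @param colMap named list mapping the required fields to column names.
#' @return A \linkS4class{MethylationTrack}.
#' @export
readMethylation <- function(path, condition = "WT",
                            colMap = list(chrom = "chr", pos = "pos",
                                          strand = "strand", context = "context",
                                          ratio = "ratio", coverage = "coverage")) {
    tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    need <- unlist(colMap)
    miss <- setdiff(need, colnames(tab))
    if (length(miss)) stop("missing columns in '", path, "': ", paste(miss, collapse = ", "))
    ratio <- tab[[colMap$ratio]]
    if (any(ratio < 0 | ratio > 1, na.rm = TRUE))
        stop("methylation ratios outside [0, 1] in '", path, "'")
    isCpg <- tab[[colMap$context]] %in% c("CG", "CpG")
    nDropped <- sum(!isCpg)
    if (nDropped) message("dropped ", nDropped, " non-CpG context rows")
    tab <- tab[isCpg, ]
    pos <- tab[[colMap$pos]]
    minus <- tab[[colMap$strand]] == "-"
    pos[minus] <- pos[minus] - 1L  # G of the minus strand -> C position
    key <- paste0(tab[[colMap$chrom]], ":", pos)
    cov <- tab[[colMap$coverage]]
    wsum <- rowsum(tab[[colMap$ratio]] * cov, key)
    csum <- rowsum(cov, key)
    keys <- rownames(wsum)
    parts <- strsplit(keys, ":", fixed = TRUE)
    gr <- GRanges(vapply(parts, `[`, "", 1L),
                  IRanges(as.integer(vapply(parts, `[`, "", 2L)), width = 1L),
                  ratio = unname(ifelse(csum[, 1] > 0, wsum[, 1] / csum[, 1],
                                        NA_real_)),
                  coverage = unname(as.integer(csum[, 1])))
    methylationTrack(gr, condition)
}

#' Write a methylation track as methratio-style TSV
#'
#' @param track a \linkS4class{MethylationTrack}.
#' @param path output path.
#' @export
writeMethylation <- function(track, path) {
    gr <- methRecords(track)
    tab <- data.frame(chr = as.character(seqnames(gr)), pos = start(gr),
                      strand = "+", context = "CG",
                      ratio = mcols(gr)$ratio, coverage = mcols(gr)$coverage)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read nucleosome fragments from a 3-column BED
#'
#' @param path BED3 path.
#' @param replicate,condition labels for the resulting set.
#' @return A \linkS4class{FragmentSet}.
#' @export
readFragments <- function(path, replicate = "rep1", condition = "WT") {
    tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("fragment BED '", path, "' needs >= 3 columns")
    fragmentSet(GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]])),
                replicate, condition)
}

#' Write nucleosome fragments as 3-column BED
#' @param frags a \linkS4class{FragmentSet}.
#' @param path output path.
#' @export
writeFragments <- function(frags, path) {
    gr <- fragments(frags)
    write.table(data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr)),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write a signal or affinity track as bedGraph
#'
#' Runs of equal value become bedGraph lines (0-based half-open); missing
#' (NA) stretches are omitted.
#'
#' @param track \linkS4class{SignalTrack} or \linkS4class{AffinityTrack}.
#' @param path output path.
#' @param log transform values with natural log before writing (for
#'   log-affinity tracks).
#' @export
writeBedGraph <- function(track, path, log = FALSE) {
    values <- trackValues(track)
    grs <- lapply(names(values), function(ch) {
        v <- values[[ch]]
        ends <- cumsum(runLength(v))
        starts <- ends - runLength(v) + 1L
        val <- runValue(v)
        keep <- !is.na(val)
        if (!any(keep)) return(GRanges())
        GRanges(ch, IRanges(starts[keep], ends[keep]),
                score = if (log) base::log(val[keep]) else val[keep])
    })
    gr <- suppressWarnings(do.call(c, unname(grs)))
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read a bedGraph into a SignalTrack
#'
#' @param path bedGraph path.
#' @param seqlens optional named chromosome lengths (default: max end seen).
#' @param normalization tag stored on the track.
#' @return A \linkS4class{SignalTrack}; positions not covered by any line
#'   are NA.
#' @export
readBedGraph <- function(path, seqlens = NULL, normalization = "raw") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (is.null(seqlens))
        seqlens <- vapply(split(end(gr), as.character(seqnames(gr))), max, 0)
    vals <- lapply(names(seqlens), function(ch) {
        v <- Rle(NA_real_, as.integer(seqlens[[ch]]))
        sel <- gr[seqnames(gr) == ch]
        if (length(sel)) {
            for (i in seq_along(sel))
                v[start(sel)[i]:end(sel)[i]] <- mcols(sel)$score[i]
        }
        v
    })
    names(vals) <- names(seqlens)
    new("SignalTrack", values = as(vals, "RleList"), normalization = normalization)
}

#' Read a transcript table
#'
#' TSV with header columns id, chrom, start, end (1-based closed), strand,
#' log2FC, signif (up/down/ns).
#'
#' @param path TSV path.
#' @return GRanges with mcols id, log2FC, signif.
#' @export
readTranscripts <- function(path) {
    tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    need <- c("id", "chrom", "start", "end", "strand", "log2FC", "signif")
    miss <- setdiff(need, colnames(tab))
    if (length(miss)) stop("missing columns in '", path, "': ", paste(miss, collapse = ", "))
    if (!all(tab$signif %in% c("up", "down", "ns")))
        stop("signif must be up/down/ns in '", path, "'")
    GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = tab$strand,
            id = tab$id, log2FC = tab$log2FC, signif = tab$signif)
}

#' Write a transcript table
#' @param tx GRanges with mcols id, log2FC, signif.
#' @param path output path.
#' @export
writeTranscripts <- function(tx, path) {
    tab <- data.frame(id = mcols(tx)$id, chrom = as.character(seqnames(tx)),
                      start = start(tx), end = end(tx),
                      strand = as.character(strand(tx)),
                      log2FC = mcols(tx)$log2FC, signif = mcols(tx)$signif)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.grToList <- function(gr) {
    out <- list(chrom = as.character(seqnames(gr)), start = start(gr),
                end = end(gr), strand = as.character(strand(gr)))
    for (nm in colnames(mcols(gr))) out[[nm]] <- mcols(gr)[[nm]]
    out
}

.listToGr <- function(x) {
    if (is.null(x) || !length(x$chrom))
        return(GRanges())
    gr <- GRanges(x$chrom, IRanges(x$start, x$end), strand = x$strand)
    for (nm in setdiff(names(x), c("chrom", "start", "end", "strand")))
        mcols(gr)[[nm]] <- x[[nm]]
    gr
}

#' Write the truth manifest as JSON
#' @param manifest a \linkS4class{TruthManifest}.
#' @param path output path.
#' @export
writeManifest <- function(manifest, path) {
    obj <- list(sites = .grToList(manifest@sites),
                dmrs = .grToList(manifest@dmrs),
                nrlTrue = manifest@nrlTrue,
                boundaries = .grToList(manifest@boundaries),
                loopBoundaries = .grToList(manifest@loopBoundaries),
                downregulated = manifest@downregulated)
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read a truth manifest from JSON
#' @param path JSON path.
#' @return A \linkS4class{TruthManifest}.
#' @export
readManifest <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("TruthManifest", sites = .listToGr(x$sites), dmrs = .listToGr(x$dmrs),
        nrlTrue = as.numeric(x$nrlTrue), boundaries = .listToGr(x$boundaries),
        loopBoundaries = .listToGr(x$loopBoundaries),
        downregulated = as.character(x$downregulated))
}

#' Write all inputs of a simulated epigenome to a directory
#'
#' @param sim result of \code{\link{simulateEpigenome}}.
#' @param outdir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeEpigenome <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(outdir, ...)
    writeXStringSet(sim$bundle$genome, p("genome.fa"))
    writeBed(sim$bundle$islands, p("islands.bed"))
    for (cond in c("wt", "dko")) {
        for (r in seq_along(sim$peaks[[cond]]))
            writeBed(sim$peaks[[cond]][[r]], p(sprintf("peaks_%s_rep%d.bed", cond, r)))
        for (r in seq_along(sim$fragments[[cond]]))
            writeFragments(sim$fragments[[cond]][[r]],
                           p(sprintf("fragments_%s_rep%d.bed", cond, r)))
    }
    writeMethylation(sim$meth$wt, p("methylation_wt.tsv"))
    writeMethylation(sim$meth$dko, p("methylation_dko.tsv"))
    writeTranscripts(sim$expression$transcripts, p("transcripts.tsv"))
    writeBed(sim$expression$tads, p("tads.bed"))
    if (length(sim$expression$loops)) writeBedpe(sim$expression$loops, p("loops.bedpe"))
    prom <- sim$expression$promoters
    mcols(prom)$name <- mcols(prom)$id
    writeBed(prom, p("promoters.bed"))
    writeManifest(sim$manifest, p("manifest.json"))
    invisible(outdir)
}
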