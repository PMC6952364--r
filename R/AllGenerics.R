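#' @include AllClasses.R
NULL

#' @rdname JunctionSet
#' @param object a `JunctionSet`
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname SpliceEventSet
#' @param object an object with event rows
#' @export
setGeneric("eventIds", function(object) standardGeneric("eventIds"))

#' @rdname SpliceEventSet
#' @export
setGeneric("eventType", function(object) standardGeneric("eventType"))

#' @rdname SpliceEventSet
#' @export
setGeneric("exonIntervals", function(object) standardGeneric("exonIntervals"))

#' @rdname SpliceEventSet
#' @export
setGeneric("inclusionJunctions",
           function(object) standardGeneric("inclusionJunctions"))

#' @rdname SpliceEventSet
#' @export
setGeneric("exclusionJunctions",
           function(object) standardGeneric("exclusionJunctions"))

#' @rdname SpliceEventSet
#' @export
setGeneric("annotatedFlag", function(object) standardGeneric("annotatedFlag"))

#' @rdname SpliceEventSet
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

# ---- JunctionSet methods -----------------------------------------------

#' @describeIn JunctionSet sample-to-group mapping (named character vector;
#'   samples without metadata carry group `"ungrouped"`).
#' @export
setMethod("sampleGroups", "JunctionSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if ("group" %in% colnames(cd))
        stats::setNames(as.character(cd$group), rownames(cd))
    else
        stats::setNames(rep("ungrouped", ncol(object)), colnames(object))
})

setMethod("show", "JunctionSet", function(object) {
    grp <- sampleGroups(object)
    cat("JunctionSet with", nrow(object), "junctions x", ncol(object),
        "samples\n")
    cat("  chromosomes:", paste(
        unique(as.character(GenomicRanges::seqnames(rowRanges(object)))),
        collapse = ", "), "\n")
    cat("  groups:", paste(unique(grp), collapse = ", "), "\n")
})

# ---- SpliceEventSet methods --------------------------------------------

#' @describeIn SpliceEventSet event identifiers (stable, sortable strings).
#' @export
setMethod("eventIds", "SpliceEventSet", function(object) object@events$eventId)

#' @describeIn SpliceEventSet event types.
#' @export
setMethod("eventType", "SpliceEventSet",
          function(object) object@events$eventType)

#' @describeIn SpliceEventSet exon intervals as a named `IRangesList`
#'   (1-based, closed), one element per event.
#' @export
setMethod("exonIntervals", "SpliceEventSet", function(object) {
    ev <- object@events
    rl <- IRanges::IRangesList(lapply(seq_len(nrow(ev)), function(i)
        IRanges::IRanges(start = ev$exonStarts[[i]], end = ev$exonEnds[[i]])))
    names(rl) <- ev$eventId
    rl
})

#' @describeIn SpliceEventSet inclusion-loop junction keys per event
#'   (`CharacterList` of `chrom:start-end`).
#' @export
setMethod("inclusionJunctions", "SpliceEventSet", function(object) {
    x <- object@events$inclusion
    names(x) <- object@events$eventId
    x
})

#' @describeIn SpliceEventSet exclusion-loop junction keys per event.
#' @export
setMethod("exclusionJunctions", "SpliceEventSet", function(object) {
    x <- object@events$exclusion
    names(x) <- object@events$eventId
    x
})

#' @describeIn SpliceEventSet tri-state annotation flag per event.
#' @export
setMethod("annotatedFlag", "SpliceEventSet", function(object)
    stats::setNames(object@events$annotated, object@events$eventId))

#' @describeIn SpliceEventSet dropped non-binary candidates with reason codes.
#' @export
setMethod("diagnostics", "SpliceEventSet",
          function(object) object@diagnostics)

setMethod("length", "SpliceEventSet", function(x) nrow(x@events))

setMethod("show", "SpliceEventSet", function(object) {
    cat("SpliceEventSet with", length(object), "events\n")
    if (length(object)) {
        tab <- table(eventType(object))
        cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
        atab <- table(annotatedFlag(object))
        cat("  annotation:",
            paste(names(atab), atab, sep = ": ", collapse = ", "), "\n")
    }
    if (nrow(object@diagnostics))
        cat("  dropped non-binary candidates:", nrow(object@diagnostics), "\n")
})

#' Subset a SpliceEventSet by index, id or logical mask
#'
#' @param x a `SpliceEventSet`
#' @param i numeric, character (event ids) or logical index
#' @param j,...,drop ignored
#' @export
setMethod("[", "SpliceEventSet", function(x, i, j, ..., drop = FALSE) {
    ev <- x@events
    if (is.character(i)) i <- match(i, ev$eventId)
    initialize(x, events = ev[i, , drop = FALSE], diagnostics = x@diagnostics)
})

setMethod("show", "PsiExperiment", function(object) {
    psi <- SummarizedExperiment::assay(object, "psi")
    cat("PsiExperiment with", nrow(object), "events x", ncol(object),
        "samples\n")
    cat(sprintf("  %.1f%% of cells informative\n",
                100 * mean(!is.na(psi))))
})

setMethod("show", "MotifProfile", function(object) {
    cat("MotifProfile:", object@motif, "at", object@anchor, "\n")
    cat("  ", nrow(object@bins), " bins, ", sum(object@bins$count),
        " occurrences over ", object@nExons, " exons\n", sep = "")
    if (object@nBaselineExons > 0)
        cat("  baseline:", object@nBaselineExons, "exons\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@loci), "loci,",
        sum(object@groups), "samples in", length(object@groups), "groups\n")
    cat("  depth", object@depth, " dispersion", object@dispersion,
        " noiseRate", object@noiseRate, " seed", object@seed, "\n")
})
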