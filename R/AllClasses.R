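#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges IRangesList IntegerList CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowRanges
NULL

#' JunctionSet: a splice-junction count table
#'
#' A `JunctionSet` holds one row per splice junction and one column per sample
#' (run accession). A junction is an intron identified by chromosome, the
#' 1-based positions of its first and last intronic base, and a strand
#' (`+`, `-`, or `*` for unknown). The single `"counts"` assay holds
#' non-negative integer split-read counts. An optional `group` column in
#' `colData` assigns each sample to a group (cell type, tissue).
#'
#' The class extends [SummarizedExperiment::RangedSummarizedExperiment-class];
#' `rowRanges()` gives the intron coordinates. Rows are kept sorted by
#' (chromosome, start, end) and are duplicate-free.
#'
#' @slot .. inherited from `RangedSummarizedExperiment`.
#' @seealso [JunctionSet()], [readStarJunctions()], [readJunctionMatrix()]
#' @exportClass JunctionSet
setClass("JunctionSet", contains = "RangedSummarizedExperiment")

setValidity("JunctionSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0, na.rm = TRUE))
            msg <- c(msg, "junction counts must be non-negative")
        if (anyNA(cnt))
            msg <- c(msg, "junction counts must not be NA")
    }
    if (ncol(object) > 0 && anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    gr <- SummarizedExperiment::rowRanges(object)
    if (length(gr) > 0) {
        if (any(GenomicRanges::start(gr) > GenomicRanges::end(gr)))
            msg <- c(msg, "junction start must not exceed end")
        key <- paste0(GenomicRanges::seqnames(gr), ":",
                      GenomicRanges::start(gr), "-", GenomicRanges::end(gr),
                      ":", GenomicRanges::strand(gr))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate junctions (chrom,start,end,strand)")
        o <- order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
        if (!identical(o, seq_along(gr)))
            msg <- c(msg, "junctions must be sorted by (chrom, start, end)")
    }
    if (length(msg)) msg else TRUE
})

#' SpliceEventSet: classified binary splicing events
#'
#' Container for the output of [discoverEvents()]: one row per event with its
#' type (`cassette`, `alt_ss_group`, `linked`, `mutually_exclusive`), the
#' inclusion- and exclusion-loop junction keys, the exon interval(s) inferred
#' between inclusion junctions, strand, and a tri-state annotation flag
#' (`annotated` / `unannotated` / `unknown`). A diagnostics table records
#' candidates dropped as non-binary, with reason codes.
#'
#' @slot events `DataFrame` with columns `eventId`, `eventType`, `chrom`,
#'   `strand`, `annotated`, `exonStarts` (`IntegerList`), `exonEnds`
#'   (`IntegerList`), `inclusion` (`CharacterList` of junction keys
#'   `chrom:start-end`), `exclusion` (`CharacterList`).
#' @slot diagnostics `DataFrame` with columns `reason`, `chrom`, `detail`.
#' @seealso [discoverEvents()], [annotateEvents()]
#' @exportClass SpliceEventSet
setClass("SpliceEventSet",
    slots = c(events = "DataFrame", diagnostics = "DataFrame"))

.EVENT_TYPES <- c("cassette", "alt_ss_group", "linked", "mutually_exclusive")

setValidity("SpliceEventSet", function(object) {
    ev <- object@events
    need <- c("eventId", "eventType", "chrom", "strand", "annotated",
              "exonStarts", "exonEnds", "inclusion", "exclusion")
    if (!all(need %in% colnames(ev)))
        return(paste("events must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(ev$eventId))
        msg <- c(msg, "event ids must be unique")
    if (!all(ev$eventType %in% .EVENT_TYPES))
        msg <- c(msg, "unknown event type")
    if (!all(ev$annotated %in% c("annotated", "unannotated", "unknown")))
        msg <- c(msg, "annotated flag must be annotated/unannotated/unknown")
    for (i in seq_len(nrow(ev))) {
        es <- ev$exonStarts[[i]]; ee <- ev$exonEnds[[i]]
        if (length(es) != length(ee) || any(es > ee))
            msg <- c(msg, sprintf("event %s: malformed exon intervals",
                                  ev$eventId[i]))
        if (length(intersect(ev$inclusion[[i]], ev$exclusion[[i]])))
            msg <- c(msg, sprintf(
                "event %s: inclusion and exclusion junctions overlap",
                ev$eventId[i]))
    }
    if (length(msg)) msg else TRUE
})

#' PsiExperiment: events-by-samples percent-spliced-in matrix
#'
#' Output of [quantifyPsi()]. Two assays: `psi` (0-100 scale, `NA` where the
#' cell had fewer informative reads than `min_informative`) and `informative`
#' (the rounded inclusion-plus-exclusion read support behind each cell).
#' `rowData()` carries the event description; `colData()` the sample groups.
#'
#' @seealso [quantifyPsi()], [writePsiMatrix()]
#' @exportClass PsiExperiment
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("psi", "informative") %in% an))
        return("assays 'psi' and 'informative' are required")
    psi <- SummarizedExperiment::assay(object, "psi")
    inf <- SummarizedExperiment::assay(object, "informative")
    msg <- character()
    ok <- !is.na(psi)
    if (any(psi[ok] < 0 | psi[ok] > 100))
        msg <- c(msg, "PSI values must lie in [0, 100]")
    if (any(inf < 0, na.rm = TRUE))
        msg <- c(msg, "informative read totals must be non-negative")
    if (length(msg)) msg else TRUE
})

#' MotifProfile: positional motif counts around splice sites
#'
#' Positional occurrence counts of a short nucleotide motif in windows anchored
#' at one splice site (`5prime_ss` donor or `3prime_ss` acceptor) of a set of
#' event exons, in transcript orientation. Bin positions are signed distances
#' from the splice site: intronic bases negative, exonic bases positive, so the
#' window spans `-intronic_flank .. +exonic_flank`. Per-bin counts are also
#' normalized per exon, and when a baseline exon set was profiled the per-bin
#' enrichment ratio is filled in.
#'
#' @slot motif character; the motif, DNA alphabet (U accepted as T).
#' @slot anchor `"5prime_ss"` or `"3prime_ss"`.
#' @slot bins data.frame with columns `bin_start`, `bin_end` (signed positions),
#'   `count`, `per_exon_mean`, `baseline_per_exon_mean`, `enrichment`.
#' @slot nExons number of exons profiled.
#' @slot nBaselineExons number of baseline exons (0 when no baseline attached).
#' @seealso [positionalProfile()], [baselineProfile()]
#' @exportClass MotifProfile
setClass("MotifProfile",
    slots = c(motif = "character", anchor = "character", bins = "data.frame",
              nExons = "numeric", nBaselineExons = "numeric"))

setValidity("MotifProfile", function(object) {
    msg <- character()
    if (!object@anchor %in% c("5prime_ss", "3prime_ss"))
        msg <- c(msg, "anchor must be 5prime_ss or 3prime_ss")
    b <- object@bins
    need <- c("bin_start", "bin_end", "count", "per_exon_mean",
              "baseline_per_exon_mean", "enrichment")
    if (!all(need %in% colnames(b)))
        msg <- c(msg, paste("bins must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(b$count < 0)) msg <- c(msg, "counts must be non-negative")
        if (nrow(b) > 1) {
            # positions are signed distances from the splice site: there is
            # no position 0, so the tiling may step from -1 straight to +1
            step_ok <- b$bin_start[-1] == b$bin_end[-nrow(b)] + 1 |
                (b$bin_end[-nrow(b)] == -1 & b$bin_start[-1] == 1)
            if (!all(step_ok))
                msg <- c(msg,
                         "bins must tile the window without gaps or overlap")
        }
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground truth for a simulated junction-count study
#'
#' Describes a set of loci with known event structure together with group-wise
#' true inclusion rates, sequencing depth, overdispersion, group sizes, a
#' noise-junction rate and the master seed. [simulateJunctions()] turns it into
#' a [JunctionSet] (plus the implied event list); [simulateGenome()] writes a
#' matching genome FASTA and GTF.
#'
#' @slot loci list of locus descriptions as built by [syntheticLocus()].
#' @slot truePsi numeric matrix, events x groups, inclusion rates in \[0,1\].
#' @slot depth expected informative reads per event per sample.
#' @slot dispersion negative-binomial overdispersion (0 = Poisson).
#' @slot groups named integer vector: samples per group.
#' @slot noiseRate expected spurious junctions per locus per table.
#' @slot seed integer master seed; all randomness flows from it.
#' @seealso [syntheticTruth()], [simulateJunctions()], [simulateGenome()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    slots = c(loci = "list", truePsi = "matrix", depth = "numeric",
              dispersion = "numeric", groups = "integer",
              noiseRate = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (any(object@truePsi < 0 | object@truePsi > 1))
        msg <- c(msg, "true PSI values must lie in [0, 1]")
    if (object@depth <= 0) msg <- c(msg, "depth must be positive")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (object@noiseRate < 0) msg <- c(msg, "noiseRate must be >= 0")
    if (is.null(names(object@groups)) || any(object@groups < 1))
        msg <- c(msg, "groups must be a named vector of positive sample counts")
    if (length(object@loci) != nrow(object@truePsi))
        msg <- c(msg, "one truePsi row per locus is required")
    if (length(msg)) msg else TRUE
})
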