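#' @include AllClasses.R AllGenerics.R utils.R
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#'   matchPattern subseq
NULL

.as_genome <- function(genome) {
    if (is.character(genome) && length(genome) == 1)
        genome <- Biostrings::readDNAStringSet(genome)
    if (!methods::is(genome, "DNAStringSet"))
        stop("genome must be a DNAStringSet or a FASTA path")
    names(genome) <- sub("\\s.*$", "", names(genome))
    genome
}

# Signed position of sequence index j in a transcript-oriented window of
# width w: intron negative, exon positive, |position| = distance from the
# splice site (adjacent base = 1).
.window_positions <- function(side, near_first, w) {
    if (w <= 0) return(integer(0))
    d <- if (near_first) seq_len(w) else rev(seq_len(w))
    if (side == "intronic") -d else d
}

# Extract the four splice-site windows for one exon, transcript-oriented.
# Returns list of list(seq = character, side, anchor, near_first).
.exon_windows <- function(genome, chrom, b, t, strand, intronic_flank,
                          exonic_flank, event_id = "") {
    if (!chrom %in% names(genome))
        stop("chromosome ", chrom, " absent from genome",
             if (nzchar(event_id)) paste0(" (event ", event_id, ")"))
    chrlen <- length(genome[[chrom]])
    L <- t - b + 1L
    half <- min(exonic_flank, L %/% 2L)
    seg <- function(lo, hi) {
        lo <- max(1L, lo); hi <- min(chrlen, hi)
        if (lo > hi) return("")
        as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
    }
    rc <- function(x) if (nzchar(x))
        as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
            x))[[1]]) else x
    if (strand == "+") {
        list(
            list(anchor = "5prime_ss", side = "intronic", near_first = TRUE,
                 seq = seg(t + 1L, t + intronic_flank)),
            list(anchor = "5prime_ss", side = "exonic", near_first = FALSE,
                 seq = if (half > 0) seg(t - half + 1L, t) else ""),
            list(anchor = "3prime_ss", side = "intronic", near_first = FALSE,
                 seq = seg(b - intronic_flank, b - 1L)),
            list(anchor = "3prime_ss", side = "exonic", near_first = TRUE,
                 seq = if (half > 0) seg(b, b + half - 1L) else ""))
    } else {
        list(
            list(anchor = "5prime_ss", side = "intronic", near_first = TRUE,
                 seq = rc(seg(b - intronic_flank, b - 1L))),
            list(anchor = "5prime_ss", side = "exonic", near_first = FALSE,
                 seq = if (half > 0) rc(seg(b, b + half - 1L)) else ""),
            list(anchor = "3prime_ss", side = "intronic", near_first = FALSE,
                 seq = rc(seg(t + 1L, t + intronic_flank))),
            list(anchor = "3prime_ss", side = "exonic", near_first = TRUE,
                 seq = if (half > 0) rc(seg(t - half + 1L, t)) else ""))
    }
}

#' Extract splice-site-anchored sequence windows for event exons
#'
#' For every exon of every stranded event, extracts the four windows used by
#' the positional motif analysis: intronic flanks (default 1000 bases) and
#' exonic margins (default 50 bases) at the 5' (donor) and 3' (acceptor)
#' splice sites. Sequences are reverse-complemented on the minus strand so
#' that all windows read in transcript orientation. Windows are truncated,
#' never padded, at chromosome ends; the two exonic windows of a short exon
#' are each clipped at half the exon length so they never overlap. The 5'SS
#' is the exon's downstream (donor) boundary in transcript orientation, the
#' 3'SS its upstream (acceptor) boundary.
#'
#' @param events a [SpliceEventSet]; events with unknown strand are skipped.
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param intronic_flank intronic window width in bases (default 1000).
#' @param exonic_flank exonic window width in bases (default 50).
#' @return list with one element per (event, exon): `event_id`, `exon`
#'   (interval string), and `windows`, a named character vector with entries
#'   `five_intronic`, `five_exonic`, `three_intronic`, `three_exonic`.
#' @export
extractSpliceWindows <- function(events, genome, intronic_flank = 1000L,
                                 exonic_flank = 50L) {
    .check_flag(intronic_flank, "intronic_flank", lo = 1, integer = TRUE)
    .check_flag(exonic_flank, "exonic_flank", lo = 1, integer = TRUE)
    genome <- .as_genome(genome)
    ev <- events@events
    out <- list()
    for (i in seq_len(nrow(ev))) {
        if (!ev$strand[i] %in% c("+", "-")) next
        es <- ev$exonStarts[[i]]; ee <- ev$exonEnds[[i]]
        for (k in seq_along(es)) {
            w <- .exon_windows(genome, ev$chrom[i], es[k], ee[k],
                               ev$strand[i], as.integer(intronic_flank),
                               as.integer(exonic_flank), ev$eventId[i])
            wv <- vapply(w, `[[`, "", "seq")
            names(wv) <- c("five_intronic", "five_exonic",
                           "three_intronic", "three_exonic")
            out[[length(out) + 1L]] <- list(
                event_id = ev$eventId[i],
                exon = paste0(es[k], "-", ee[k]), windows = wv)
        }
    }
    out
}

.empty_bins <- function(intronic_flank, exonic_flank, bin_width) {
    if (intronic_flank %% bin_width != 0 || exonic_flank %% bin_width != 0)
        stop("flanks must be multiples of bin_width")
    starts <- c(seq(-intronic_flank, -bin_width, by = bin_width),
                seq(1, exonic_flank, by = bin_width))
    data.frame(bin_start = starts, bin_end = starts + bin_width - 1L,
               count = 0, per_exon_mean = NA_real_,
               baseline_per_exon_mean = NA_real_, enrichment = NA_real_)
}

# Count overlapping motif occurrences in transcript-oriented windows of a
# set of exons; tally by the signed position of each occurrence's first base.
.profile_engine <- function(exons, genome, motifs, bin_width, intronic_flank,
                            exonic_flank) {
    motifs <- vapply(motifs, .normalize_motif, "")
    bins <- lapply(c("5prime_ss", "3prime_ss"), function(a)
        .empty_bins(intronic_flank, exonic_flank, bin_width))
    names(bins) <- c("5prime_ss", "3prime_ss")
    n_exon <- 0L
    for (x in exons) {
        n_exon <- n_exon + 1L
        wins <- .exon_windows(genome, x$chrom, x$start, x$end, x$strand,
                              intronic_flank, exonic_flank)
        for (w in wins) {
            sq <- w$seq
            if (!nzchar(sq)) next
            pos <- .window_positions(w$side, w$near_first, nchar(sq))
            for (mf in motifs) {
                if (nchar(sq) < nchar(mf)) next
                hits <- Biostrings::matchPattern(mf, Biostrings::DNAString(sq))
                st <- BiocGenerics::start(hits)
                if (!length(st)) next
                p <- pos[st]
                b <- bins[[w$anchor]]
                k <- findInterval(p, b$bin_start)
                ok <- k >= 1 & p <= b$bin_end[pmax(k, 1)]
                for (kk in k[ok])
                    bins[[w$anchor]]$count[kk] <-
                        bins[[w$anchor]]$count[kk] + 1
            }
        }
    }
    for (a in names(bins))
        bins[[a]]$per_exon_mean <- if (n_exon > 0)
            bins[[a]]$count / n_exon else NA_real_
    list(bins = bins, n_exon = n_exon)
}

.events_to_exons <- function(events) {
    ev <- events@events
    out <- list()
    for (i in seq_len(nrow(ev))) {
        if (!ev$strand[i] %in% c("+", "-")) next
        es <- ev$exonStarts[[i]]; ee <- ev$exonEnds[[i]]
        for (k in seq_along(es))
            out[[length(out) + 1L]] <- list(chrom = ev$chrom[i],
                                            start = es[k], end = ee[k],
                                            strand = ev$strand[i])
    }
    out
}

#' Positional motif profile around event exons
#'
#' Counts occurrences of a motif (overlapping matches, scanned base by base;
#' each occurrence assigned to the bin of its first base) in the
#' splice-site-anchored windows of all stranded event exons, and returns one
#' [MotifProfile] per anchor. Positions are signed distances from the splice
#' site (intron negative, exon positive) in transcript orientation. U and T
#' are treated identically. Passing several motifs (e.g. `c("CUCU","UCUC")`
#' for CU/UC repeats) sums their profiles; `motif = "ptbp1"` is a preset for
#' exactly that pair.
#'
#' @param events a [SpliceEventSet].
#' @param genome named `DNAStringSet` or FASTA path.
#' @param motif motif string(s), length >= 3 each, over A/C/G/U(T);
#'   or the preset name `"ptbp1"`.
#' @param bin_width positional bin width in bases (default 25).
#' @param intronic_flank,exonic_flank window extents (defaults 1000 and 50).
#' @return named list of two [MotifProfile] objects: `fiveprime` and
#'   `threeprime`.
#' @export
positionalProfile <- function(events, genome, motif = "TAG", bin_width = 25L,
                              intronic_flank = 1000L, exonic_flank = 50L) {
    if (identical(motif, "ptbp1")) motif <- c("CUCU", "UCUC")
    if (any(nchar(motif) < 3)) stop("motif length must be >= 3")
    genome <- .as_genome(genome)
    exons <- .events_to_exons(events)
    res <- .profile_engine(exons, genome, motif, as.integer(bin_width),
                           as.integer(intronic_flank),
                           as.integer(exonic_flank))
    label <- paste(vapply(motif, .normalize_motif, ""), collapse = "+")
    list(fiveprime = methods::new("MotifProfile", motif = label,
                                  anchor = "5prime_ss",
                                  bins = res$bins[["5prime_ss"]],
                                  nExons = res$n_exon, nBaselineExons = 0),
         threeprime = methods::new("MotifProfile", motif = label,
                                   anchor = "3prime_ss",
                                   bins = res$bins[["3prime_ss"]],
                                   nExons = res$n_exon, nBaselineExons = 0))
}

#' Baseline motif profile over annotated protein-coding exons
#'
#' Applies the same windowing and counting as [positionalProfile()] to all
#' protein-coding exons shorter than `max_exon_len` bases (strict) in a gene
#' annotation, after deduplicating identical intervals. Used as the
#' denominator for enrichment ratios.
#'
#' @param annotation GTF path or `GRanges` of protein-coding exon features.
#' @param genome named `DNAStringSet` or FASTA path.
#' @param max_exon_len strict upper bound on exon length (default 400).
#' @param motif,bin_width,intronic_flank,exonic_flank as in
#'   [positionalProfile()].
#' @return named list of two [MotifProfile] objects (`fiveprime`,
#'   `threeprime`).
#' @export
baselineProfile <- function(annotation, genome, max_exon_len = 400L,
                            motif = "TAG", bin_width = 25L,
                            intronic_flank = 1000L, exonic_flank = 50L) {
    if (identical(motif, "ptbp1")) motif <- c("CUCU", "UCUC")
    genome <- .as_genome(genome)
    gr <- if (is.character(annotation))
        readGtfExons(annotation, protein_coding_only = TRUE)
    else annotation
    st <- as.character(GenomicRanges::strand(gr))
    gr <- gr[st %in% c("+", "-")]
    gr <- gr[GenomicRanges::width(gr) < max_exon_len]
    if (!length(gr)) stop("annotation has no usable protein-coding exons")
    key <- paste0(GenomicRanges::seqnames(gr), ":", GenomicRanges::start(gr),
                  "-", GenomicRanges::end(gr), ":",
                  GenomicRanges::strand(gr))
    gr <- gr[!duplicated(key)]
    exons <- lapply(seq_along(gr), function(i) list(
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i],
        strand = as.character(GenomicRanges::strand(gr))[i]))
    res <- .profile_engine(exons, genome, motif, as.integer(bin_width),
                           as.integer(intronic_flank),
                           as.integer(exonic_flank))
    label <- paste(vapply(motif, .normalize_motif, ""), collapse = "+")
    list(fiveprime = methods::new("MotifProfile", motif = label,
                                  anchor = "5prime_ss",
                                  bins = res$bins[["5prime_ss"]],
                                  nExons = res$n_exon, nBaselineExons = 0),
         threeprime = methods::new("MotifProfile", motif = label,
                                   anchor = "3prime_ss",
                                   bins = res$bins[["3prime_ss"]],
                                   nExons = res$n_exon, nBaselineExons = 0))
}

#' Attach a baseline to a motif profile
#'
#' Copies the per-exon means of a baseline profile into the event profile and
#' fills the per-bin enrichment ratio where the baseline mean is positive.
#'
#' @param profile a [MotifProfile] from [positionalProfile()].
#' @param baseline the matching-anchor [MotifProfile] from
#'   [baselineProfile()].
#' @return the profile with `baseline_per_exon_mean` and `enrichment` filled.
#' @export
withBaseline <- function(profile, baseline) {
    if (profile@anchor != baseline@anchor)
        stop("profile and baseline anchors differ")
    if (nrow(profile@bins) != nrow(baseline@bins))
        stop("profile and baseline bin layouts differ")
    b <- profile@bins
    b$baseline_per_exon_mean <- baseline@bins$per_exon_mean
    b$enrichment <- ifelse(b$baseline_per_exon_mean > 0,
                           b$per_exon_mean / b$baseline_per_exon_mean,
                           NA_real_)
    methods::initialize(profile, bins = b,
                        nBaselineExons = baseline@nExons)
}

#' Mean enrichment in the proximal intronic window
#'
#' Averages the per-bin enrichment over the intronic bins within `window`
#' bases of the splice site (for the default 25-base bins and a 200-base
#' window, the last eight intronic bins). The statistic used to summarize
#' proximal-intron motif clustering at the 5' splice site.
#'
#' @param profile a [MotifProfile] with baseline attached.
#' @param window proximal window width in bases (default 200).
#' @return mean enrichment (NA if no bin has a defined ratio).
#' @export
proximalEnrichment <- function(profile, window = 200L) {
    b <- profile@bins
    sel <- b$bin_end <= -1L & b$bin_start >= -as.integer(window)
    mean(b$enrichment[sel], na.rm = TRUE)
}

#' Write motif profiles as a TSV
#'
#' @param profiles named list of [MotifProfile] (as returned by
#'   [positionalProfile()]), baselines attached or not.
#' @param path output TSV path with columns anchor, bin_start, bin_end,
#'   count, per_exon_mean, baseline, enrichment.
#' @return invisibly, `path`.
#' @export
writeMotifProfiles <- function(profiles, path) {
    rows <- lapply(profiles, function(p)
        cbind(data.frame(anchor = p@anchor, motif = p@motif,
                         stringsAsFactors = FALSE), p@bins))
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
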