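#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a JunctionSet from coordinates and counts
#'
#' Coordinates follow the STAR / junction-database convention: 1-based, fully
#' closed, `start` and `end` are the first and last base of the intron.
#' Junctions shorter than `min_intron` are dropped (alignment artifacts);
#' duplicate (chrom, start, end, strand) rows are collapsed by summing counts;
#' rows are sorted by (chrom, start, end).
#'
#' @param junctions data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`+`, `-` or `*`).
#' @param counts integer matrix, one row per junction, one column per sample.
#' @param sample_ids character vector of unique sample identifiers.
#' @param groups optional named character vector mapping sample id to group;
#'   samples not named get group `"ungrouped"`.
#' @param min_intron minimum intron length in bases (default 20).
#' @return a [JunctionSet].
#' @export
JunctionSet <- function(junctions, counts, sample_ids,
                        groups = NULL, min_intron = 20L) {
    counts <- as.matrix(counts)
    if (nrow(junctions) != nrow(counts))
        stop("junctions and counts disagree on row count")
    if (length(sample_ids) != ncol(counts))
        stop("sample_ids length must match count columns")
    if (anyDuplicated(sample_ids))
        stop("duplicate sample_id: ",
             sample_ids[duplicated(sample_ids)][1])
    if (any(counts < 0)) stop("negative junction count (corrupt input)")
    strand <- as.character(junctions$strand)
    strand[!strand %in% c("+", "-")] <- "*"
    keep <- (junctions$end - junctions$start + 1L) >= min_intron
    junctions <- junctions[keep, , drop = FALSE]
    counts <- counts[keep, , drop = FALSE]
    strand <- strand[keep]

    key <- paste0(junctions$chrom, ":", junctions$start, "-",
                  junctions$end, ":", strand)
    if (anyDuplicated(key)) {
        counts <- rowsum(counts, key, reorder = FALSE)
        first <- !duplicated(key)
        junctions <- junctions[first, , drop = FALSE]
        strand <- strand[first]
        counts <- counts[match(key[first], rownames(counts)), , drop = FALSE]
        rownames(counts) <- NULL
    }
    o <- order(as.character(junctions$chrom), junctions$start, junctions$end)
    junctions <- junctions[o, , drop = FALSE]
    strand <- strand[o]
    counts <- counts[o, , drop = FALSE]

    gr <- GenomicRanges::GRanges(
        seqnames = as.character(junctions$chrom),
        ranges = IRanges::IRanges(start = as.integer(junctions$start),
                                  end = as.integer(junctions$end)),
        strand = strand)
    names(gr) <- if (nrow(junctions))
        .jkey(as.character(junctions$chrom), junctions$start,
              junctions$end)
    else character(0)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(NULL, sample_ids)
    grp <- rep("ungrouped", length(sample_ids))
    if (!is.null(groups)) {
        hit <- match(sample_ids, names(groups))
        grp[!is.na(hit)] <- as.character(groups[hit[!is.na(hit)]])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = gr,
        colData = S4Vectors::DataFrame(group = grp, row.names = sample_ids))
    methods::new("JunctionSet", se)
}

#' Junction keys of a JunctionSet
#'
#' @param js a [JunctionSet]
#' @return character vector `chrom:start-end`, one per junction row.
#' @export
junctionKeys <- function(js) names(SummarizedExperiment::rowRanges(js))

#' Read STAR SJ.out.tab files into a JunctionSet
#'
#' Reads one 8-column `SJ.out.tab` per sample (columns: chrom, intron start,
#' intron end, strand code 0/1/2, motif code, annotated flag, unique reads,
#' multi-mapped reads) and unions the junctions: a junction absent from a
#' sample gets count 0 there. Only unique-read counts are kept; multi-mapped
#' counts are discarded. Strand code 1 maps to `+`, 2 to `-`, 0 to unknown
#' (`*`); unknown-strand junctions are retained.
#'
#' @param paths character vector of SJ.out.tab paths.
#' @param sample_ids character vector of the same length, unique sample names.
#' @param groups optional named character vector: sample id -> group label.
#' @param min_intron minimum intron length (default 20).
#' @return a [JunctionSet].
#' @export
readStarJunctions <- function(paths, sample_ids, groups = NULL,
                              min_intron = 20L) {
    if (length(paths) != length(sample_ids))
        stop("paths and sample_ids must have the same length")
    if (anyDuplicated(sample_ids))
        stop("duplicate sample_id: ",
             sample_ids[duplicated(sample_ids)][1])
    per <- lapply(seq_along(paths), function(i) {
        path <- paths[i]
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        if (!length(lines))
            return(data.frame(chrom = character(), start = integer(),
                              end = integer(), strand = character(),
                              count = integer()))
        fields <- strsplit(lines, "\t", fixed = TRUE)
        nf <- vapply(fields, length, 1L)
        if (any(nf < 8))
            stop(sprintf("malformed STAR SJ line in %s, line %d: %d fields",
                         path, which(nf < 8)[1], nf[nf < 8][1]))
        m <- do.call(rbind, fields)
        start <- suppressWarnings(as.integer(m[, 2]))
        end <- suppressWarnings(as.integer(m[, 3]))
        code <- suppressWarnings(as.integer(m[, 4]))
        uniq <- suppressWarnings(as.integer(m[, 7]))
        bad <- which(is.na(start) | is.na(end) | is.na(code) | is.na(uniq))
        if (length(bad))
            stop(sprintf("malformed STAR SJ line in %s, line %d", path,
                         bad[1]))
        data.frame(chrom = m[, 1], start = start, end = end,
                   strand = c("*", "+", "-")[code + 1L],
                   count = uniq, stringsAsFactors = FALSE)
    })
    all_keys <- unique(unlist(lapply(per, function(d)
        paste0(d$chrom, ":", d$start, "-", d$end, ":", d$strand))))
    if (!length(all_keys)) {
        empty <- data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character())
        return(JunctionSet(empty,
                           matrix(0L, 0, length(sample_ids)),
                           sample_ids, groups, min_intron))
    }
    counts <- matrix(0L, length(all_keys), length(paths),
                     dimnames = list(all_keys, sample_ids))
    for (i in seq_along(per)) {
        d <- per[[i]]
        k <- paste0(d$chrom, ":", d$start, "-", d$end, ":", d$strand)
        counts[k, i] <- counts[k, i] + d$count
    }
    parts <- regmatches(all_keys,
                        regexec("^(.+):([0-9]+)-([0-9]+):(.+)$", all_keys))
    jdf <- data.frame(
        chrom = vapply(parts, `[`, "", 2L),
        start = as.integer(vapply(parts, `[`, "", 3L)),
        end = as.integer(vapply(parts, `[`, "", 4L)),
        strand = vapply(parts, `[`, "", 5L), stringsAsFactors = FALSE)
    JunctionSet(jdf, counts, sample_ids, groups, min_intron)
}

#' Read a junction-count matrix TSV
#'
#' The matrix dialect has header columns `chrom`, `start`, `end`, `strand`
#' followed by one column per sample (each row a splice junction, each column
#' a run accession). An optional metadata TSV (`sample_id`, `group`) assigns
#' samples to groups; metadata samples missing from the matrix are an error,
#' matrix samples missing from the metadata get group `"ungrouped"`.
#'
#' @param path matrix TSV path.
#' @param metadata_path optional metadata TSV path.
#' @param min_intron minimum intron length (default 20).
#' @return a [JunctionSet].
#' @export
readJunctionMatrix <- function(path, metadata_path = NULL, min_intron = 20L) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character")
    need <- c("chrom", "start", "end", "strand")
    if (!all(need %in% colnames(d)))
        stop("junction matrix header must contain columns: ",
             paste(setdiff(need, colnames(d)), collapse = ", "))
    samp <- setdiff(colnames(d), need)
    cnt <- matrix(0L, nrow(d), length(samp),
                  dimnames = list(NULL, samp))
    for (j in seq_along(samp)) {
        v <- suppressWarnings(as.numeric(d[[samp[j]]]))
        bad <- which(is.na(v) | v != floor(v))
        if (length(bad))
            stop(sprintf(
                "non-integer count in %s at row %d, sample '%s': '%s'",
                path, bad[1], samp[j], d[[samp[j]]][bad[1]]))
        cnt[, j] <- as.integer(v)
    }
    groups <- NULL
    if (!is.null(metadata_path)) {
        md <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                                check.names = FALSE,
                                colClasses = "character")
        if (!all(c("sample_id", "group") %in% colnames(md)))
            stop("metadata must have columns sample_id and group")
        missing <- setdiff(md$sample_id, samp)
        if (length(missing))
            stop("metadata samples absent from the matrix: ",
                 paste(missing, collapse = ", "))
        groups <- stats::setNames(md$group, md$sample_id)
    }
    jdf <- data.frame(chrom = d$chrom,
                      start = as.integer(d$start),
                      end = as.integer(d$end),
                      strand = d$strand, stringsAsFactors = FALSE)
    JunctionSet(jdf, cnt, samp, groups, min_intron)
}

#' Write a JunctionSet as a junction-matrix TSV (and optional metadata TSV)
#'
#' Inverse of [readJunctionMatrix()]: reading the written file reproduces the
#' same junctions, samples and counts.
#'
#' @param js a [JunctionSet].
#' @param path output TSV path.
#' @param metadata_path optional path for a `sample_id`/`group` metadata TSV.
#' @return invisibly, `path`.
#' @export
writeJunctionMatrix <- function(js, path, metadata_path = NULL) {
    gr <- SummarizedExperiment::rowRanges(js)
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE, check.names = FALSE)
    d <- cbind(d, as.data.frame(SummarizedExperiment::assay(js, "counts"),
                                check.names = FALSE))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metadata_path)) {
        grp <- sampleGroups(js)
        utils::write.table(
            data.frame(sample_id = names(grp), group = unname(grp)),
            metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Write a PSI matrix TSV
#'
#' One row per event with its id, type, chromosome, exon interval(s), strand
#' and annotation flag, then one PSI column per sample. Missing cells are
#' written as `NA`; PSI is printed with one decimal on the 0-100 scale.
#'
#' @param psi a [PsiExperiment].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writePsiMatrix <- function(psi, path) {
    rd <- SummarizedExperiment::rowData(psi)
    vals <- SummarizedExperiment::assay(psi, "psi")
    fmt <- matrix(NA_character_, nrow(vals), ncol(vals),
                  dimnames = dimnames(vals))
    ok <- !is.na(vals)
    fmt[ok] <- sprintf("%.1f", vals[ok])
    fmt[!ok] <- "NA"
    d <- data.frame(event_id = rownames(psi),
                    type = rd$eventType,
                    chrom = rd$chrom,
                    exons = rd$exons,
                    strand = rd$strand,
                    annotated = rd$annotated,
                    stringsAsFactors = FALSE, check.names = FALSE)
    d <- cbind(d, as.data.frame(fmt, check.names = FALSE))
    ok <- tryCatch({
        utils::write.table(d, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) stop("cannot write PSI matrix to ", path, ": ",
                                conditionMessage(e)))
    invisible(path)
}

#' Write events as BED6+
#'
#' BED output is 0-based, half-open (converted from the internal 1-based
#' closed intervals). One BED line per event spanning its exon interval(s);
#' name is the event id; score is the rounded mean PSI across samples when a
#' [PsiExperiment] is supplied, else 0.
#'
#' @param events a [SpliceEventSet].
#' @param path output BED path.
#' @param psi optional [PsiExperiment] for the score column.
#' @return invisibly, `path`.
#' @export
writeEventsBed <- function(events, path, psi = NULL) {
    ev <- events@events
    score <- rep(0L, nrow(ev))
    if (!is.null(psi)) {
        m <- SummarizedExperiment::assay(psi, "psi")
        hit <- match(ev$eventId, rownames(m))
        mp <- rowMeans(m[hit, , drop = FALSE], na.rm = TRUE)
        score <- ifelse(is.finite(mp), as.integer(round(mp)), 0L)
    }
    lines <- vapply(seq_len(nrow(ev)), function(i) {
        s <- min(ev$exonStarts[[i]]); e <- max(ev$exonEnds[[i]])
        paste(ev$chrom[i], s - 1L, e, ev$eventId[i], score[i],
              ev$strand[i], sep = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Write the events table TSV
#'
#' Flat description of discovered events: id, type, coordinates, member
#' junctions and annotation flag.
#'
#' @param events a [SpliceEventSet].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeEventsTable <- function(events, path) {
    ev <- events@events
    d <- data.frame(
        event_id = ev$eventId,
        type = ev$eventType,
        chrom = ev$chrom,
        exons = vapply(seq_len(nrow(ev)), function(i)
            paste0(ev$exonStarts[[i]], "-", ev$exonEnds[[i]],
                   collapse = ";"), ""),
        strand = ev$strand,
        inclusion = vapply(ev$inclusion, paste, "", collapse = ","),
        exclusion = vapply(ev$exclusion, function(x)
            if (length(x)) paste(x, collapse = ",") else ".", ""),
        annotated = ev$annotated,
        stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
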