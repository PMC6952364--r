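#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Discovery parameters
#'
#' Tunables for the junction-walking search.
#'
#' @param min_reads a junction participates in discovery if it reaches this
#'   count (default 5) ...
#' @param min_samples ... in at least this many samples (default 1).
#' @param mxe_noise_frac a bridge junction between two candidate mutually
#'   exclusive exons counts as "absent" if its total reads are below this
#'   fraction (default 0.01) of the mean total of the four path junctions.
#' @param max_linked maximum number of exons in a linked-exon chain
#'   (default 3); longer chains are dropped and logged.
#' @return a named list of validated parameters.
#' @export
discoveryParams <- function(min_reads = 5L, min_samples = 1L,
                            mxe_noise_frac = 0.01, max_linked = 3L) {
    .check_flag(min_reads, "min_reads", lo = 0, integer = TRUE)
    .check_flag(min_samples, "min_samples", lo = 1, integer = TRUE)
    .check_flag(mxe_noise_frac, "mxe_noise_frac", lo = 0, hi = 1)
    .check_flag(max_linked, "max_linked", lo = 2, integer = TRUE)
    list(min_reads = as.integer(min_reads),
         min_samples = as.integer(min_samples),
         mxe_noise_frac = mxe_noise_frac,
         max_linked = as.integer(max_linked))
}

#' Build the two-way coordinate index over junctions
#'
#' Groups junctions by shared start coordinate (`by_left`) and by shared end
#' coordinate (`by_right`); closed loops in the splice graph are then found by
#' walking between buckets. Bucket contents are sorted ascending by partner
#' coordinate, so the index is deterministic.
#'
#' @param js a [JunctionSet] (sorted, duplicate-free by construction).
#' @return list with elements `by_left` (named list: `"chrom:start"` ->
#'   integer vector of end coordinates) and `by_right` (`"chrom:end"` ->
#'   start coordinates).
#' @export
buildCoordinateIndex <- function(js) {
    gr <- SummarizedExperiment::rowRanges(js)
    if (!length(gr))
        return(list(by_left = list(), by_right = list()))
    chrom <- as.character(GenomicRanges::seqnames(gr))
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    by_left <- lapply(split(e, paste0(chrom, ":", s)), sort)
    by_right <- lapply(split(s, paste0(chrom, ":", e)), sort)
    list(by_left = by_left, by_right = by_right)
}

# Discovery engine for one chromosome. `s`, `e` are intron first/last bases
# of presence-filtered junctions; `total` their read totals; `strand` their
# declared strands. `fs`, `fe`, `ftotal` describe the full (unfiltered) table,
# consulted only for the MXE bridge-junction noise rule: a bridge too weak to
# pass the presence filter can still veto a mutually exclusive pair if its
# total reads are non-negligible. Returns list(events, diagnostics).
.walk_chrom <- function(chrom, s, e, strand, total, fs, fe, ftotal, params) {
    n <- length(s)
    key <- paste0(s, ":", e)
    idx <- stats::setNames(seq_len(n), key)
    idx_full <- stats::setNames(seq_along(fs), paste0(fs, ":", fe))
    lefts <- split(seq_len(n), s)    # junction rows by start coord
    rights <- split(seq_len(n), e)   # junction rows by end coord
    bridge_total <- function(a, b) {
        i <- idx_full[paste0(a, ":", b)]
        if (is.na(i)) 0 else ftotal[i]
    }
    jtotal <- function(a, b) total[idx[paste0(a, ":", b)]]
    # any junction strictly inside the exon interval [a+1, d-1]?
    inside <- function(a, d) any(s >= a + 1L & e <= d - 1L)

    diag <- list()
    note <- function(reason, detail)
        diag[[length(diag) + 1L]] <<- data.frame(
            reason = reason, chrom = chrom, detail = detail,
            stringsAsFactors = FALSE)

    event_strand <- function(rows) {
        st <- unique(strand[rows])
        st <- st[st %in% c("+", "-")]
        if (length(st) == 1) st else "*"
    }

    # ---- cassette candidates under each exclusion junction ---------------
    # candidate: exclusion E=(S,E_), inclusion (S,a) and (d,E_), exon
    # [a+1, d-1] non-empty with no junction strictly inside.
    cand <- list()
    for (i in seq_len(n)) {
        S <- s[i]; E_ <- e[i]
        la <- lefts[[as.character(S)]]; la <- la[e[la] < E_]
        rd <- rights[[as.character(E_)]]; rd <- rd[s[rd] > S]
        if (!length(la) || !length(rd)) next
        for (ia in la) for (id in rd) {
            a <- e[ia]; d <- s[id]
            if (a > d - 2L) next
            if (inside(a, d)) {
                # internal junctions: linked-chain territory (or nested,
                # non-binary structure; the chain walk decides)
                note("exon_contains_junction",
                     sprintf("%d-%d under %d-%d", a + 1L, d - 1L, S, E_))
                next
            }
            cand[[length(cand) + 1L]] <- list(
                S = S, E = E_, a = a, d = d, rows = c(i, ia, id))
        }
    }

    # ---- linked-exon chains ---------------------------------------------
    events <- list()
    for (i in seq_len(n)) {
        S <- s[i]; E_ <- e[i]
        starts <- lefts[[as.character(S)]]; starts <- starts[e[starts] < E_]
        for (ia in starts) {
            # DFS over internal junctions; exons accumulated between steps
            walk <- function(cur, exon_s, exon_e, rows) {
                if (length(exon_s) > params$max_linked) {
                    note("chain_too_long",
                         sprintf("%d-%d via %d exons", S, E_,
                                 length(exon_s)))
                    return()
                }
                # close the loop at E_
                ends <- rights[[as.character(E_)]]
                ends <- ends[s[ends] >= cur + 2L & s[ends] > S]
                for (id in ends) {
                    d <- s[id]
                    if (inside(cur, d)) next
                    k <- length(exon_s) + 1L
                    if (k >= 2L && k <= params$max_linked)
                        events[[length(events) + 1L]] <<- list(
                            type = "linked", S = S, E = E_,
                            exon_s = c(exon_s, cur + 1L),
                            exon_e = c(exon_e, d - 1L),
                            rows = c(i, rows, id))
                }
                # extend through an internal junction
                mids <- which(s >= cur + 2L & e <= E_ - 2L & s > S)
                for (im in mids) {
                    x <- s[im]
                    if (inside(cur, x)) next
                    walk(e[im], c(exon_s, cur + 1L), c(exon_e, x - 1L),
                         c(rows, im))
                }
            }
            walk(e[ia], integer(0), integer(0), ia)
        }
    }

    # ---- mutually exclusive pairs ---------------------------------------
    mxe_keep <- list()
    flank_s <- sort(unique(s)); flank_e <- sort(unique(e))
    for (S in flank_s) {
        la <- lefts[[as.character(S)]]
        if (length(la) < 2) next
        for (E_ in flank_e) {
            if (E_ <= S) next
            rd <- rights[[as.character(E_)]]
            rd <- rd[s[rd] > S]
            if (length(rd) < 2) next
            avec <- sort(e[la][e[la] < E_]); dvec <- sort(s[rd])
            pairs <- list()
            for (aA in avec) for (aB in avec[avec > aA])
                for (dA in dvec) for (dB in dvec[dvec > dA]) {
                    if (aA > dA - 2L || aB > dB - 2L) next
                    if (dA > aB + 1L) next            # exons must not overlap
                    if (aB < dA) next                 # B starts after A ends
                    if (inside(aA, dA) || inside(aB, dB)) next
                    # bridge junction between the two exons vetoes MXE
                    br <- bridge_total(dA, aB)
                    if (br > 0) {
                        four <- mean(c(jtotal(S, aA), jtotal(dA, E_),
                                       jtotal(S, aB), jtotal(dB, E_)))
                        if (br >= params$mxe_noise_frac * four) {
                            note("mxe_bridge_present",
                                 sprintf("%d-%d / %d-%d", aA + 1L, dA - 1L,
                                         aB + 1L, dB - 1L))
                            next
                        }
                    }
                    pairs[[length(pairs) + 1L]] <- c(aA, dA, aB, dB)
                }
            if (!length(pairs)) next
            exset <- unique(unlist(lapply(pairs, function(p)
                c(paste0(p[1] + 1L, "-", p[2] - 1L),
                  paste0(p[3] + 1L, "-", p[4] - 1L)))))
            if (length(pairs) > 1 || length(exset) > 2) {
                note("mxe_gt2_paths", sprintf("%d-%d: %d paths", S, E_,
                                              length(exset)))
                next
            }
            p <- pairs[[1]]
            rows <- idx[paste0(c(S, p[2], S, p[4]), ":",
                               c(p[1], E_, p[3], E_))]
            events[[length(events) + 1L]] <- list(
                type = "mutually_exclusive", S = S, E = E_,
                exon_s = c(p[1] + 1L, p[3] + 1L),
                exon_e = c(p[2] - 1L, p[4] - 1L),
                rows = unname(rows))
            mxe_keep[[length(mxe_keep) + 1L]] <-
                list(S = S, E = E_, p = p)
        }
    }

    # ---- MXE precedence over the cassette reading -----------------------
    # When the direct flank-to-flank junction exists alongside a mutually
    # exclusive pair, three cassette-shaped loops arise under it: each
    # partner exon alone, and the union path spanning both. All three are
    # readings of the mutually exclusive structure and are suppressed.
    if (length(mxe_keep) && length(cand)) {
        drop <- logical(length(cand))
        for (m in mxe_keep) {
            p <- m$p
            for (k in seq_along(cand)) {
                cc <- cand[[k]]
                if (cc$S != m$S || cc$E != m$E) next
                partner <- (cc$a == p[1] && cc$d == p[2]) ||
                    (cc$a == p[3] && cc$d == p[4])
                spans <- cc$a <= p[1] && cc$d >= p[4]
                if (partner || spans) {
                    drop[k] <- TRUE
                    note(if (partner) "cassette_suppressed_by_mxe"
                         else "cassette_spans_mxe",
                         sprintf("%d-%d", cc$a + 1L, cc$d - 1L))
                }
            }
        }
        cand <- cand[!drop]
    }

    # ---- group cassette candidates sharing a splice site into alt_ss ----
    if (length(cand)) {
        byE <- split(seq_along(cand),
                     vapply(cand, function(x) paste0(x$S, ":", x$E), ""))
        for (grp in byE) {
            m <- length(grp)
            comp <- seq_len(m)           # union-find over shared boundaries
            find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
            for (i in seq_len(m)) for (j in seq_len(m)) {
                if (i >= j) next
                ci <- cand[[grp[i]]]; cj <- cand[[grp[j]]]
                if (ci$a == cj$a || ci$d == cj$d)
                    comp[find(j)] <- find(i)
            }
            roots <- vapply(seq_len(m), find, 1L)
            for (r in unique(roots)) {
                members <- grp[roots == r]
                cc <- cand[members]
                o <- order(vapply(cc, `[[`, 1L, "a"),
                           vapply(cc, `[[`, 1L, "d"))
                cc <- cc[o]
                rows <- unique(unlist(lapply(cc, `[[`, "rows")))
                if (length(cc) == 1L)
                    events[[length(events) + 1L]] <- list(
                        type = "cassette", S = cc[[1]]$S, E = cc[[1]]$E,
                        exon_s = cc[[1]]$a + 1L, exon_e = cc[[1]]$d - 1L,
                        rows = rows)
                else
                    events[[length(events) + 1L]] <- list(
                        type = "alt_ss_group", S = cc[[1]]$S, E = cc[[1]]$E,
                        exon_s = vapply(cc, `[[`, 1L, "a") + 1L,
                        exon_e = vapply(cc, `[[`, 1L, "d") - 1L,
                        rows = rows)
            }
        }
    }

    # ---- assemble rows ---------------------------------------------------
    out <- lapply(events, function(ev) {
        id <- .event_id(ev$type, chrom, ev$S, ev$E, ev$exon_s, ev$exon_e)
        rows <- ev$rows
        if (ev$type == "mutually_exclusive") {
            incl <- .jkey(chrom, s[rows], e[rows])
            excl <- character(0)
        } else {
            excl_row <- rows[s[rows] == ev$S & e[rows] == ev$E]
            incl_rows <- setdiff(rows, excl_row)
            incl <- .jkey(chrom, s[incl_rows], e[incl_rows])
            excl <- .jkey(chrom, ev$S, ev$E)
        }
        list(eventId = id, eventType = ev$type, chrom = chrom,
             strand = event_strand(rows),
             exonStarts = as.integer(ev$exon_s),
             exonEnds = as.integer(ev$exon_e),
             inclusion = incl, exclusion = excl,
             span = c(ev$S, ev$E))
    })
    diag <- if (length(diag)) do.call(rbind, diag) else
        data.frame(reason = character(), chrom = character(),
                   detail = character(), stringsAsFactors = FALSE)
    list(events = out, diagnostics = diag)
}

#' Discover binary splicing events by junction walking
#'
#' Groups the junctions of a [JunctionSet] by shared start or end coordinate
#' and finds pairs of closed loops that share an exclusion condition,
#' classifying each as one of four binary patterns: cassette exon, alternative
#' splice-site exon group, linked exons, or mutually exclusive exon pair. Exon
#' intervals are inferred purely from junction coordinates — the positions
#' between consecutive inclusion junctions — so no transcript annotation is
#' used. Discovery runs on genomic coordinates; strand is carried through for
#' downstream motif orientation only.
#'
#' A junction takes part if it reaches `min_reads` in at least `min_samples`
#' samples. Candidates that entangle with junctions beyond the binary pattern
#' (more than two mutually exclusive paths, chains longer than `max_linked`,
#' a bridge junction joining two putative mutually exclusive exons) are
#' dropped and logged in `diagnostics()`. When an exon qualifies both as a
#' lone cassette and as a mutually exclusive partner, the mutually exclusive
#' reading wins and the cassette reading is logged.
#'
#' @param js a [JunctionSet].
#' @param params a list from [discoveryParams()].
#' @return a [SpliceEventSet], sorted by genomic position, annotation flag
#'   `"unknown"` throughout (see [annotateEvents()]).
#' @export
discoverEvents <- function(js, params = discoveryParams()) {
    cnt <- SummarizedExperiment::assay(js, "counts")
    pass <- rowSums(cnt >= params$min_reads) >= params$min_samples
    gr_all <- SummarizedExperiment::rowRanges(js)
    total_all <- rowSums(cnt)
    gr <- gr_all[pass]
    total <- total_all[pass]
    chrom <- as.character(GenomicRanges::seqnames(gr))
    chrom_all <- as.character(GenomicRanges::seqnames(gr_all))
    rows <- list(); diags <- list()
    for (ch in sort(unique(chrom))) {
        sel <- chrom == ch
        sel_all <- chrom_all == ch
        res <- .walk_chrom(ch, GenomicRanges::start(gr)[sel],
                           GenomicRanges::end(gr)[sel],
                           as.character(GenomicRanges::strand(gr))[sel],
                           unname(total[sel]),
                           GenomicRanges::start(gr_all)[sel_all],
                           GenomicRanges::end(gr_all)[sel_all],
                           unname(total_all[sel_all]), params)
        rows <- c(rows, res$events)
        diags[[length(diags) + 1L]] <- res$diagnostics
    }
    .as_event_set(rows, diags)
}

.as_event_set <- function(rows, diags) {
    diag <- if (length(diags)) do.call(rbind, diags) else
        data.frame(reason = character(), chrom = character(),
                   detail = character(), stringsAsFactors = FALSE)
    if (!length(rows)) {
        ev <- S4Vectors::DataFrame(
            eventId = character(), eventType = character(),
            chrom = character(), strand = character(),
            annotated = character(),
            exonStarts = IRanges::IntegerList(),
            exonEnds = IRanges::IntegerList(),
            inclusion = IRanges::CharacterList(),
            exclusion = IRanges::CharacterList())
        return(methods::new("SpliceEventSet", events = ev,
                            diagnostics = S4Vectors::DataFrame(diag)))
    }
    ids <- vapply(rows, `[[`, "", "eventId")
    keep <- !duplicated(ids)
    rows <- rows[keep]; ids <- ids[keep]
    o <- order(vapply(rows, `[[`, "", "chrom"),
               vapply(rows, function(r) r$span[1], 1L),
               vapply(rows, function(r) r$span[2], 1L), ids)
    rows <- rows[o]
    ev <- S4Vectors::DataFrame(
        eventId = vapply(rows, `[[`, "", "eventId"),
        eventType = vapply(rows, `[[`, "", "eventType"),
        chrom = vapply(rows, `[[`, "", "chrom"),
        strand = vapply(rows, `[[`, "", "strand"),
        annotated = rep("unknown", length(rows)),
        exonStarts = IRanges::IntegerList(lapply(rows, `[[`, "exonStarts")),
        exonEnds = IRanges::IntegerList(lapply(rows, `[[`, "exonEnds")),
        inclusion = IRanges::CharacterList(lapply(rows, `[[`, "inclusion")),
        exclusion = IRanges::CharacterList(lapply(rows, `[[`, "exclusion")))
    methods::new("SpliceEventSet", events = ev,
                 diagnostics = S4Vectors::DataFrame(diag))
}

#' Flag event exons as annotated or unannotated against a GTF
#'
#' An event exon is "annotated" only when an annotation exon with exactly the
#' same chromosome, start and end exists; any boundary mismatch makes it
#' unannotated. Multi-exon events (alternative splice-site groups, linked
#' chains, mutually exclusive pairs) are annotated only if every member
#' interval matches. With no annotation supplied the flag stays `"unknown"`.
#'
#' @param events a [SpliceEventSet].
#' @param annotation a GTF file path or a `GRanges` of exon features
#'   (1-based, closed coordinates); `NULL` leaves flags unknown.
#' @return the [SpliceEventSet] with the `annotated` flag filled in.
#' @export
annotateEvents <- function(events, annotation = NULL) {
    ev <- events@events
    if (is.null(annotation)) {
        ev$annotated <- rep("unknown", nrow(ev))
        return(initialize(events, events = ev))
    }
    exons <- if (is.character(annotation)) readGtfExons(annotation)
             else annotation
    akey <- paste0(as.character(GenomicRanges::seqnames(exons)), ":",
                   GenomicRanges::start(exons), "-",
                   GenomicRanges::end(exons))
    flag <- vapply(seq_len(nrow(ev)), function(i) {
        ks <- paste0(ev$chrom[i], ":", ev$exonStarts[[i]], "-",
                     ev$exonEnds[[i]])
        if (all(ks %in% akey)) "annotated" else "unannotated"
    }, "")
    ev$annotated <- flag
    initialize(events, events = ev)
}

#' Read exon features from a GTF file
#'
#' Thin wrapper over [rtracklayer::import()] restricted to `exon` rows, with
#' an up-front structural check so a malformed line is reported by number.
#'
#' @param path GTF path (Ensembl/GENCODE dialect, 1-based closed).
#' @param protein_coding_only keep only exons whose gene is protein coding
#'   (`gene_biotype` or `gene_type` attribute).
#' @return `GRanges` of exon intervals.
#' @export
readGtfExons <- function(path, protein_coding_only = FALSE) {
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
    if (any(nf != 9))
        stop(sprintf("unparseable GTF %s: line %d has %d fields (9 expected)",
                     path, which(body)[nf != 9][1], nf[nf != 9][1]))
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (protein_coding_only) {
        bt <- if ("gene_biotype" %in% colnames(S4Vectors::mcols(gr)))
            gr$gene_biotype
        else if ("gene_type" %in% colnames(S4Vectors::mcols(gr)))
            gr$gene_type
        else stop("GTF has no gene_biotype/gene_type attribute")
        gr <- gr[!is.na(bt) & bt == "protein_coding"]
    }
    gr
}
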