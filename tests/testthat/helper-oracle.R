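# Brute-force event oracle.
#
# Enumerates binary splicing events for a synthetic locus directly from its
# transcript structures: the junction set is derived from consecutive exon
# pairs within each transcript, and events are found by exhaustively checking
# every exon triple/quadruple of the locus against the event definitions
# (cassette, alternative splice-site group, linked chain, mutually exclusive
# pair, with the stated precedence and non-binary exclusion rules). This is
# O(n^4) in the number of exons and shares no code with the coordinate-index
# junction walk it is used to validate.

oracle_locus_events <- function(loc, max_linked = 3L) {
    ex <- loc$exons
    n <- nrow(ex)
    adj <- unique(do.call(rbind, lapply(loc$transcripts, function(tr)
        if (length(tr) < 2) NULL else cbind(tr[-length(tr)], tr[-1]))))
    js <- ex$end[adj[, 1]] + 1L
    je <- ex$start[adj[, 2]] - 1L
    jk <- paste(js, je)
    has_j <- function(i, j) paste(ex$end[i] + 1L, ex$start[j] - 1L) %in% jk
    inside_free <- function(i)
        !any(js >= ex$start[i] & je <= ex$end[i])
    gap <- function(i, j) ex$start[j] - ex$end[i] >= 2L  # intron >= 1 base
    id_of <- function(type, S, E, ss, ee)
        paste0(type, "|", loc$chrom, "|", S, "-", E, "|",
               paste0(ss, "-", ee, collapse = ";"))

    # cassette-shaped triples (flank1, exon, flank2)
    triples <- list()
    for (f1 in seq_len(n)) for (c in seq_len(n)) for (f2 in seq_len(n)) {
        if (length(unique(c(f1, c, f2))) < 3) next
        if (!gap(f1, c) || !gap(c, f2)) next
        if (!has_j(f1, c) || !has_j(c, f2) || !has_j(f1, f2)) next
        if (!inside_free(c)) next
        triples[[length(triples) + 1L]] <- c(f1, c, f2)
    }

    # mutually exclusive quadruples (flank1, a, b, flank2)
    mxe <- list()
    cand_q <- list()
    for (f1 in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n))
        for (f2 in seq_len(n)) {
            if (length(unique(c(f1, a, b, f2))) < 4) next
            if (!gap(f1, a) || !gap(a, b) || !gap(b, f2)) next
            if (!has_j(f1, a) || !has_j(a, f2)) next
            if (!has_j(f1, b) || !has_j(b, f2)) next
            if (has_j(a, b)) next                 # bridge vetoes the pair
            if (!inside_free(a) || !inside_free(b)) next
            cand_q[[length(cand_q) + 1L]] <- c(f1, a, b, f2)
        }
    if (length(cand_q)) {
        flank_key <- vapply(cand_q, function(q)
            paste(ex$end[q[1]] + 1L, ex$start[q[4]] - 1L), "")
        for (fk in unique(flank_key)) {
            qs <- cand_q[flank_key == fk]
            exons_involved <- unique(unlist(lapply(qs, function(q)
                paste(ex$start[q[2:3]], ex$end[q[2:3]]))))
            if (length(qs) == 1 && length(exons_involved) == 2)
                mxe[[length(mxe) + 1L]] <- qs[[1]]
        }
    }

    # MXE precedence: drop cassette triples under the same flanks whose exon
    # is a partner exon or spans both partners
    if (length(mxe) && length(triples)) {
        keep <- vapply(triples, function(tr) {
            for (q in mxe) {
                if (ex$end[tr[1]] != ex$end[q[1]] ||
                    ex$start[tr[3]] != ex$start[q[4]]) next
                c_int <- c(ex$start[tr[2]], ex$end[tr[2]])
                a_int <- c(ex$start[q[2]], ex$end[q[2]])
                b_int <- c(ex$start[q[3]], ex$end[q[3]])
                if (identical(c_int, a_int) || identical(c_int, b_int))
                    return(FALSE)
                if (c_int[1] <= a_int[1] && c_int[2] >= b_int[2])
                    return(FALSE)
            }
            TRUE
        }, TRUE)
        triples <- triples[keep]
    }

    ids <- character(0)
    for (q in mxe)
        ids <- c(ids, id_of("mutually_exclusive",
                            ex$end[q[1]] + 1L, ex$start[q[4]] - 1L,
                            ex$start[q[2:3]], ex$end[q[2:3]]))

    # group cassette triples by exclusion junction; merge variants sharing
    # one splice site into alternative splice-site groups
    if (length(triples)) {
        ekey <- vapply(triples, function(tr)
            paste(ex$end[tr[1]] + 1L, ex$start[tr[3]] - 1L), "")
        for (ek in unique(ekey)) {
            trs <- triples[ekey == ek]
            m <- length(trs)
            comp <- seq_len(m)
            find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
            if (m > 1)
                for (i in 1:(m - 1)) for (j in (i + 1):m) {
                    ci <- trs[[i]][2]; cj <- trs[[j]][2]
                    if (ex$start[ci] == ex$start[cj] ||
                        ex$end[ci] == ex$end[cj])
                        comp[find(j)] <- find(i)
                }
            roots <- vapply(seq_len(m), find, 1L)
            S <- ex$end[trs[[1]][1]] + 1L
            E <- ex$start[trs[[1]][3]] - 1L
            for (r in unique(roots)) {
                cs <- vapply(trs[roots == r], `[`, 1L, 2L)
                o <- order(ex$start[cs], ex$end[cs])
                cs <- cs[o]
                type <- if (length(cs) > 1) "alt_ss_group" else "cassette"
                ids <- c(ids, id_of(type, S, E, ex$start[cs], ex$end[cs]))
            }
        }
    }

    # linked chains (flank1, c1..ck, flank2), 2 <= k <= max_linked
    for (f1 in seq_len(n)) for (f2 in seq_len(n)) {
        if (f1 == f2 || !gap(f1, f2) || !has_j(f1, f2)) next
        mids <- setdiff(which(ex$start > ex$end[f1] &
                                  ex$end < ex$start[f2]), c(f1, f2))
        if (length(mids) < 2) next
        for (k in 2:min(max_linked, length(mids))) {
            combs <- utils::combn(mids, k, simplify = FALSE)
            for (cb in combs) {
                chain <- cb[order(ex$start[cb])]
                nodes <- c(f1, chain, f2)
                ok <- all(vapply(seq_len(length(nodes) - 1L), function(i)
                    gap(nodes[i], nodes[i + 1L]) &&
                        has_j(nodes[i], nodes[i + 1L]), TRUE)) &&
                    all(vapply(chain, inside_free, TRUE))
                if (ok)
                    ids <- c(ids, id_of("linked",
                                        ex$end[f1] + 1L,
                                        ex$start[f2] - 1L,
                                        ex$start[chain], ex$end[chain]))
            }
        }
    }
    sort(unique(ids))
}

oracle_truth_events <- function(truth, max_linked = 3L)
    sort(unique(unlist(lapply(truth@loci, oracle_locus_events,
                              max_linked = max_linked))))
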