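#' @include AllClasses.R AllGenerics.R utils.R event-discovery.R
NULL

# ---------------------------------------------------------------------------
# Locus construction. A locus is one alternative-splicing unit: constitutive
# flanking exons around 0-2 alternative exon paths, with the junction
# structure both the simulator and the implied event list are derived from.
# Coordinates are 1-based closed; junction (s, e) spans the first and last
# intronic base.
# ---------------------------------------------------------------------------

#' Build one synthetic locus
#'
#' Lays out flanking exons and alternative exon(s) for one binary event type
#' on a chromosome, from explicit geometry. All introns must be at least 20
#' bases so simulated junctions survive default input filtering.
#'
#' @param chrom chromosome name.
#' @param type one of `cassette`, `alt_ss_group`, `linked`,
#'   `mutually_exclusive`, or `none` (constitutive exons only).
#' @param origin genomic start of the first flanking exon.
#' @param strand `+` or `-`.
#' @param flank_len length of each flanking exon.
#' @param exon_lens lengths of the alternative exons (one per cassette;
#'   one per variant for `alt_ss_group` — variants share their downstream
#'   boundary; one per chained exon for `linked`; two for
#'   `mutually_exclusive`).
#' @param intron_lens intron lengths between consecutive exons on the
#'   inclusion path (`length(exon_lens) + 1` values). For `alt_ss_group`
#'   the first value is the intron before the *longest* variant.
#' @param n_extra_flanks constitutive exons appended upstream (each adds a
#'   constitutive junction).
#' @param mxe_skip for `mutually_exclusive`: also emit the direct
#'   flank-to-flank skip junction (the cassette reading it licenses is
#'   suppressed by the mutually-exclusive precedence rule).
#' @param mxe_bridge for `mutually_exclusive`: emit a bridge junction joining
#'   the two exons (a transcript containing both); this vetoes the event, so
#'   the locus contributes no true event.
#' @return a locus description list (used by [syntheticTruth()]).
#' @export
syntheticLocus <- function(chrom, type = "cassette", origin = 1000L,
                           strand = "+", flank_len = 120L,
                           exon_lens = 80L, intron_lens = NULL,
                           n_extra_flanks = 0L, mxe_skip = FALSE,
                           mxe_bridge = FALSE) {
    origin <- as.integer(origin)
    exon_lens <- as.integer(exon_lens)
    if (is.null(intron_lens))
        intron_lens <- rep(300L, length(exon_lens) + 1L)
    intron_lens <- as.integer(intron_lens)
    if (any(intron_lens < 20L)) stop("introns must be >= 20 bases")
    if (any(exon_lens < 2L)) stop("alternative exons must be >= 2 bases")
    if (!type %in% c(.EVENT_TYPES, "none")) stop("unknown locus type")

    exons <- data.frame(start = integer(), end = integer(),
                        label = character(), stringsAsFactors = FALSE)
    add_exon <- function(start, len, label) {
        exons[nrow(exons) + 1L, ] <<- list(as.integer(start),
                                           as.integer(start + len - 1L),
                                           label)
        as.integer(start + len - 1L)
    }
    jn <- function(from_end, to_start) c(from_end + 1L, to_start - 1L)

    cur <- origin
    const_j <- list()
    for (k in seq_len(n_extra_flanks)) {
        fe <- add_exon(cur, flank_len, paste0("extra_flank", k))
        const_j[[length(const_j) + 1L]] <- jn(fe, fe + 101L)
        cur <- fe + 101L
    }
    f1_end <- add_exon(cur, flank_len, "flankL")

    incl <- list(); excl <- NULL; events <- list()
    alt_idx <- integer(0)

    if (type == "none") {
        f2s <- f1_end + intron_lens[1] + 1L
        add_exon(f2s, flank_len, "flankR")
        const_j[[length(const_j) + 1L]] <- jn(f1_end, f2s)
    } else if (type %in% c("cassette", "linked")) {
        k <- length(exon_lens)
        if (type == "cassette" && k != 1L)
            stop("cassette takes exactly one exon length")
        if (type == "linked" && k < 2L)
            stop("linked takes >= 2 exon lengths")
        cur <- f1_end
        path <- list(); exon_s <- integer(0); exon_e <- integer(0)
        prev_end <- f1_end
        for (i in seq_len(k)) {
            es <- prev_end + intron_lens[i] + 1L
            ee <- add_exon(es, exon_lens[i], paste0("alt", i))
            alt_idx <- c(alt_idx, nrow(exons))
            path[[length(path) + 1L]] <- jn(prev_end, es)
            exon_s <- c(exon_s, es); exon_e <- c(exon_e, ee)
            prev_end <- ee
        }
        f2s <- prev_end + intron_lens[k + 1L] + 1L
        add_exon(f2s, flank_len, "flankR")
        path[[length(path) + 1L]] <- jn(prev_end, f2s)
        S <- f1_end + 1L; E <- f2s - 1L
        incl <- list(list(junctions = do.call(rbind, path), frac = 1))
        excl <- rbind(c(S, E))
        events <- list(list(type = type, S = S, E = E,
                            exon_s = exon_s, exon_e = exon_e,
                            incl_j = do.call(rbind, path),
                            excl_j = rbind(c(S, E))))
    } else if (type == "alt_ss_group") {
        m <- length(exon_lens)
        if (m < 2L) stop("alt_ss_group takes >= 2 variant lengths")
        exon_lens <- sort(exon_lens, decreasing = TRUE)
        if (anyDuplicated(exon_lens))
            stop("alt_ss_group variant lengths must be distinct")
        # variants share the downstream boundary; starts differ
        vstart_long <- f1_end + intron_lens[1] + 1L
        vend <- vstart_long + exon_lens[1] - 1L
        f2s <- vend + intron_lens[2] + 1L
        vstarts <- vend - exon_lens + 1L
        for (i in seq_len(m)) {
            add_exon(vstarts[i], exon_lens[i], paste0("variant", i))
            alt_idx <- c(alt_idx, nrow(exons))
        }
        add_exon(f2s, flank_len, "flankR")
        S <- f1_end + 1L; E <- f2s - 1L
        shared <- c(vend + 1L, f2s - 1L)
        incl <- c(
            lapply(vstarts, function(vs)
                list(junctions = rbind(jn(f1_end, vs)), frac = 1 / m)),
            list(list(junctions = rbind(shared), frac = 1)))
        excl <- rbind(c(S, E))
        o <- order(vstarts)
        events <- list(list(
            type = "alt_ss_group", S = S, E = E,
            exon_s = vstarts[o], exon_e = rep(vend, m),
            incl_j = rbind(do.call(rbind, lapply(sort(vstarts),
                                                 function(vs)
                                                     jn(f1_end, vs))),
                           shared),
            excl_j = rbind(c(S, E))))
    } else {  # mutually_exclusive
        if (length(exon_lens) != 2L)
            stop("mutually_exclusive takes exactly two exon lengths")
        if (length(intron_lens) < 3L)
            intron_lens <- c(intron_lens, 300L)[1:3]
        as_ <- f1_end + intron_lens[1] + 1L
        ae <- add_exon(as_, exon_lens[1], "altA"); alt_idx <- c(alt_idx, nrow(exons))
        bs <- ae + intron_lens[2] + 1L
        be <- add_exon(bs, exon_lens[2], "altB"); alt_idx <- c(alt_idx, nrow(exons))
        f2s <- be + intron_lens[3] + 1L
        add_exon(f2s, flank_len, "flankR")
        S <- f1_end + 1L; E <- f2s - 1L
        pathA <- rbind(jn(f1_end, as_), jn(ae, f2s))
        pathB <- rbind(jn(f1_end, bs), jn(be, f2s))
        incl <- list(list(junctions = pathA, frac = 1))
        excl <- pathB
        # a bridged pair represents transcripts including both exons (the
        # third transcript is flank-A-B-flank, not flank-flank), so the
        # skip junction cannot coexist in that reading
        if (mxe_bridge) mxe_skip <- FALSE
        if (mxe_skip)
            const_j[[length(const_j) + 1L]] <- c(S, E)
        if (mxe_bridge) {
            bridge <- jn(ae, bs)
            const_j[[length(const_j) + 1L]] <- bridge
            # with the bridge, the pair is not mutually exclusive: each
            # exon is instead a cassette against the other path's junction
            events <- list(
                list(type = "cassette", S = S, E = bs - 1L,
                     exon_s = as_, exon_e = ae,
                     incl_j = rbind(jn(f1_end, as_), bridge),
                     excl_j = rbind(jn(f1_end, bs))),
                list(type = "cassette", S = ae + 1L, E = E,
                     exon_s = bs, exon_e = be,
                     incl_j = rbind(bridge, jn(be, f2s)),
                     excl_j = rbind(jn(ae, f2s))))
        } else {
            events <- list(list(
                type = "mutually_exclusive", S = S, E = E,
                exon_s = c(as_, bs), exon_e = c(ae, be),
                incl_j = rbind(pathA, pathB),
                excl_j = matrix(integer(0), 0, 2)))
        }
    }
    # transcript exon chains (row indices into exons), the generative truth
    # the junction table is implied by
    pre <- which(grepl("^extra_flank", exons$label) |
                     exons$label == "flankL")
    last <- which(exons$label == "flankR")
    transcripts <- if (type == "none") {
        list(c(pre, last))
    } else if (type %in% c("cassette", "linked")) {
        list(c(pre, alt_idx, last), c(pre, last))
    } else if (type == "alt_ss_group") {
        c(lapply(alt_idx, function(v) c(pre, v, last)),
          list(c(pre, last)))
    } else {
        tr <- list(c(pre, alt_idx[1], last), c(pre, alt_idx[2], last))
        if (mxe_skip) tr <- c(tr, list(c(pre, last)))
        if (mxe_bridge) tr <- c(tr, list(c(pre, alt_idx, last)))
        tr
    }
    list(chrom = chrom, strand = strand, type = type, exons = exons,
         alt_exon_idx = alt_idx, transcripts = transcripts,
         incl = incl, excl = excl, const_j = const_j, events = events)
}

#' Assemble a synthetic ground truth
#'
#' @param loci list of loci from [syntheticLocus()] (chromosome names should
#'   be distinct per locus to keep loci independent).
#' @param true_psi numeric matrix (loci x groups) of inclusion rates in
#'   \[0, 1\]; for mutually exclusive pairs, the rate of the upstream exon.
#'   Column names are the group labels.
#' @param groups named integer vector: samples per group (names must match
#'   `colnames(true_psi)`).
#' @param depth expected informative reads per event per sample (default 200).
#' @param dispersion negative-binomial overdispersion; 0 gives Poisson depth
#'   (default 0.2).
#' @param noise_rate expected number of spurious junctions per locus
#'   (default 0).
#' @param seed integer master seed.
#' @return a [SyntheticTruth].
#' @export
syntheticTruth <- function(loci, true_psi, groups, depth = 200,
                           dispersion = 0.2, noise_rate = 0, seed = 1L) {
    true_psi <- as.matrix(true_psi)
    if (is.null(colnames(true_psi)))
        colnames(true_psi) <- names(groups)
    if (!identical(sort(colnames(true_psi)), sort(names(groups))))
        stop("true_psi columns must match group names")
    methods::new("SyntheticTruth", loci = loci, truePsi = true_psi,
                 depth = depth, dispersion = dispersion,
                 groups = stats::setNames(as.integer(groups), names(groups)),
                 noiseRate = noise_rate, seed = as.integer(seed))
}

# All structural junctions of a locus: inclusion paths, exclusion loop,
# constitutive. Returns a matrix (s, e) with a role column index.
.locus_junctions <- function(loc) {
    rows <- list()
    for (p in loc$incl)
        for (r in seq_len(nrow(p$junctions)))
            rows[[length(rows) + 1L]] <-
                c(p$junctions[r, ], 1, p$frac)
    if (!is.null(loc$excl))
        for (r in seq_len(nrow(loc$excl)))
            rows[[length(rows) + 1L]] <- c(loc$excl[r, ], 2, 1)
    for (cj in loc$const_j)
        rows[[length(rows) + 1L]] <- c(cj, 3, 1)
    m <- do.call(rbind, rows)
    colnames(m) <- c("s", "e", "role", "frac")
    m[!duplicated(m[, c("s", "e"), drop = FALSE]), , drop = FALSE]
}

.truth_event_rows <- function(truth) {
    rows <- list()
    for (loc in truth@loci) {
        for (ev in loc$events) {
            incl_m <- ev$incl_j[!duplicated(ev$incl_j), , drop = FALSE]
            rows[[length(rows) + 1L]] <- list(
                eventId = .event_id(ev$type, loc$chrom, ev$S, ev$E,
                                    ev$exon_s, ev$exon_e),
                eventType = ev$type, chrom = loc$chrom,
                strand = loc$strand,
                exonStarts = as.integer(ev$exon_s),
                exonEnds = as.integer(ev$exon_e),
                inclusion = .jkey(loc$chrom, incl_m[, 1], incl_m[, 2]),
                exclusion = if (nrow(ev$excl_j))
                    .jkey(loc$chrom, ev$excl_j[, 1], ev$excl_j[, 2])
                else character(0),
                span = c(ev$S, ev$E))
        }
    }
    rows
}

#' The event list implied by a synthetic truth
#'
#' @param truth a [SyntheticTruth].
#' @return a [SpliceEventSet] of the planted events (loci whose structure
#'   vetoes an event, e.g. a bridged mutually exclusive pair, contribute
#'   none).
#' @export
impliedEvents <- function(truth) .as_event_set(.truth_event_rows(truth), list())

#' Deterministic junction table implied by a synthetic truth
#'
#' Every structural junction of every locus with a constant count
#' (default 50) in every sample — the noiseless limit used to check that
#' discovery inverts the construction exactly.
#'
#' @param truth a [SyntheticTruth].
#' @param count constant per-cell count (default 50).
#' @return a [JunctionSet].
#' @export
impliedJunctions <- function(truth, count = 50L) {
    sample_ids <- .truth_samples(truth)$sample_id
    rows <- list()
    for (loc in truth@loci) {
        jm <- .locus_junctions(loc)
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = loc$chrom, start = jm[, "s"], end = jm[, "e"],
            strand = loc$strand, stringsAsFactors = FALSE)
    }
    jdf <- do.call(rbind, rows)
    cnt <- matrix(as.integer(count), nrow(jdf), length(sample_ids))
    JunctionSet(jdf, cnt, sample_ids,
                groups = stats::setNames(.truth_samples(truth)$group,
                                         sample_ids))
}

.truth_samples <- function(truth) {
    g <- truth@groups
    data.frame(
        sample_id = unlist(lapply(names(g), function(nm)
            paste0(nm, "_", seq_len(g[[nm]])))),
        group = rep(names(g), g), stringsAsFactors = FALSE)
}

#' Simulate a junction-count table from a synthetic truth
#'
#' Per locus and sample, the informative read total n is drawn from a
#' negative binomial with mean `depth` and the stated overdispersion
#' (Poisson when `dispersion = 0`). Each junction on the inclusion side then
#' receives an independent Binomial(n, psi * frac) count, where `frac` is the
#' fraction of inclusion molecules crossing that junction (1 except for
#' variant-specific junctions of an alternative splice-site group); each
#' exclusion-side junction receives Binomial(n, 1 - psi). Constitutive
#' junctions draw Poisson(depth) counts. Optional noise junctions appear at
#' `noise_rate` expected per locus, placed at least 20 bases from any true
#' splice site, with Poisson(1) counts per sample. Fully reproducible from
#' the truth's seed.
#'
#' @param truth a [SyntheticTruth].
#' @return list with `junctions` (a [JunctionSet]), `events` (the implied
#'   [SpliceEventSet]) and `samples` (sample metadata data.frame).
#' @export
simulateJunctions <- function(truth) {
    set.seed(truth@seed)
    smp <- .truth_samples(truth)
    ns <- nrow(smp)
    draw_n <- function(k) {
        if (truth@dispersion == 0) stats::rpois(k, truth@depth)
        else stats::rnbinom(k, mu = truth@depth,
                            size = 1 / truth@dispersion)
    }
    jrows <- list(); crows <- list()
    for (li in seq_along(truth@loci)) {
        loc <- truth@loci[[li]]
        psi <- truth@truePsi[li, smp$group]
        n <- draw_n(ns)
        jm <- .locus_junctions(loc)
        cnt <- matrix(0L, nrow(jm), ns)
        for (r in seq_len(nrow(jm))) {
            role <- jm[r, "role"]; frac <- jm[r, "frac"]
            cnt[r, ] <- if (role == 1)
                stats::rbinom(ns, n, pmin(1, psi * frac))
            else if (role == 2)
                stats::rbinom(ns, n, pmin(1, (1 - psi) * frac))
            else
                stats::rpois(ns, truth@depth)
        }
        jdf <- data.frame(chrom = loc$chrom, start = jm[, "s"],
                          end = jm[, "e"], strand = loc$strand,
                          stringsAsFactors = FALSE)
        if (truth@noiseRate > 0) {
            k <- stats::rpois(1, truth@noiseRate)
            if (k > 0) {
                ss_coords <- sort(unique(c(jm[, "s"], jm[, "e"])))
                lo <- min(ss_coords) - 500L; hi <- max(ss_coords) + 500L
                made <- 0L; guard <- 0L
                while (made < k && guard < 200L) {
                    guard <- guard + 1L
                    a <- sample(lo:hi, 1)
                    b <- a + sample(40:400, 1)
                    # keep noise splice sites >= 20 bases from true ones
                    if (min(abs(c(a, b) - rep(ss_coords, each = 2))) < 20L)
                        next
                    jdf[nrow(jdf) + 1L, ] <- list(loc$chrom, a, b, "*")
                    cnt <- rbind(cnt, stats::rpois(ns, 1))
                    made <- made + 1L
                }
            }
        }
        jrows[[length(jrows) + 1L]] <- jdf
        crows[[length(crows) + 1L]] <- cnt
    }
    jdf <- do.call(rbind, jrows)
    cnt <- do.call(rbind, crows)
    js <- JunctionSet(jdf, cnt, smp$sample_id,
                      groups = stats::setNames(smp$group, smp$sample_id))
    list(junctions = js, events = impliedEvents(truth), samples = smp)
}

# ---------------------------------------------------------------------------
# Genome + annotation synthesis
# ---------------------------------------------------------------------------

# Genomic coordinates, in transcript order, of a splice-site window.
.window_gcoords <- function(b, t, strand, anchor, side, intronic_flank,
                            exonic_flank) {
    half <- min(exonic_flank, (t - b + 1L) %/% 2L)
    if (strand == "+") {
        if (anchor == "5prime_ss") {
            if (side == "intronic") (t + 1L):(t + intronic_flank)
            else if (half > 0) (t - half + 1L):t else integer(0)
        } else {
            if (side == "intronic") (b - intronic_flank):(b - 1L)
            else if (half > 0) b:(b + half - 1L) else integer(0)
        }
    } else {
        if (anchor == "5prime_ss") {
            if (side == "intronic") (b - 1L):(b - intronic_flank)
            else if (half > 0) (b + half - 1L):b else integer(0)
        } else {
            if (side == "intronic") (t + intronic_flank):(t + 1L)
            else if (half > 0) t:(t - half + 1L) else integer(0)
        }
    }
}

#' Simulate a genome FASTA and GTF matching a synthetic truth
#'
#' Builds one i.i.d.-uniform random chromosome per locus, writes canonical
#' splice dinucleotides (GT..AG in transcript orientation) at every
#' structural junction, optionally plants motif copies at stated positions
#' inside splice-site windows, and removes any accidental motif occurrence
#' elsewhere by resampling bases (so planted copies are the only ones; the
#' motif and its reverse complement are both scrubbed). The GTF contains all
#' constitutive/flanking exons as `protein_coding` exon features; event exons
#' are included except for loci listed in `withhold_exons`, which lets the
#' annotated/unannotated flag be exercised against a known truth.
#'
#' @param truth a [SyntheticTruth].
#' @param plants optional list of motif plants, each a list with `locus`
#'   (index), `exon` (alternative-exon index within the locus, default 1),
#'   `anchor` (`"5prime_ss"`/`"3prime_ss"`), `from`, `to` (signed positions;
#'   intronic negative), `copies`. Copies are placed at distinct
#'   non-overlapping positions drawn between `from` and `to`; a plant
#'   colliding with a splice dinucleotide is an error.
#' @param motif motif to plant/scrub (default `"TAG"`).
#' @param withhold_exons integer locus indices whose event exons are left out
#'   of the GTF.
#' @param scrub remove accidental motif occurrences from the background
#'   (default TRUE); with `scrub = FALSE` the background keeps its chance-rate
#'   occurrences, which is what a baseline exon set should be profiled on.
#' @param intronic_flank,exonic_flank window extents for position mapping.
#' @return list with `genome` (named `DNAStringSet`), `annotation`
#'   (`GRanges` of exon features with `type` and `gene_biotype` set) and
#'   `plants` (data.frame of realized plant positions).
#' @export
simulateGenome <- function(truth, plants = list(), motif = "TAG",
                           withhold_exons = integer(0), scrub = TRUE,
                           intronic_flank = 1000L, exonic_flank = 50L) {
    motif <- .normalize_motif(motif)
    mlen <- nchar(motif)
    set.seed(.derive_seed(truth@seed, 17L))
    rcmotif <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    chrs <- list(); protected <- list(); planted_df <- list()
    ann <- list()
    for (li in seq_along(truth@loci)) {
        loc <- truth@loci[[li]]
        jm <- .locus_junctions(loc)
        chrlen <- max(loc$exons$end, jm[, "e"]) + intronic_flank + 100L
        seqv <- sample(c("A", "C", "G", "T"), chrlen, replace = TRUE)
        prot <- integer(0)
        # canonical splice dinucleotides in transcript orientation
        for (r in seq_len(nrow(jm))) {
            s <- jm[r, "s"]; e <- jm[r, "e"]
            if (loc$strand == "+") {
                seqv[s] <- "G"; seqv[s + 1L] <- "T"
                seqv[e - 1L] <- "A"; seqv[e] <- "G"
            } else {
                seqv[s] <- "C"; seqv[s + 1L] <- "T"
                seqv[e - 1L] <- "A"; seqv[e] <- "C"
            }
            prot <- c(prot, s, s + 1L, e - 1L, e)
        }
        # plant requested motif copies
        for (p in plants) {
            if (p$locus != li) next
            exon <- if (is.null(p$exon)) 1L else p$exon
            ei <- loc$alt_exon_idx[exon]
            if (is.na(ei)) stop("plant names a missing alternative exon")
            b <- loc$exons$start[ei]; t <- loc$exons$end[ei]
            side <- if (p$from < 0) "intronic" else "exonic"
            gco <- .window_gcoords(b, t, loc$strand, p$anchor, side,
                                   intronic_flank, exonic_flank)
            pos <- .window_positions(side, xor(side == "intronic",
                                               p$anchor == "3prime_ss"),
                                     length(gco))
            # candidate first-base positions, keeping copies non-overlapping
            cand <- p$from:p$to
            chosen <- integer(0)
            for (rep_i in seq_len(p$copies)) {
                ok <- cand[vapply(cand, function(x)
                    all(abs(x - chosen) >= mlen), TRUE)]
                if (!length(ok)) stop("plant window too small for copies")
                chosen <- c(chosen, sample(ok, 1))
            }
            for (x in sort(chosen)) {
                j0 <- which(pos == x)
                if (!length(j0) || j0 + mlen - 1L > length(gco))
                    stop("plant offset outside the window")
                gc <- gco[j0:(j0 + mlen - 1L)]
                if (any(gc %in% prot))
                    stop("motif plant collides with a splice dinucleotide")
                bases <- if (gc[1] < gc[length(gc)])
                    strsplit(motif, "")[[1]]
                else strsplit(rcmotif, "")[[1]]
                seqv[sort(gc)] <- bases
                prot <- c(prot, gc)
                planted_df[[length(planted_df) + 1L]] <- data.frame(
                    locus = li, chrom = loc$chrom, anchor = p$anchor,
                    position = x, gstart = min(gc),
                    stringsAsFactors = FALSE)
            }
        }
        # scrub accidental motif occurrences (both orientations), leaving
        # protected positions untouched
        sq <- paste0(seqv, collapse = "")
        if (scrub) for (iter in 1:50) {
            hits <- c(BiocGenerics::start(Biostrings::matchPattern(
                          motif, Biostrings::DNAString(sq))),
                      BiocGenerics::start(Biostrings::matchPattern(
                          rcmotif, Biostrings::DNAString(sq))))
            hits <- unique(hits)
            hits <- hits[vapply(hits, function(h)
                !all((h:(h + mlen - 1L)) %in% prot), TRUE)]
            if (!length(hits)) break
            for (h in hits) {
                free <- setdiff(h:(h + mlen - 1L), prot)
                pick <- free[sample.int(length(free), 1)]
                old <- substr(sq, pick, pick)
                substr(sq, pick, pick) <-
                    sample(setdiff(c("A", "C", "G", "T"), old), 1)
            }
        }
        chrs[[loc$chrom]] <- sq
        # annotation: constitutive exons always; event exons unless withheld
        keep <- seq_len(nrow(loc$exons))
        if (li %in% withhold_exons)
            keep <- setdiff(keep, loc$alt_exon_idx)
        ann[[length(ann) + 1L]] <- GenomicRanges::GRanges(
            seqnames = loc$chrom,
            ranges = IRanges::IRanges(start = loc$exons$start[keep],
                                      end = loc$exons$end[keep]),
            strand = loc$strand,
            type = "exon",
            source = "synthetic",
            gene_id = paste0("gene_", li),
            transcript_id = paste0("tx_", li),
            gene_biotype = "protein_coding")
    }
    genome <- Biostrings::DNAStringSet(unlist(chrs))
    annotation <- suppressWarnings(do.call(c, ann))
    plants_out <- if (length(planted_df)) do.call(rbind, planted_df) else
        data.frame(locus = integer(), chrom = character(),
                   anchor = character(), position = integer(),
                   gstart = integer(), stringsAsFactors = FALSE)
    list(genome = genome, annotation = annotation, plants = plants_out)
}

#' Write simulated data to disk
#'
#' Emits the standard file set for a simulated study: junction matrix TSV,
#' per-sample STAR-style SJ files, sample metadata TSV, genome FASTA, GTF and
#' a truth JSON.
#'
#' @param truth a [SyntheticTruth].
#' @param outdir output directory (created if needed).
#' @param genome_sim optional output of [simulateGenome()]; when supplied the
#'   FASTA and GTF are written too.
#' @return invisibly, a named character vector of the written paths.
#' @export
writeSimulation <- function(truth, outdir, genome_sim = NULL) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateJunctions(truth)
    paths <- c(matrix = file.path(outdir, "junctions.tsv"),
               metadata = file.path(outdir, "metadata.tsv"),
               truth = file.path(outdir, "truth.json"))
    writeJunctionMatrix(sim$junctions, paths[["matrix"]],
                        metadata_path = paths[["metadata"]])
    gr <- SummarizedExperiment::rowRanges(sim$junctions)
    cnt <- SummarizedExperiment::assay(sim$junctions, "counts")
    strand_code <- c("+" = 1L, "-" = 2L, "*" = 0L)
    for (sid in colnames(cnt)) {
        sj <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr),
            end = GenomicRanges::end(gr),
            strand = strand_code[as.character(GenomicRanges::strand(gr))],
            motif = 0L, annotated = 0L,
            unique = cnt[, sid], multi = 0L)
        p <- file.path(outdir, paste0(sid, ".SJ.out.tab"))
        utils::write.table(sj, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        paths[paste0("sj_", sid)] <- p
    }
    truth_js <- list(
        seed = truth@seed, depth = truth@depth,
        dispersion = truth@dispersion, noise_rate = truth@noiseRate,
        groups = as.list(truth@groups),
        true_psi = as.data.frame(truth@truePsi),
        events = eventIds(impliedEvents(truth)))
    jsonlite::write_json(truth_js, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(genome_sim)) {
        paths[["fasta"]] <- file.path(outdir, "genome.fa")
        Biostrings::writeXStringSet(genome_sim$genome, paths[["fasta"]])
        paths[["gtf"]] <- file.path(outdir, "annotation.gtf")
        rtracklayer::export(genome_sim$annotation, paths[["gtf"]],
                            format = "gtf")
    }
    invisible(paths)
}

#' Draw a random synthetic locus
#'
#' Samples an event type and geometry (exon/intron lengths, variant counts,
#' extra constitutive flanks, optional skip junction or bridge junction for
#' mutually exclusive pairs) from a seeded RNG. Loci stay within 8 exons and
#' imply at most 6 transcripts.
#'
#' @param chrom chromosome name for the locus.
#' @param seed integer seed.
#' @param types event types to sample from (default all four).
#' @return a locus description (see [syntheticLocus()]).
#' @export
randomLocus <- function(chrom, seed,
                        types = c("cassette", "alt_ss_group", "linked",
                                  "mutually_exclusive")) {
    set.seed(.derive_seed(seed, 101L))
    type <- sample(types, 1)
    n_extra <- sample(0:2, 1)
    flank_len <- sample(80:200, 1)
    origin <- sample(500:2000, 1)
    strand <- sample(c("+", "-"), 1)
    if (type == "cassette") {
        syntheticLocus(chrom, "cassette", origin, strand, flank_len,
                       exon_lens = sample(20:150, 1),
                       intron_lens = sample(50:500, 2, replace = TRUE),
                       n_extra_flanks = n_extra)
    } else if (type == "alt_ss_group") {
        m <- sample(2:3, 1)
        syntheticLocus(chrom, "alt_ss_group", origin, strand, flank_len,
                       exon_lens = sample(20:150, m),
                       intron_lens = sample(50:500, 2, replace = TRUE),
                       n_extra_flanks = n_extra)
    } else if (type == "linked") {
        k <- sample(2:3, 1)
        syntheticLocus(chrom, "linked", origin, strand, flank_len,
                       exon_lens = sample(20:150, k, replace = TRUE),
                       intron_lens = sample(50:500, k + 1, replace = TRUE),
                       n_extra_flanks = n_extra)
    } else {
        r <- stats::runif(1)
        syntheticLocus(chrom, "mutually_exclusive", origin, strand,
                       flank_len,
                       exon_lens = sample(20:150, 2, replace = TRUE),
                       intron_lens = sample(50:500, 3, replace = TRUE),
                       n_extra_flanks = n_extra,
                       mxe_skip = r < 0.3,
                       mxe_bridge = r >= 0.3 && r < 0.5)
    }
}
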