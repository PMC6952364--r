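#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Decompose an event into inclusion path(s) and exclusion side.
# Returns list(incl = list of junction-key vectors, one per path/variant,
#              excl = junction-key vector). For mutually exclusive pairs the
# "exclusion" side is the downstream partner path; for the other types it is
# the single exclusion junction.
.event_paths <- function(ev, i) {
    type <- ev$eventType[i]
    chrom <- ev$chrom[i]
    es <- ev$exonStarts[[i]]; ee <- ev$exonEnds[[i]]
    if (type == "mutually_exclusive") {
        keys <- ev$inclusion[[i]]
        jc <- .parse_jkey(keys)
        path_for <- function(k) {
            left <- keys[jc$end == es[k] - 1L]
            right <- keys[jc$start == ee[k] + 1L]
            c(left[1], right[1])
        }
        list(incl = list(path_for(1L)), excl = path_for(2L))
    } else if (type == "alt_ss_group") {
        excl <- ev$exclusion[[i]]
        span <- .parse_jkey(excl)
        incl <- lapply(seq_along(es), function(k)
            c(.jkey(chrom, span$start, es[k] - 1L),
              .jkey(chrom, ee[k] + 1L, span$end)))
        list(incl = incl, excl = excl)
    } else {
        list(incl = list(ev$inclusion[[i]]), excl = ev$exclusion[[i]])
    }
}

.path_aggregate <- function(m, mode) {
    # m: junctions x samples count matrix for one path
    switch(mode,
           mean = colMeans(m),
           sum = colSums(m),
           min = apply(m, 2, min),
           stop("unknown PSI mode: ", mode))
}

#' Percent spliced-in for events in one sample
#'
#' Computes PSI = 100 * I / (I + X) where I aggregates the inclusion-path
#' junction counts and X the exclusion side. With the default `mode = "mean"`
#' a two-junction inclusion path is averaged so it is commensurate with the
#' single exclusion junction; `"sum"` and `"min"` reproduce the other common
#' junction-ratio conventions. For alternative splice-site groups, I is the
#' sum of the per-variant path aggregates; for mutually exclusive pairs, X is
#' the partner (downstream-exon) path aggregate and PSI refers to the upstream
#' exon. Cells whose informative total `round(I + X)` falls below
#' `min_informative` are missing (`NA`), not 0.
#'
#' @param events a [SpliceEventSet].
#' @param counts named numeric vector of junction counts for one sample
#'   (names `chrom:start-end`); junctions absent from the lookup count 0.
#' @param min_informative minimum informative reads per cell (default 15).
#' @param mode inclusion aggregation: `"mean"` (default), `"sum"` or `"min"`.
#' @return data.frame with columns `event_id`, `psi`, `informative`.
#' @export
eventPsi <- function(events, counts, min_informative = 15L, mode = "mean") {
    if (any(counts < 0)) stop("negative junction count (corrupt input)")
    cnt <- matrix(counts, ncol = 1, dimnames = list(names(counts), "s"))
    pe <- .psi_engine(events, cnt, min_informative, mode, warn = FALSE)
    data.frame(event_id = eventIds(events),
               psi = as.numeric(pe$psi[, 1]),
               informative = as.integer(pe$informative[, 1]),
               stringsAsFactors = FALSE)
}

.psi_engine <- function(events, cnt, min_informative, mode, warn = TRUE) {
    .check_flag(min_informative, "min_informative", lo = 0, integer = TRUE)
    ev <- events@events
    ns <- ncol(cnt)
    lookup <- function(keys) {
        hit <- match(keys, rownames(cnt))
        m <- matrix(0, length(keys), ns)
        ok <- !is.na(hit)
        m[ok, ] <- cnt[hit[ok], , drop = FALSE]
        list(m = m, found = ok)
    }
    psi <- matrix(NA_real_, nrow(ev), ns,
                  dimnames = list(ev$eventId, colnames(cnt)))
    informative <- matrix(0L, nrow(ev), ns,
                          dimnames = dimnames(psi))
    for (i in seq_len(nrow(ev))) {
        paths <- .event_paths(ev, i)
        any_found <- FALSE
        I <- rep(0, ns)
        for (p in paths$incl) {
            lk <- lookup(p)
            any_found <- any_found || any(lk$found)
            I <- I + .path_aggregate(lk$m, mode)
        }
        lk <- lookup(paths$excl)
        any_found <- any_found || any(lk$found)
        X <- .path_aggregate(lk$m, mode)
        if (warn && !any_found)
            warning("event ", ev$eventId[i],
                    ": no member junction found in the table; cells missing")
        tot <- I + X
        inf <- as.integer(round(tot))
        val <- ifelse(tot > 0, 100 * I / tot, NA_real_)
        val[inf < min_informative] <- NA_real_
        psi[i, ] <- val
        informative[i, ] <- inf
    }
    list(psi = psi, informative = informative)
}

#' Quantify PSI for all events across all samples
#'
#' Applies [eventPsi()] per cell of the events-by-samples grid, producing a
#' [PsiExperiment] with assays `psi` (0-100, `NA` below `min_informative`
#' reads) and `informative`.
#'
#' @param events a [SpliceEventSet] discovered from `js` (or from a superset
#'   of its junctions; absent junctions count 0).
#' @param js the [JunctionSet] with the counts.
#' @param min_informative minimum informative reads per cell (default 15).
#' @param mode inclusion aggregation convention, see [eventPsi()].
#' @return a [PsiExperiment]; `rowData()` carries the event description and
#'   `colData()` the sample groups.
#' @export
quantifyPsi <- function(events, js, min_informative = 15L, mode = "mean") {
    cnt <- SummarizedExperiment::assay(js, "counts")
    if (any(cnt < 0)) stop("negative junction count (corrupt input)")
    rownames(cnt) <- junctionKeys(js)
    pe <- .psi_engine(events, cnt, min_informative, mode)
    ev <- events@events
    rd <- S4Vectors::DataFrame(
        eventType = ev$eventType,
        chrom = ev$chrom,
        exons = vapply(seq_len(nrow(ev)), function(i)
            paste0(ev$exonStarts[[i]], "-", ev$exonEnds[[i]],
                   collapse = ";"), ""),
        strand = ev$strand,
        annotated = ev$annotated,
        row.names = ev$eventId)
    grp <- sampleGroups(js)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(psi = pe$psi, informative = pe$informative),
        rowData = rd,
        colData = S4Vectors::DataFrame(group = unname(grp),
                                       row.names = names(grp)))
    methods::new("PsiExperiment", se)
}
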