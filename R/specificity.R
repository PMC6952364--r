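#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Per-group mean PSI
#'
#' Summarizes a [PsiExperiment] by sample group: for every event and group,
#' the mean PSI over non-missing cells and the number of informative samples
#' behind it. Groups with fewer than `min_group_n` informative samples are
#' reported as missing for that event.
#'
#' @param psi a [PsiExperiment].
#' @param groups optional named character vector (sample -> group); defaults
#'   to the groups carried in `colData(psi)`. Every sample must have a group,
#'   and every name must be a sample of `psi`.
#' @param min_group_n minimum informative samples per group mean (default 2).
#' @return list with two matrices (events x groups): `mean_psi` and
#'   `n_informative`.
#' @export
groupMeanPsi <- function(psi, groups = NULL, min_group_n = 2L) {
    .check_flag(min_group_n, "min_group_n", lo = 1, integer = TRUE)
    m <- SummarizedExperiment::assay(psi, "psi")
    if (is.null(groups)) {
        cd <- SummarizedExperiment::colData(psi)
        groups <- stats::setNames(as.character(cd$group), rownames(cd))
    }
    unknown <- setdiff(names(groups), colnames(m))
    if (length(unknown))
        stop("unknown sample in group mapping: ",
             paste(unknown, collapse = ", "))
    missing <- setdiff(colnames(m), names(groups))
    if (length(missing))
        stop("samples without a group: ", paste(missing, collapse = ", "))
    glab <- sort(unique(unname(groups)))
    mean_psi <- matrix(NA_real_, nrow(m), length(glab),
                       dimnames = list(rownames(m), glab))
    n_inf <- matrix(0L, nrow(m), length(glab), dimnames = dimnames(mean_psi))
    for (g in glab) {
        cols <- names(groups)[groups == g]
        sub <- m[, cols, drop = FALSE]
        n <- rowSums(!is.na(sub))
        mu <- rowMeans(sub, na.rm = TRUE)
        mu[n < min_group_n] <- NA_real_
        mean_psi[, g] <- mu
        n_inf[, g] <- n
    }
    list(mean_psi = mean_psi, n_informative = n_inf)
}

#' Call group-specific events
#'
#' Descriptive thresholding on group-mean PSI, mirroring the qualitative
#' "high in one cell type, skipped everywhere else" contrast: for each event
#' and each group G with an informative mean, an *enriched* call is made when
#' mean(G) minus the maximum mean over all other informative groups is at
#' least `threshold` percentage points; a *depleted* call when the minimum
#' over the others exceeds mean(G) by at least `threshold`. The contrast is
#' the min-gap against the best (worst) other group, so a single other group
#' sharing the exon vetoes specificity. Events with fewer than
#' `min_groups_informative` informative groups are skipped. No hypothesis
#' testing is involved.
#'
#' @param summaries output of [groupMeanPsi()].
#' @param threshold percentage points in (0, 100\] (default 50).
#' @param min_groups_informative minimum informative groups per event
#'   (default 3).
#' @return data.frame (`event_id`, `target_group`, `delta`, `direction`)
#'   sorted by `abs(delta)` descending; `delta` is signed: positive for
#'   enriched, negative for depleted.
#' @export
callSpecificEvents <- function(summaries, threshold = 50,
                               min_groups_informative = 3L) {
    .check_flag(threshold, "threshold", lo = 1e-9, hi = 100)
    .check_flag(min_groups_informative, "min_groups_informative", lo = 1,
                integer = TRUE)
    mu <- summaries$mean_psi
    out <- list()
    for (i in seq_len(nrow(mu))) {
        v <- mu[i, ]
        inf <- which(!is.na(v))
        if (length(inf) < min_groups_informative) next
        for (g in inf) {
            others <- v[setdiff(inf, g)]
            if (!length(others)) next
            gap_up <- v[g] - max(others)
            gap_dn <- min(others) - v[g]
            if (gap_up >= threshold)
                out[[length(out) + 1L]] <- data.frame(
                    event_id = rownames(mu)[i],
                    target_group = colnames(mu)[g],
                    delta = unname(gap_up), direction = "enriched",
                    stringsAsFactors = FALSE)
            else if (gap_dn >= threshold)
                out[[length(out) + 1L]] <- data.frame(
                    event_id = rownames(mu)[i],
                    target_group = colnames(mu)[g],
                    delta = unname(-gap_dn), direction = "depleted",
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(event_id = character(), target_group = character(),
                          delta = numeric(), direction = character(),
                          stringsAsFactors = FALSE))
    d <- do.call(rbind, out)
    d[order(-abs(d$delta), d$event_id, d$target_group), , drop = FALSE]
}

#' Write the group-summary and calls tables
#'
#' @param summaries output of [groupMeanPsi()].
#' @param path output TSV path (event x group matrix of mean PSI, one decimal,
#'   `NA` for missing).
#' @return invisibly, `path`.
#' @export
writeGroupSummary <- function(summaries, path) {
    mu <- summaries$mean_psi
    fmt <- matrix("NA", nrow(mu), ncol(mu), dimnames = dimnames(mu))
    ok <- !is.na(mu)
    fmt[ok] <- sprintf("%.1f", mu[ok])
    d <- data.frame(event_id = rownames(mu), fmt,
                    stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
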