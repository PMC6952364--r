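# Shared fixture builders. Everything is generated in code; no data files.

# JunctionSet from a compact description: data.frame(chrom, start, end)
# plus a count matrix (or a single count recycled over one sample).
jset <- function(jdf, counts = 50L, samples = NULL, strand = "+",
                 groups = NULL) {
    if (is.null(dim(counts)))
        counts <- matrix(counts, nrow = nrow(jdf))
    if (is.null(samples)) samples <- paste0("s", seq_len(ncol(counts)))
    jdf$strand <- if (length(strand) == 1) rep(strand, nrow(jdf)) else strand
    JunctionSet(jdf, counts, samples, groups = groups)
}

# One-line junction data.frame helper: jdf(c(100,199), c(100,149), ...)
jdf <- function(..., chrom = "chr1") {
    rows <- list(...)
    data.frame(chrom = chrom,
               start = vapply(rows, function(r) as.integer(r[1]), 1L),
               end = vapply(rows, function(r) as.integer(r[2]), 1L))
}

# A batch of random loci (distinct chromosomes) with one shared group.
random_truth <- function(n, seed, psi = 0.5, groups = c(g = 2L),
                         depth = 200, dispersion = 0, noise_rate = 0,
                         types = c("cassette", "alt_ss_group", "linked",
                                   "mutually_exclusive")) {
    loci <- lapply(seq_len(n), function(i)
        randomLocus(paste0("L", i), seed = seed * 1000 + i, types = types))
    psi_m <- matrix(psi, n, length(groups),
                    dimnames = list(NULL, names(groups)))
    syntheticTruth(loci, psi_m, groups, depth = depth,
                   dispersion = dispersion, noise_rate = noise_rate,
                   seed = seed)
}

# Cassette loci with introns long enough (>= 300 bases) that a motif plant
# in the proximal-200 donor window can never touch a splice dinucleotide.
motif_truth <- function(n, seed) {
    set.seed(seed)
    loci <- lapply(seq_len(n), function(i)
        syntheticLocus(paste0("M", i), "cassette",
                       origin = sample(500:1500, 1),
                       strand = sample(c("+", "-"), 1),
                       exon_lens = sample(60:150, 1),
                       intron_lens = sample(300:600, 2, replace = TRUE)))
    syntheticTruth(loci, matrix(0.5, n, 1, dimnames = list(NULL, "g")),
                   c(g = 2L), dispersion = 0, seed = seed)
}

# Cassette-only truth with one enriched group, for specificity checks.
specificity_truth <- function(n_loci, target_psi, other_psi, n_groups,
                              samples_per_group, depth = 200, seed = 1) {
    loci <- lapply(seq_len(n_loci), function(i)
        randomLocus(paste0("L", i), seed = seed * 500 + i,
                    types = "cassette"))
    groups <- stats::setNames(rep(as.integer(samples_per_group), n_groups),
                              paste0("grp", seq_len(n_groups)))
    psi <- matrix(other_psi, n_loci, n_groups,
                  dimnames = list(NULL, names(groups)))
    psi[, 1] <- target_psi
    syntheticTruth(loci, psi, groups, depth = depth, dispersion = 0,
                   seed = seed)
}
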