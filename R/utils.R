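# Internal helpers shared across modules.

# Junction key: "chrom:start-end" on intron coordinates (1-based, closed,
# first/last intronic base). Strand is intentionally not part of the key:
# discovery runs on genomic coordinates only.
.jkey <- function(chrom, start, end) paste0(chrom, ":", start, "-", end)

.parse_jkey <- function(key) {
    m <- regmatches(key, regexec("^(.+):([0-9]+)-([0-9]+)$", key))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad)) stop("malformed junction key: ", key[bad][1])
    data.frame(chrom = vapply(m, `[`, "", 2L),
               start = as.integer(vapply(m, `[`, "", 3L)),
               end = as.integer(vapply(m, `[`, "", 4L)),
               stringsAsFactors = FALSE)
}

# Event id: <type>|<chrom>|<outer span>|<exon intervals joined by ;>
.event_id <- function(type, chrom, span_start, span_end, exon_starts,
                      exon_ends) {
    paste0(type, "|", chrom, "|", span_start, "-", span_end, "|",
           paste0(exon_starts, "-", exon_ends, collapse = ";"))
}

.check_flag <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x))
        stop(name, " must be a single number")
    if (x < lo || x > hi)
        stop(name, " must lie in [", lo, ", ", hi, "]")
    if (integer && x != as.integer(x))
        stop(name, " must be an integer")
    invisible(TRUE)
}

# Normalize U->T, validate alphabet, uppercase.
.normalize_motif <- function(motif) {
    if (!is.character(motif) || length(motif) != 1 || nchar(motif) < 1)
        stop("motif must be a single nucleotide string")
    m <- chartr("u", "t", motif)
    m <- toupper(chartr("U", "T", m))
    if (grepl("[^ACGT]", m))
        stop("motif contains characters outside the A/C/G/U(T) alphabet: ",
             motif)
    m
}

# Deterministic per-purpose seed derived from a master seed (kept < 2^31).
.derive_seed <- function(seed, salt) {
    (as.numeric(seed) * 1103 + as.numeric(salt) * 7919) %% 2147483647
}
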