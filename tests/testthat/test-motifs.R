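# A plain cassette event set (exon [150,159]) over a handmade genome.
manual_event <- function(strand = "+") {
    discoverEvents(jset(jdf(c(100, 199), c(100, 149), c(160, 199)),
                        strand = strand))
}
# 1500 bases of C with substrings written at given positions.
manual_genome <- function(..., len = 1500) {
    s <- strrep("C", len)
    ins <- list(...)
    for (x in ins) substr(s, x[[1]], x[[1]] + nchar(x[[2]]) - 1L) <- x[[2]]
    Biostrings::DNAStringSet(c(chr1 = s))
}

test_that("splice-site windows are oriented, clipped and anchored correctly", {
    g <- manual_genome(list(150, "ACGTACGTAC"))
    w <- extractSpliceWindows(manual_event(), g)[[1]]$windows
    # 10-base exon: each exonic window clipped to half the exon (5 bases)
    expect_equal(w[["five_exonic"]], "CGTAC")
    expect_equal(w[["three_exonic"]], "ACGTA")
    # intronic windows: downstream of the donor, upstream of the acceptor;
    # the acceptor window is truncated at the chromosome start (149 < 1000)
    expect_equal(nchar(w[["five_intronic"]]), 1000L)
    expect_equal(nchar(w[["three_intronic"]]), 149L)

    # minus strand: same coordinates read in transcript orientation
    wm <- extractSpliceWindows(manual_event("-"), g)[[1]]$windows
    rc <- function(x) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x)))
    expect_equal(wm[["five_exonic"]], rc("ACGTA"))
    expect_equal(wm[["five_intronic"]], rc(substr(as.character(g[[1]]),
                                                  1, 149)))
    # events without strand are skipped
    expect_length(extractSpliceWindows(manual_event("*"), g), 0L)
    expect_error(extractSpliceWindows(
        manual_event(), Biostrings::DNAStringSet(c(chrZ = "ACGT"))),
        "absent from genome")
})

test_that("occurrences are counted with overlap and binned by first base", {
    # TAGTAG right after the donor: occurrences at positions -1 and -4
    g <- manual_genome(list(160, "TAGTAG"))
    pr <- positionalProfile(manual_event(), g, motif = "TAG")
    b <- pr$fiveprime@bins
    expect_equal(sum(b$count), 2)
    expect_equal(b$count[b$bin_start == -25], 2)
    expect_equal(sum(pr$threeprime@bins$count), 0)

    # overlap scan: TATAG holds one TAG
    g2 <- manual_genome(list(160, "TATAG"))
    expect_equal(sum(positionalProfile(manual_event(), g2,
                                       motif = "TAG")$fiveprime@bins$count),
                 1)
    # U and T are interchangeable in the motif alphabet
    expect_equal(positionalProfile(manual_event(), g, "UAG")$fiveprime@bins,
                 pr$fiveprime@bins)
    expect_error(positionalProfile(manual_event(), g, "TAX"), "alphabet")
    expect_error(positionalProfile(manual_event(), g, "TA"), ">= 3")
})

test_that("profiles are invariant under a full reverse complement of the locus", {
    g <- manual_genome(list(160, "TAGCCTAG"), list(120, "TAG"))
    L <- 1500L
    pr <- positionalProfile(manual_event("+"), g, motif = "TAG")
    grc <- Biostrings::DNAStringSet(c(
        chr1 = as.character(Biostrings::reverseComplement(g[[1]]))))
    mirror <- function(j) c(L - j[2] + 1L, L - j[1] + 1L)
    jsm <- jset(jdf(mirror(c(100, 199)), mirror(c(100, 149)),
                    mirror(c(160, 199))), strand = "-")
    prm <- positionalProfile(discoverEvents(jsm), grc, motif = "TAG")
    expect_equal(prm$fiveprime@bins, pr$fiveprime@bins)
    expect_equal(prm$threeprime@bins, pr$threeprime@bins)
})

test_that("planted motifs are recovered in the proximal donor window and nowhere else", {
    truth <- motif_truth(10, seed = 19)
    plants <- lapply(1:10, function(i)
        list(locus = i, anchor = "5prime_ss", from = -200, to = -3,
             copies = 8))
    gs <- simulateGenome(truth, plants = plants, motif = "TAG")
    sim_events <- impliedEvents(truth)
    pr <- positionalProfile(sim_events, gs$genome, motif = "TAG")
    b5 <- pr$fiveprime@bins
    proximal <- b5$bin_start >= -200
    expect_equal(sum(b5$count[proximal & b5$bin_start < 0]), 80)
    expect_equal(sum(b5$count[!proximal]), 0)
    expect_equal(sum(b5$count[b5$bin_start > 0]), 0)
    expect_equal(sum(pr$threeprime@bins$count), 0)
    # conservation: the counts seen per exon sum to the planted total
    expect_equal(sum(b5$count), nrow(gs$plants))

    # enrichment against a chance-rate baseline exceeds 2 in the window
    base_truth <- motif_truth(30, seed = 20)
    base_gs <- simulateGenome(base_truth, scrub = FALSE)
    bl <- baselineProfile(base_gs$annotation, base_gs$genome,
                          motif = "TAG")
    enr <- withBaseline(pr$fiveprime, bl$fiveprime)
    expect_gte(proximalEnrichment(enr), 2)
})

test_that("baseline deduplicates intervals and applies the strict length cutoff", {
    g <- manual_genome(list(150, "ACGTACGTAC"))
    ann <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(150, 150, 300), c(159, 159, 699)),
        strand = "+")
    bl <- baselineProfile(ann, g, max_exon_len = 400L)
    expect_equal(bl$fiveprime@nExons, 1)  # dup removed, 400-base exon < only
    ann2 <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(150, 300), c(159, 699)), strand = "+")
    expect_equal(baselineProfile(ann2, g, max_exon_len = 401L)
                 $fiveprime@nExons, 2)
    expect_error(baselineProfile(ann2[integer(0)], g), "no usable")
})

test_that("a uniform-background baseline is flat at the chance 3-mer rate", {
    base_truth <- motif_truth(40, seed = 21)
    gs <- simulateGenome(base_truth, scrub = FALSE)
    bl <- baselineProfile(gs$annotation, gs$genome, motif = "TAG")
    for (p in bl) {
        b <- p@bins
        # central intronic bins, clear of window-truncation edge effects
        inner <- b$bin_start >= -450 & b$bin_end <= -26
        observed <- mean(b$per_exon_mean[inner])
        expected <- 25 / 64
        se <- sqrt(expected / p@nExons / sum(inner))
        expect_lt(abs(observed - expected), 3 * se + 0.02)
    }
})

test_that("the PTBP1 preset sums the CU/UC repeat profiles", {
    g <- manual_genome(list(160, "CTCTC"))  # CTCT at -1, TCTC at -2
    pr <- positionalProfile(manual_event(), g, motif = "ptbp1")
    expect_equal(sum(pr$fiveprime@bins$count), 2)
    expect_equal(pr$fiveprime@motif, "CTCT+TCTC")
})
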