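write_star <- function(rows, path) {
    writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), ""),
               path)
    path
}

test_that("STAR SJ files are unioned with zero-fill, strand decoding and unique counts only", {
    f1 <- write_star(list(c("chr1", 1000, 2000, 1, 0, 0, 10, 99)),
                     withr::local_tempfile())
    f2 <- write_star(list(c("chr1", 1000, 2000, 1, 0, 0, 4, 50)),
                     withr::local_tempfile())
    js <- readStarJunctions(c(f1, f2), c("a", "b"))
    expect_equal(nrow(js), 1)
    expect_equal(unname(SummarizedExperiment::assay(js)[1, ]), c(10L, 4L))

    # disjoint junctions zero-fill; strand code 0 retained as unknown
    f3 <- write_star(list(c("chr1", 1000, 2000, 1, 0, 0, 7, 0)),
                     withr::local_tempfile())
    f4 <- write_star(list(c("chr1", 1000, 3000, 0, 0, 0, 5, 0)),
                     withr::local_tempfile())
    js2 <- readStarJunctions(c(f3, f4), c("a", "b"))
    expect_equal(nrow(js2), 2)
    cnt <- SummarizedExperiment::assay(js2)
    expect_equal(unname(cnt), matrix(c(7L, 0L, 0L, 5L), 2))
    expect_equal(as.character(GenomicRanges::strand(
        SummarizedExperiment::rowRanges(js2))), c("+", "*"))
})

test_that("STAR reader rejects malformed input", {
    bad <- withr::local_tempfile()
    writeLines(c("chr1\t100\t200\t1\t0\t0\t5\t0", "chr1\tbroken"), bad)
    expect_error(readStarJunctions(bad, "a"), "line 2")
    ok <- write_star(list(c("chr1", 100, 200, 1, 0, 0, 5, 0)),
                     withr::local_tempfile())
    expect_error(readStarJunctions(c(ok, ok), c("a", "a")),
                 "duplicate sample_id")
    expect_error(readStarJunctions(c(ok, ok), "a"), "same length")
})

test_that("union load is invariant to file order given the sample id pairing", {
    f1 <- write_star(list(c("chr1", 500, 900, 1, 0, 0, 3, 0),
                          c("chr2", 100, 300, 2, 0, 0, 8, 0)),
                     withr::local_tempfile())
    f2 <- write_star(list(c("chr1", 500, 900, 1, 0, 0, 6, 0)),
                     withr::local_tempfile())
    a <- readStarJunctions(c(f1, f2), c("x", "y"))
    b <- readStarJunctions(c(f2, f1), c("y", "x"))
    expect_identical(junctionKeys(a), junctionKeys(b))
    expect_identical(SummarizedExperiment::assay(a)[, c("x", "y")],
                     SummarizedExperiment::assay(b)[, c("x", "y")])
})

test_that("junction matrix round-trips through write and read", {
    for (seed in 1:3) {
        truth <- random_truth(4, seed = seed, noise_rate = 1)
        js <- simulateJunctions(truth)$junctions
        p <- withr::local_tempfile(); m <- withr::local_tempfile()
        writeJunctionMatrix(js, p, metadata_path = m)
        back <- readJunctionMatrix(p, m)
        expect_identical(junctionKeys(back), junctionKeys(js))
        expect_identical(SummarizedExperiment::assay(back),
                         SummarizedExperiment::assay(js))
        expect_identical(sampleGroups(back), sampleGroups(js))
        expect_identical(
            as.character(GenomicRanges::strand(
                SummarizedExperiment::rowRanges(back))),
            as.character(GenomicRanges::strand(
                SummarizedExperiment::rowRanges(js))))
    }
})

test_that("matrix reader validates counts, header and metadata consistency", {
    p <- withr::local_tempfile()
    writeLines(c("chrom\tstart\tend\tstrand\ts1",
                 "chr1\t100\t200\t+\t5",
                 "chr1\t300\t400\t+\t2.5"), p)
    expect_error(readJunctionMatrix(p), "non-integer count")
    p2 <- withr::local_tempfile()
    writeLines(c("chrom\tstart\tend\ts1", "chr1\t100\t200\t5"), p2)
    expect_error(readJunctionMatrix(p2), "strand")
    p3 <- withr::local_tempfile()
    writeLines(c("chrom\tstart\tend\tstrand\ts1",
                 "chr1\t100\t200\t+\t5"), p3)
    md <- withr::local_tempfile()
    writeLines(c("sample_id\tgroup", "s1\trod", "ghost\trod"), md)
    expect_error(readJunctionMatrix(p3, md), "ghost")
    # sample without metadata gets the ungrouped label
    md2 <- withr::local_tempfile()
    writeLines(c("sample_id\tgroup"), md2)
    expect_equal(unname(sampleGroups(readJunctionMatrix(p3, md2))),
                 "ungrouped")
})

test_that("JunctionSet normalizes: intron filter, duplicate collapse, sorting", {
    d <- data.frame(chrom = c("chr2", "chr1", "chr1", "chr1"),
                    start = c(50L, 500L, 100L, 100L),
                    end = c(80L, 600L, 200L, 200L),
                    strand = c("+", "+", "+", "+"))
    d$end[1] <- d$start[1] + 10L  # 11-base intron, below the default 20
    js <- JunctionSet(d, matrix(c(1L, 2L, 3L, 4L), 4), "s1")
    expect_equal(junctionKeys(js), c("chr1:100-200", "chr1:500-600"))
    # duplicates collapsed by summing
    expect_equal(unname(SummarizedExperiment::assay(js)[, 1]), c(7L, 2L))
    expect_error(JunctionSet(d, matrix(-1L, 4), "s1"), "negative")
})

test_that("PSI matrix serialization: one decimal, NA cells, header-only degenerate case", {
    truth <- random_truth(2, seed = 5, types = "cassette")
    sim <- simulateJunctions(truth)
    psi <- quantifyPsi(sim$events, sim$junctions)
    p <- withr::local_tempfile()
    writePsiMatrix(psi, p)
    lines <- readLines(p)
    expect_equal(length(lines), 3L)
    expect_match(lines[1], "^event_id\ttype\tchrom\texons\tstrand\tannotated")
    # every PSI cell prints with exactly one decimal
    cells <- unlist(lapply(strsplit(lines[-1], "\t"), `[`, -(1:6)))
    expect_true(all(grepl("^([0-9]+\\.[0-9]|NA)$", cells)))

    empty <- quantifyPsi(sim$events[integer(0)], sim$junctions)
    p2 <- withr::local_tempfile()
    writePsiMatrix(empty, p2)
    expect_equal(length(readLines(p2)), 1L)

    # masked cells write as NA
    low <- quantifyPsi(sim$events, sim$junctions, min_informative = 10000L)
    p3 <- withr::local_tempfile()
    writePsiMatrix(low, p3)
    cells <- unlist(lapply(strsplit(readLines(p3)[-1], "\t"), `[`, -(1:6)))
    expect_true(all(cells == "NA"))
})

test_that("event BED output is 0-based half-open with mean-PSI scores", {
    loc <- syntheticLocus("chr1", "cassette", origin = 100,
                          exon_lens = 50L, intron_lens = c(100L, 120L))
    truth <- syntheticTruth(list(loc), matrix(0.5, 1, 1,
                                              dimnames = list(NULL, "g")),
                            c(g = 4L), dispersion = 0, seed = 2)
    sim <- simulateJunctions(truth)
    psi <- quantifyPsi(sim$events, sim$junctions)
    p <- withr::local_tempfile()
    writeEventsBed(sim$events, p, psi)
    f <- strsplit(readLines(p), "\t")[[1]]
    ev <- sim$events@events
    expect_equal(as.integer(f[2]), ev$exonStarts[[1]][1] - 1L)
    expect_equal(as.integer(f[3]), ev$exonEnds[[1]][1])
    expect_true(as.integer(f[5]) >= 0 && as.integer(f[5]) <= 100)
    expect_equal(f[6], "+")
})
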