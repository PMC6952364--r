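test_that("coordinate index buckets junctions by shared start and end", {
    js <- jset(jdf(c(1000, 2000), c(1000, 3000), c(1500, 3000)))
    idx <- buildCoordinateIndex(js)
    expect_equal(idx$by_left[["chr1:1000"]], c(2000L, 3000L))
    expect_equal(idx$by_right[["chr1:3000"]], c(1000L, 1500L))

    empty <- jset(jdf(c(100, 200))[0, ], matrix(0L, 0, 1))
    idx0 <- buildCoordinateIndex(empty)
    expect_length(idx0$by_left, 0)
    expect_length(idx0$by_right, 0)

    # every junction is retrievable from both maps, on random tables
    for (seed in 1:3) {
        truth <- random_truth(10, seed = seed)
        jsr <- impliedJunctions(truth)
        idx <- buildCoordinateIndex(jsr)
        gr <- SummarizedExperiment::rowRanges(jsr)
        for (i in seq_along(gr)) {
            ch <- as.character(GenomicRanges::seqnames(gr))[i]
            s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
            expect_true(e %in% idx$by_left[[paste0(ch, ":", s)]])
            expect_true(s %in% idx$by_right[[paste0(ch, ":", e)]])
        }
    }
})

test_that("a skipped exon between shared coordinates is called as a cassette", {
    js <- jset(jdf(c(100, 199), c(100, 149), c(160, 199)))
    ev <- discoverEvents(js)
    expect_equal(length(ev), 1L)
    expect_equal(eventType(ev), "cassette")
    exons <- exonIntervals(ev)[[1]]
    expect_equal(IRanges::start(exons), 150L)
    expect_equal(IRanges::end(exons), 159L)
    expect_setequal(inclusionJunctions(ev)[[1]],
                    c("chr1:100-149", "chr1:160-199"))
    expect_equal(exclusionJunctions(ev)[[1]], "chr1:100-199")
})

test_that("cassette variants sharing a splice site merge into one alt-SS group", {
    js <- jset(jdf(c(100, 199), c(100, 149), c(160, 199), c(100, 144)))
    ev <- discoverEvents(js)
    expect_equal(length(ev), 1L)
    expect_equal(eventType(ev), "alt_ss_group")
    exons <- exonIntervals(ev)[[1]]
    expect_equal(IRanges::start(exons), c(145L, 150L))
    expect_equal(IRanges::end(exons), c(159L, 159L))
    expect_equal(exclusionJunctions(ev)[[1]], "chr1:100-199")
})

test_that("two non-overlapping unconnected exon paths form a mutually exclusive pair", {
    js <- jset(jdf(c(100, 149), c(160, 199), c(100, 169), c(180, 199)))
    ev <- discoverEvents(js)
    expect_equal(length(ev), 1L)
    expect_equal(eventType(ev), "mutually_exclusive")
    exons <- exonIntervals(ev)[[1]]
    expect_equal(IRanges::start(exons), c(150L, 170L))
    expect_equal(IRanges::end(exons), c(159L, 179L))
    expect_length(exclusionJunctions(ev)[[1]], 0L)
    expect_length(inclusionJunctions(ev)[[1]], 4L)

    # a bridge junction between the exons vetoes the pair (wider geometry so
    # the bridge intron clears the minimum intron length)
    js2 <- jset(jdf(c(100, 149), c(160, 239), c(100, 189), c(200, 239),
                    c(160, 189)))
    ev2 <- discoverEvents(js2)
    expect_false("mutually_exclusive" %in% eventType(ev2))
    expect_true("mxe_bridge_present" %in% diagnostics(ev2)$reason)
})

test_that("junctions below the presence filter do not seed events", {
    js <- jset(jdf(c(100, 199), c(100, 149), c(160, 199)),
               counts = matrix(c(50L, 50L, 3L), 3))
    expect_length(discoverEvents(js), 0L)
    # lowering min_reads brings the event back
    expect_length(discoverEvents(js, discoveryParams(min_reads = 3L)), 1L)
})

test_that("discovery is local: other chromosomes never change events on chr1", {
    base <- jdf(c(100, 199), c(100, 149), c(160, 199))
    ev1 <- discoverEvents(jset(base))
    withother <- rbind(base, jdf(c(100, 199), c(100, 149), c(160, 199),
                                 c(300, 500), chrom = "chr9"))
    ev2 <- discoverEvents(jset(withother))
    on1 <- ev2[ev2@events$chrom == "chr1"]
    expect_identical(eventIds(ev1), eventIds(on1))
})

test_that("discovery is deterministic and invariant to row and column order", {
    truth <- random_truth(20, seed = 11)
    js <- simulateJunctions(truth)$junctions
    ref <- discoverEvents(js)
    gr <- SummarizedExperiment::rowRanges(js)
    cnt <- SummarizedExperiment::assay(js)
    set.seed(1)
    perm <- sample(nrow(js)); cperm <- sample(ncol(js))
    js2 <- JunctionSet(
        data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[perm],
                   start = GenomicRanges::start(gr)[perm],
                   end = GenomicRanges::end(gr)[perm],
                   strand = as.character(GenomicRanges::strand(gr))[perm]),
        cnt[perm, cperm], colnames(js)[cperm])
    expect_identical(ref@events, discoverEvents(js2)@events)
    expect_identical(ref@events, discoverEvents(js)@events)
})

test_that("every emitted event satisfies its type invariants", {
    truth <- random_truth(40, seed = 23)
    ev <- discoverEvents(impliedJunctions(truth))
    expect_true(methods::validObject(ev))
    d <- ev@events
    for (i in seq_len(nrow(d))) {
        ni <- length(d$inclusion[[i]]); nx <- length(d$exclusion[[i]])
        ne <- length(d$exonStarts[[i]])
        switch(d$eventType[i],
            cassette = {
                expect_equal(ni, 2L); expect_equal(nx, 1L)
                expect_equal(ne, 1L)
            },
            linked = {
                expect_equal(ni, ne + 1L); expect_equal(nx, 1L)
                expect_gte(ne, 2L)
            },
            alt_ss_group = {
                expect_gte(ne, 2L); expect_equal(nx, 1L)
            },
            mutually_exclusive = {
                expect_equal(ni, 4L); expect_equal(nx, 0L)
                expect_equal(ne, 2L)
            })
        # exon intervals non-empty, non-overlapping, inside the outer span
        ss <- d$exonStarts[[i]]; ee <- d$exonEnds[[i]]
        expect_true(all(ss <= ee))
        if (ne > 1 && d$eventType[i] != "alt_ss_group")
            expect_true(all(ss[-1] > ee[-ne]))
    }
})

test_that("junction walk matches brute-force transcript enumeration on random loci", {
    truth <- random_truth(120, seed = 77)
    disc <- sort(eventIds(discoverEvents(impliedJunctions(truth))))
    orc <- oracle_truth_events(truth)
    expect_identical(disc, orc)
})

test_that("annotation flagging requires exact exon boundary matches", {
    js <- jset(jdf(c(100, 199), c(100, 149), c(160, 199)))
    ev <- discoverEvents(js)
    exact <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(150, 159), "+")
    off <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 160), "+")
    expect_equal(unname(annotatedFlag(annotateEvents(ev, exact))),
                 "annotated")
    expect_equal(unname(annotatedFlag(annotateEvents(ev, off))),
                 "unannotated")
    expect_equal(unname(annotatedFlag(annotateEvents(ev, NULL))),
                 "unknown")
})

test_that("a malformed GTF is reported with its line number", {
    p <- withr::local_tempfile()
    writeLines(c("# comment",
                 paste("chr1", "src", "exon", 150, 159, ".", "+", ".",
                       "gene_id \"g1\";", sep = "\t"),
                 "chr1\tbroken line"), p)
    expect_error(readGtfExons(p), "line 3")
})
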