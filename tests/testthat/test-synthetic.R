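test_that("boundary inclusion rates zero out the opposite junction counts", {
    loc <- syntheticLocus("chr1", "cassette", exon_lens = 60L)
    mk <- function(psi) {
        truth <- syntheticTruth(list(loc),
                                matrix(psi, 1, 1,
                                       dimnames = list(NULL, "g")),
                                c(g = 10L), dispersion = 0, noise_rate = 0,
                                seed = 4)
        sim <- simulateJunctions(truth)
        cnt <- SummarizedExperiment::assay(sim$junctions)
        rownames(cnt) <- junctionKeys(sim$junctions)
        list(cnt = cnt, ev = sim$events@events)
    }
    hi <- mk(1)
    excl_key <- hi$ev$exclusion[[1]]
    expect_true(all(hi$cnt[excl_key, ] == 0))
    expect_true(all(hi$cnt[hi$ev$inclusion[[1]], ] > 0))
    lo <- mk(0)
    expect_true(all(lo$cnt[lo$ev$inclusion[[1]], ] == 0))
})

test_that("simulation is byte-identical across runs with the same seed", {
    truth <- random_truth(6, seed = 8, noise_rate = 0.5, dispersion = 0.2)
    a <- simulateJunctions(truth)
    b <- simulateJunctions(truth)
    expect_identical(SummarizedExperiment::assay(a$junctions),
                     SummarizedExperiment::assay(b$junctions))
    expect_identical(junctionKeys(a$junctions), junctionKeys(b$junctions))
})

test_that("sampled PSI concentrates on the true inclusion rate", {
    loc <- syntheticLocus("chr1", "cassette", exon_lens = 80L)
    truth <- syntheticTruth(list(loc),
                            matrix(0.5, 1, 1, dimnames = list(NULL, "g")),
                            c(g = 200L), depth = 200, dispersion = 0,
                            seed = 12)
    sim <- simulateJunctions(truth)
    psi <- quantifyPsi(sim$events, sim$junctions)
    mu <- mean(SummarizedExperiment::assay(psi, "psi"), na.rm = TRUE)
    expect_gt(mu, 49); expect_lt(mu, 51)
})

test_that("the transcript chains and the emitted junction table are consistent", {
    truth <- random_truth(25, seed = 14)
    expected <- sort(unique(unlist(lapply(truth@loci, function(loc) {
        ex <- loc$exons
        unlist(lapply(loc$transcripts, function(tr) {
            if (length(tr) < 2) return(character(0))
            from <- tr[-length(tr)]; to <- tr[-1]
            paste0(loc$chrom, ":", ex$end[from] + 1L, "-",
                   ex$start[to] - 1L)
        }))
    }))))
    expect_identical(sort(junctionKeys(impliedJunctions(truth))), expected)
})

test_that("discovery inverts the simulation: exact at zero noise, superset with noise", {
    truth <- random_truth(30, seed = 16, psi = 0.5, depth = 200)
    sim <- simulateJunctions(truth)
    expect_setequal(eventIds(discoverEvents(sim$junctions)),
                    eventIds(sim$events))

    noisy <- random_truth(30, seed = 16, psi = 0.5, depth = 200,
                          noise_rate = 2)
    simn <- simulateJunctions(noisy)
    expect_true(all(eventIds(simn$events) %in%
                        eventIds(discoverEvents(simn$junctions))))
})

test_that("synthetic genomes carry canonical splice dinucleotides at every junction", {
    for (strand in c("+", "-")) {
        loc <- syntheticLocus("chr1", "linked", strand = strand,
                              exon_lens = c(40L, 60L),
                              intron_lens = c(120L, 90L, 150L))
        truth <- syntheticTruth(list(loc),
                                matrix(0.5, 1, 1,
                                       dimnames = list(NULL, "g")),
                                c(g = 2L), seed = 6)
        gs <- simulateGenome(truth)
        sq <- as.character(gs$genome[["chr1"]])
        gr <- SummarizedExperiment::rowRanges(impliedJunctions(truth))
        for (i in seq_along(gr)) {
            s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
            donor <- substr(sq, s, s + 1L)
            acceptor <- substr(sq, e - 1L, e)
            if (strand == "+") {
                expect_equal(donor, "GT"); expect_equal(acceptor, "AG")
            } else {
                expect_equal(donor, "CT"); expect_equal(acceptor, "AC")
            }
        }
    }
})

test_that("withholding event exons from the GTF flags exactly those events unannotated", {
    truth <- random_truth(12, seed = 22)
    withheld <- c(2L, 5L, 9L)
    gs <- simulateGenome(truth, withhold_exons = withheld)
    sim_ev <- impliedEvents(truth)
    flagged <- annotateEvents(sim_ev, gs$annotation)
    expect_flags <- vapply(seq_along(truth@loci), function(li) {
        if (li %in% withheld) "unannotated" else "annotated"
    }, "")
    # map events back to their locus by chromosome name
    ev_chrom <- flagged@events$chrom
    locus_of <- match(ev_chrom, vapply(truth@loci, `[[`, "", "chrom"))
    expect_equal(unname(annotatedFlag(flagged)),
                 expect_flags[locus_of])

    # the same flags come back after a GTF file round trip
    p <- withr::local_tempfile(fileext = ".gtf")
    rtracklayer::export(gs$annotation, p, format = "gtf")
    flagged2 <- annotateEvents(sim_ev, p)
    expect_identical(annotatedFlag(flagged2), annotatedFlag(flagged))
})

test_that("planted motif copies are written where requested and counted back exactly", {
    truth <- motif_truth(4, seed = 25)
    plants <- lapply(1:4, function(i)
        list(locus = i, anchor = "3prime_ss", from = -150, to = -10,
             copies = 3))
    gs <- simulateGenome(truth, plants = plants, motif = "TAG")
    expect_equal(nrow(gs$plants), 12L)
    pr <- positionalProfile(impliedEvents(truth), gs$genome, motif = "TAG")
    expect_equal(sum(pr$threeprime@bins$count), 12)
    expect_equal(sum(pr$fiveprime@bins$count), 0)
    # a plant that would overwrite a splice dinucleotide is refused
    expect_error(
        simulateGenome(truth,
                       plants = list(list(locus = 1, anchor = "5prime_ss",
                                          from = -1, to = -1, copies = 1)),
                       motif = "TAG"),
        "splice dinucleotide")
})

test_that("simulation writes a complete, reloadable file set", {
    truth <- random_truth(3, seed = 28, groups = c(gA = 2L, gB = 2L))
    outdir <- withr::local_tempdir()
    paths <- writeSimulation(truth, outdir, genome_sim = simulateGenome(truth))
    expect_true(all(file.exists(paths)))
    back <- readJunctionMatrix(paths[["matrix"]], paths[["metadata"]])
    sim <- simulateJunctions(truth)
    expect_identical(SummarizedExperiment::assay(back),
                     SummarizedExperiment::assay(sim$junctions))
    expect_identical(sampleGroups(back), sampleGroups(sim$junctions))
    # STAR dialect round trip reproduces the same table
    sj_paths <- paths[grepl("^sj_", names(paths))]
    ids <- sub("^sj_", "", names(sj_paths))
    star <- readStarJunctions(unname(sj_paths), ids)
    expect_identical(
        SummarizedExperiment::assay(star)[, colnames(back)],
        SummarizedExperiment::assay(back))
    tj <- jsonlite::read_json(paths[["truth"]])
    expect_equal(unlist(tj$events), eventIds(sim$events))
})
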