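#' @include AllClasses.R AllGenerics.R utils.R
NULL

.CONFIG_SPEC <- list(
    min_reads = list(default = 5L, lo = 0, hi = Inf, int = TRUE),
    min_samples = list(default = 1L, lo = 1, hi = Inf, int = TRUE),
    min_informative = list(default = 15L, lo = 0, hi = Inf, int = TRUE),
    mxe_noise_frac = list(default = 0.01, lo = 0, hi = 1, int = FALSE),
    max_linked = list(default = 3L, lo = 2, hi = 10, int = TRUE),
    psi_mode = list(default = "mean", choices = c("mean", "sum", "min")),
    threshold = list(default = 50, lo = 1e-9, hi = 100, int = FALSE),
    min_group_n = list(default = 2L, lo = 1, hi = Inf, int = TRUE),
    min_groups_informative = list(default = 3L, lo = 1, hi = Inf,
                                  int = TRUE),
    intronic_flank = list(default = 1000L, lo = 25, hi = 1e6, int = TRUE),
    exonic_flank = list(default = 50L, lo = 25, hi = 1e4, int = TRUE),
    bin_width = list(default = 25L, lo = 1, hi = 1000, int = TRUE),
    motif = list(default = "TAG", motif = TRUE),
    seed = list(default = 1L, lo = 0, hi = 2^31 - 1, int = TRUE))

#' Build and validate a run configuration
#'
#' Collects every tunable of the pipeline with its documented default, range
#' and type. Values can come from a YAML file and/or named overrides
#' (overrides win). Unknown keys and out-of-range values are rejected before
#' any I/O happens.
#'
#' @param ... named overrides of individual tunables.
#' @param yaml optional path to a YAML file of tunables.
#' @return validated named list of all tunables, class `"runConfig"`.
#' @export
runConfig <- function(..., yaml = NULL) {
    vals <- lapply(.CONFIG_SPEC, `[[`, "default")
    set <- function(kv, origin) {
        for (k in names(kv)) {
            if (!k %in% names(.CONFIG_SPEC))
                stop("unknown configuration key (", origin, "): ", k)
            vals[[k]] <<- kv[[k]]
        }
    }
    if (!is.null(yaml)) set(yaml::read_yaml(yaml), yaml)
    ov <- list(...)
    if (length(ov)) {
        if (is.null(names(ov)) || any(!nzchar(names(ov))))
            stop("configuration overrides must be named")
        set(ov, "override")
    }
    for (k in names(.CONFIG_SPEC)) {
        sp <- .CONFIG_SPEC[[k]]
        v <- vals[[k]]
        if (!is.null(sp$choices)) {
            if (!is.character(v) || length(v) != 1 || !v %in% sp$choices)
                stop(k, " must be one of: ",
                     paste(sp$choices, collapse = ", "))
        } else if (isTRUE(sp$motif)) {
            if (!identical(v, "ptbp1")) vapply(v, .normalize_motif, "")
        } else {
            .check_flag(v, k, lo = sp$lo, hi = sp$hi, integer = sp$int)
            if (sp$int) vals[[k]] <- as.integer(v)
        }
    }
    structure(vals, class = "runConfig")
}

#' @export
print.runConfig <- function(x, ...) {
    cat("runConfig:\n")
    for (k in names(x))
        cat(sprintf("  %-24s %s\n", k, paste(x[[k]], collapse = ",")))
    invisible(x)
}

.config_digest <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(vapply(names(config), function(k)
        paste0(k, "=", paste(config[[k]], collapse = ",")), ""), tmp)
    unname(tools::md5sum(tmp))
}

.stamp <- function(path, digest) {
    lines <- readLines(path)
    writeLines(c(paste0("# config_digest=", digest), lines), path)
}

#' Run the full analysis pipeline
#'
#' Chains ingest, event discovery, PSI quantification, group specificity and
#' (when a genome and annotation are supplied) motif profiling, writing
#' stage outputs with stable names plus a machine-readable JSON run report
#' (config, input digests, per-stage row counts, diagnostics of dropped
#' non-binary candidates). Output tables carry a header comment line with
#' the config digest; identical inputs and config give identical outputs.
#'
#' @param config a [runConfig()].
#' @param outdir output directory, created if needed.
#' @param matrix path to a junction-matrix TSV, or
#' @param star_paths,sample_ids STAR SJ.out.tab files plus sample names.
#' @param metadata optional sample metadata TSV (`sample_id`, `group`).
#' @param gtf optional GTF for annotation flagging and the motif baseline.
#' @param fasta optional genome FASTA enabling the motif stage.
#' @return invisibly, the run report list.
#' @export
runPipeline <- function(config, outdir, matrix = NULL, star_paths = NULL,
                        sample_ids = NULL, metadata = NULL, gtf = NULL,
                        fasta = NULL) {
    stopifnot(inherits(config, "runConfig"))
    inputs <- c(matrix = matrix, metadata = metadata, gtf = gtf,
                fasta = fasta, star_paths)
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    digest <- .config_digest(config)
    report <- list(package_version =
                       as.character(utils::packageVersion("JunctionWalker")),
                   config = unclass(config), config_digest = digest,
                   input_md5 = as.list(tools::md5sum(unname(inputs))),
                   stages = list())
    stage <- function(name, fun) {
        res <- tryCatch(fun(), error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        res
    }

    js <- stage("ingest", function() {
        if (!is.null(matrix)) readJunctionMatrix(matrix, metadata)
        else if (!is.null(star_paths)) {
            groups <- NULL
            if (!is.null(metadata)) {
                md <- utils::read.table(metadata, header = TRUE, sep = "\t",
                                        colClasses = "character")
                groups <- stats::setNames(md$group, md$sample_id)
            }
            readStarJunctions(star_paths, sample_ids, groups)
        } else stop("either matrix or star_paths is required")
    })
    writeJunctionMatrix(js, file.path(outdir, "junctions.tsv"))
    .stamp(file.path(outdir, "junctions.tsv"), digest)
    report$stages$ingest <- list(junctions = nrow(js), samples = ncol(js))

    events <- stage("discover", function() {
        ev <- discoverEvents(js, discoveryParams(
            min_reads = config$min_reads, min_samples = config$min_samples,
            mxe_noise_frac = config$mxe_noise_frac,
            max_linked = config$max_linked))
        annotateEvents(ev, gtf)
    })
    writeEventsTable(events, file.path(outdir, "events.tsv"))
    .stamp(file.path(outdir, "events.tsv"), digest)
    dg <- as.data.frame(diagnostics(events))
    report$stages$discover <- list(
        events = length(events),
        by_type = as.list(table(eventType(events))),
        dropped_nonbinary = nrow(dg),
        drop_reasons = as.list(table(dg$reason)))

    psi <- stage("quantify", function()
        quantifyPsi(events, js, min_informative = config$min_informative,
                    mode = config$psi_mode))
    writePsiMatrix(psi, file.path(outdir, "psi.tsv"))
    .stamp(file.path(outdir, "psi.tsv"), digest)
    writeEventsBed(events, file.path(outdir, "events.bed"), psi)
    report$stages$quantify <- list(
        cells = length(SummarizedExperiment::assay(psi, "psi")),
        informative_cells =
            sum(!is.na(SummarizedExperiment::assay(psi, "psi"))))

    calls <- stage("specificity", function() {
        gm <- groupMeanPsi(psi, min_group_n = config$min_group_n)
        writeGroupSummary(gm, file.path(outdir, "group_psi.tsv"))
        callSpecificEvents(gm, threshold = config$threshold,
                           min_groups_informative =
                               config$min_groups_informative)
    })
    .stamp(file.path(outdir, "group_psi.tsv"), digest)
    utils::write.table(calls, file.path(outdir, "specific_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stamp(file.path(outdir, "specific_calls.tsv"), digest)
    report$stages$specificity <- list(calls = nrow(calls))

    if (!is.null(fasta)) {
        profs <- stage("motifs", function() {
            pr <- positionalProfile(events, fasta, motif = config$motif,
                                    bin_width = config$bin_width,
                                    intronic_flank = config$intronic_flank,
                                    exonic_flank = config$exonic_flank)
            if (!is.null(gtf)) {
                bl <- baselineProfile(gtf, fasta, motif = config$motif,
                                      bin_width = config$bin_width,
                                      intronic_flank =
                                          config$intronic_flank,
                                      exonic_flank = config$exonic_flank)
                pr$fiveprime <- withBaseline(pr$fiveprime, bl$fiveprime)
                pr$threeprime <- withBaseline(pr$threeprime, bl$threeprime)
            }
            pr
        })
        writeMotifProfiles(profs, file.path(outdir, "motif_profile.tsv"))
        .stamp(file.path(outdir, "motif_profile.tsv"), digest)
        report$stages$motifs <- list(
            total_occurrences = sum(profs$fiveprime@bins$count) +
                sum(profs$threeprime@bins$count),
            proximal_5ss_enrichment =
                proximalEnrichment(profs$fiveprime))
    }

    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
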