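#' Pipeline orchestration
#'
#' \code{runSummarize} and \code{runAll} run the analysis stages over a set
#' of annotated mitogenomes (a list of \linkS4class{Mitogenome} objects or
#' a directory of GenBank flat files) and write the standard TSV reports.
#' All thresholds default to the survey regime (E-value 1e-10, tandem
#' arrays > 10 bp, common Pcls strictly > 1/5 of species) and are echoed
#' into the log.
#' @name pipeline
NULL

.loadAnnotations <- function(input) {
    if (is(input, "Mitogenome")) return(list(input))
    if (is.list(input)) return(input)
    stopifnot(dir.exists(input))
    files <- list.files(input, pattern = "\\.(gb|gbk|genbank)$",
                        full.names = TRUE)
    if (!length(files)) stop("no GenBank files found in ", input)
    out <- list(); failed <- 0L
    for (f in files) {
        mg <- tryCatch(readGenBank(f), error = function(e) {
            message("skipping unreadable record ", basename(f), ": ",
                    conditionMessage(e))
            NULL
        })
        if (is.null(mg)) failed <- failed + 1L else out[[length(out) + 1L]] <- mg
    }
    if (!length(out))
        stop("all ", failed, " input records failed to parse")
    out
}

#' Per-species summary report
#'
#' One row per species (length, GC, skews, region partition, feature
#' counts) plus an aggregate attribute (min/max/mean size, counts of
#' positive and negative skews).
#'
#' @param input a list of \linkS4class{Mitogenome} objects or a directory
#'   of GenBank files.
#' @return data.frame with one row per species; aggregate statistics in
#'   \code{attr(, "aggregate")}.
#' @export
runSummarize <- function(input) {
    anns <- .loadAnnotations(input)
    rows <- lapply(anns, function(mg) {
        bc <- baseComposition(mg)
        sk <- strandSkew(mg)
        rp <- regionPartition(mg)
        g <- mg@genes
        data.frame(
            species = speciesName(mg),
            size = genomeLength(mg),
            gc_percent = bc$gc_percent,
            at_percent = bc$at_percent,
            at_skew = sk$at_skew, gc_skew = sk$gc_skew,
            coding_bp = rp$coding_bp, intronic_bp = rp$intronic_bp,
            intergenic_bp = rp$intergenic_bp, rna_bp = rp$rna_bp,
            n_core_pcg = sum(g$class == "core_pcg"),
            n_free_orf = sum(g$class == "free_orf"),
            n_intronic_orf = sum(g$class == "intronic_orf"),
            n_trna = sum(g$class == "trna"),
            n_rrna = sum(g$class == "rrna"),
            n_introns = nrow(mg@introns),
            stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    attr(df, "aggregate") <- list(
        n_species = nrow(df),
        min_size = min(df$size), max_size = max(df$size),
        mean_size = mean(df$size),
        n_positive_at_skew = sum(df$at_skew > 0, na.rm = TRUE),
        n_negative_at_skew = sum(df$at_skew < 0, na.rm = TRUE),
        n_positive_gc_skew = sum(df$gc_skew > 0, na.rm = TRUE),
        n_negative_gc_skew = sum(df$gc_skew < 0, na.rm = TRUE))
    df
}

#' Run every pipeline stage and write a report bundle
#'
#' Executes composition summary, repeat detection, Pcl classification,
#' gene-order comparison and supermatrix preparation, writing TSV/newick
#' outputs plus a manifest with md5 checksums into \code{outDir}.  The
#' manifest is identical across reruns on identical inputs.
#'
#' @param input as in \code{\link{runSummarize}}.
#' @param outDir output directory (created if needed).
#' @param referenceCds reference cox1 CDS for Pcl mapping (default the
#'   package's synthetic reference).
#' @param evalueMax interspersed-repeat E-value threshold.
#' @param minRepeatLen minimum exact-repeat length.
#' @param tandemMinTotal minimum tandem-array length.
#' @param tandemMaxPeriod maximum tandem period examined.
#' @param commonFraction strict prevalence fraction for common Pcls.
#' @param repeatsOn indices of species on which the (quadratic-ish) repeat
#'   detectors run; defaults to all.
#' @return invisible list: \code{summary}, \code{pcl}, \code{orders},
#'   \code{manifest} (data.frame file/md5).
#' @export
runAll <- function(input, outDir, referenceCds = referenceCox1CDS(),
                   evalueMax = 1e-10, minRepeatLen = 8L,
                   tandemMinTotal = 11L, tandemMaxPeriod = 500L,
                   commonFraction = 1 / 5, repeatsOn = NULL) {
    anns <- .loadAnnotations(input)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    message("thresholds: evalueMax=", evalueMax,
            " minRepeatLen=", minRepeatLen,
            " tandemMinTotal=", tandemMinTotal,
            " commonFraction=", format(commonFraction))
    paths <- character(0)
    put <- function(name) {
        p <- file.path(outDir, name); paths <<- c(paths, p); p
    }

    smry <- runSummarize(anns)
    utils::write.table(smry, put("summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    if (is.null(repeatsOn)) repeatsOn <- seq_along(anns)
    reps <- list()
    for (i in repeatsOn) {
        mg <- anns[[i]]
        ir <- findInterspersedRepeats(mg, evalueMax = evalueMax)
        td <- findTandemRepeats(mg, minTotal = tandemMinTotal,
                                maxPeriod = tandemMaxPeriod)
        if (nrow(ir)) ir$species <- speciesName(mg)
        if (nrow(td)) td$species <- speciesName(mg)
        reps[[i]] <- list(interspersed = ir, tandem = td)
    }
    irAll <- do.call(rbind, lapply(reps, `[[`, "interspersed"))
    tdAll <- do.call(rbind, lapply(reps, `[[`, "tandem"))
    utils::write.table(irAll, put("repeats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tdAll, put("tandem.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    pcl <- buildPclMatrix(anns, referenceCds, commonFraction = commonFraction)
    writePclMatrixTSV(pcl, put("pcl_matrix.tsv"))
    utils::write.table(pcl$details, put("pcl_details.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    orders <- lapply(anns, extractGeneOrder)
    names(orders) <- vapply(anns, speciesName, "")
    og <- orderGroup(orders)
    utils::write.table(og, put("gene_orders.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    n <- length(orders)
    bpm <- matrix(0L, n, n, dimnames = list(names(orders), names(orders)))
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        bpm[i, j] <- bpm[j, i] <-
            breakpointDistance(orders[[i]], orders[[j]])$breakpoints
    }
    utils::write.table(bpm, put("breakpoint_matrix.tsv"), sep = "\t",
                       quote = FALSE)

    gs <- extractGeneSet(anns)
    aligned <- lapply(gs, alignGenes)
    sm <- concatenateAlignments(aligned)
    writePhylip(sm, put("supermatrix.phy"))
    writeNexus(sm, put("supermatrix.nex"))
    writePartitionFile(sm, put("partitions.txt"))
    if (length(sm$sequences) >= 4L) {
        d <- pDistance(sm)
        if (all(is.finite(d))) {
            tr <- njTree(d)
            ape::write.tree(tr, put("nj_tree.nwk"))
        }
    }

    manifest <- data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(outDir, "MANIFEST.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(summary = smry, pcl = pcl, orders = og,
                   manifest = manifest))
}
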