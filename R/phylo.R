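#' Supermatrix preparation for the combined mitochondrial gene set
#'
#' The combined set is the 15 core PCGs (as genetic-code-4 translations)
#' plus the two rRNA genes (as nucleotide sequences).  Per-gene alignments
#' are concatenated in fixed (alphabetical) gene order into a supermatrix
#' with a contiguous, non-overlapping partition table; taxa missing a gene
#' are gap-filled.  External ML/BI inference consumes the exported files; a
#' neighbor-joining tree on p-distances is provided as a sanity check.
#' @name phylo_prep
NULL

#' Extract the 17-gene comparison set across species
#'
#' @param annotations list of \linkS4class{Mitogenome} objects (length >= 2).
#' @return named list of 17 collections; each is a named character vector
#'   (species -> sequence) with attribute \code{type} (\code{"protein"} or
#'   \code{"rna"}) and attribute \code{missing} (species lacking the gene).
#' @export
extractGeneSet <- function(annotations) {
    stopifnot(length(annotations) >= 2L)
    sp <- vapply(annotations, speciesName, "")
    genes <- sort(ORDER_GENE_SET)
    out <- list()
    for (g in genes) {
        type <- if (g %in% RRNA_GENES) "rna" else "protein"
        seqs <- character(0)
        for (k in seq_along(annotations)) {
            mg <- annotations[[k]]
            if (!(g %in% mg@genes$gene)) next
            s <- suppressWarnings(extractCDS(mg, g))
            if (type == "protein")
                s <- suppressWarnings(translateCode4(s))
            seqs[sp[k]] <- s
        }
        attr(seqs, "type") <- type
        attr(seqs, "missing") <- setdiff(sp, names(seqs))
        out[[g]] <- seqs
    }
    out
}

#' Align one gene collection
#'
#' \code{method = "builtin"} uses the package's deterministic progressive
#' aligner: every sequence is globally aligned to the first sequence in
#' input order and the per-position insertion profiles merged, so results
#' are reproducible offline.  \code{method = "mafft"} shells out to a
#' \code{mafft} executable when one is on the PATH.
#'
#' @param seqs named character vector with a \code{type} attribute
#'   (\code{"protein"} or \code{"rna"}), as from
#'   \code{\link{extractGeneSet}}.
#' @param method \code{"builtin"} (default) or \code{"mafft"}.
#' @return named character vector of equal-length aligned sequences
#'   (\code{"-"} gaps), \code{type} attribute preserved.
#' @export
alignGenes <- function(seqs, method = c("builtin", "mafft")) {
    method <- match.arg(method)
    type <- attr(seqs, "type")
    if (is.null(type)) type <- "protein"
    if (length(seqs) == 0L) return(seqs)
    if (length(seqs) == 1L || length(unique(nchar(seqs))) == 1L &&
        length(unique(seqs)) == 1L) {
        out <- seqs; attr(out, "type") <- type; return(out)
    }
    out <- switch(method,
        builtin = .alignProgressive(seqs, type),
        mafft = .alignMafft(seqs))
    attr(out, "type") <- type
    out
}

.alignPair <- function(a, b, type) {
    if (type == "protein") {
        al <- alignProteinGlobal(a, b)
        list(a = al$aligned_query, b = al$aligned_reference)
    } else {
        mat <- Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -2, baseOnly = FALSE)
        pa <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(a), Biostrings::DNAString(b),
            substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
            type = "global")
        list(a = as.character(Biostrings::alignedPattern(pa)),
             b = as.character(Biostrings::alignedSubject(pa)))
    }
}

# progressive reference-anchored alignment: every sequence aligned to the
# first; insertion profiles (gaps opened in the reference) merged by max
.alignProgressive <- function(seqs, type) {
    ref <- seqs[[1L]]
    n <- nchar(ref)
    ins <- integer(n + 1L)              # insertions after ref position 0..n
    parsed <- list()
    for (k in seq_along(seqs)[-1L]) {
        al <- .alignPair(seqs[[k]], ref, type)
        qa <- strsplit(al$a, "")[[1L]]
        rb <- strsplit(al$b, "")[[1L]]
        refpos <- cumsum(rb != "-")
        runs <- rle(rb == "-")
        # per ref position: how many query chars inserted after it
        insHere <- integer(n + 1L)
        i <- 1L
        for (r in seq_along(runs$lengths)) {
            if (runs$values[r]) {
                after <- if (i == 1L) 0L else refpos[i - 1L]
                insHere[after + 1L] <- insHere[after + 1L] + runs$lengths[r]
            }
            i <- i + runs$lengths[r]
        }
        ins <- pmax(ins, insHere)
        parsed[[names(seqs)[k]]] <- list(qa = qa, rb = rb)
    }
    # rebuild rows against the merged insertion profile
    refchars <- strsplit(ref, "")[[1L]]
    refRow <- rep("-", ins[1L])
    for (p in seq_len(n))
        refRow <- c(refRow, refchars[p], rep("-", ins[p + 1L]))
    out <- c(paste(refRow, collapse = ""))
    names(out) <- names(seqs)[1L]
    for (k in seq_along(seqs)[-1L]) {
        pr <- parsed[[names(seqs)[k]]]
        out[names(seqs)[k]] <- .buildRow(pr$qa, pr$rb, ins)
    }
    stopifnot(length(unique(nchar(out))) == 1L)
    out
}

.buildRow <- function(qa, rb, ins) {
    outchars <- character(0)
    pos <- 0L
    gotIns <- character(0)
    for (i in seq_along(rb)) {
        if (rb[i] == "-") {
            gotIns <- c(gotIns, qa[i])
        } else {
            need <- ins[pos + 1L]
            outchars <- c(outchars, gotIns, rep("-", need - length(gotIns)))
            gotIns <- character(0)
            pos <- pos + 1L
            outchars <- c(outchars, qa[i])
        }
    }
    need <- ins[pos + 1L]
    outchars <- c(outchars, gotIns, rep("-", need - length(gotIns)))
    paste(outchars, collapse = "")
}

.alignMafft <- function(seqs) {
    if (Sys.which("mafft") == "")
        stop("mafft executable not found on PATH")
    tin <- tempfile(fileext = ".fa"); tout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(tin, tout)))
    writeLines(paste0(">", names(seqs), "\n", seqs), tin)
    system2("mafft", c("--auto", "--quiet", tin), stdout = tout)
    x <- Biostrings::readBStringSet(tout)
    out <- toupper(as.character(x))
    names(out) <- names(x)
    out[names(seqs)]
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in alphabetical order; a taxon absent from a gene
#' receives all-gap characters in that partition.  Duplicate taxon labels
#' are an error.
#'
#' @param alignedGenes named list of aligned collections (see
#'   \code{\link{alignGenes}}).
#' @return list of class \code{"Supermatrix"}: \code{sequences} (named
#'   character vector, equal lengths), \code{partitions} (data.frame:
#'   \code{gene}, \code{start}, \code{end}, \code{type}),
#'   \code{gap_fraction} (named numeric per taxon).
#' @export
concatenateAlignments <- function(alignedGenes) {
    genes <- sort(names(alignedGenes))
    for (g in genes)
        if (anyDuplicated(names(alignedGenes[[g]])))
            stop("duplicate taxon labels in gene '", g, "'")
    taxa <- unique(unlist(lapply(alignedGenes, names)))
    rows <- setNames(rep("", length(taxa)), taxa)
    parts <- data.frame(gene = character(0), start = integer(0),
                        end = integer(0), type = character(0),
                        stringsAsFactors = FALSE)
    pos <- 0L
    for (g in genes) {
        al <- alignedGenes[[g]]
        if (!length(al)) next
        wl <- unique(nchar(al))
        if (length(wl) != 1L)
            stop("gene '", g, "': aligned lengths differ")
        type <- attr(al, "type"); if (is.null(type)) type <- "protein"
        gaps <- strrep("-", wl)
        for (tx in taxa)
            rows[tx] <- paste0(rows[tx],
                               if (tx %in% names(al)) al[[tx]] else gaps)
        parts <- rbind(parts, data.frame(gene = g, start = pos + 1L,
                                         end = pos + wl, type = type,
                                         stringsAsFactors = FALSE))
        pos <- pos + wl
    }
    gapFrac <- vapply(rows, function(r) {
        ch <- strsplit(r, "")[[1L]]
        mean(ch == "-")
    }, 1)
    out <- list(sequences = rows, partitions = parts,
                gap_fraction = gapFrac)
    class(out) <- "Supermatrix"
    out
}

#' @export
print.Supermatrix <- function(x, ...) {
    cat(sprintf("Supermatrix: %d taxa x %d columns, %d partitions\n",
                length(x$sequences), nchar(x$sequences[[1L]]),
                nrow(x$partitions)))
    invisible(x)
}

#' Relaxed-PHYLIP, NEXUS and partition-file writers
#'
#' \code{writePhylip} writes relaxed PHYLIP (taxon name, two spaces,
#' sequence); \code{readPhylip} reads it back; \code{writeNexus} writes a
#' minimal NEXUS DATA block; \code{writePartitionFile} writes RAxML-style
#' lines \code{"<model>, <gene> = <start>-<end>"}.
#'
#' @param sm a \code{Supermatrix} (for \code{writePhylip} a named character
#'   vector is also accepted).
#' @param path output file.
#' @param proteinModel,rnaModel model tokens for the partition file.
#' @return the path, invisibly (\code{readPhylip}: named character vector).
#' @export
writePhylip <- function(sm, path) {
    seqs <- if (inherits(sm, "Supermatrix")) sm$sequences else sm
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf(" %d %d", length(seqs), nchar(seqs[[1L]])), con)
    writeLines(sprintf("%s  %s", names(seqs), unname(seqs)), con)
    invisible(path)
}

#' @rdname writePhylip
#' @export
readPhylip <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]])
    body <- lines[-1L][nzchar(trimws(lines[-1L]))]
    parts <- strsplit(body, "[[:space:]]+")
    out <- setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
    if (length(out) != hdr[1L] || any(nchar(out) != hdr[2L]))
        stop("PHYLIP header does not match body")
    out
}

#' @rdname writePhylip
#' @export
writeNexus <- function(sm, path) {
    stopifnot(inherits(sm, "Supermatrix"))
    seqs <- sm$sequences
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("#NEXUS", "BEGIN DATA;",
        sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs),
                nchar(seqs[[1L]])),
        "  FORMAT DATATYPE=PROTEIN GAP=- MISSING=?;",
        "  MATRIX"), con)
    writeLines(sprintf("    %s  %s", names(seqs), unname(seqs)), con)
    writeLines(c("  ;", "END;"), con)
    invisible(path)
}

#' @rdname writePhylip
#' @export
writePartitionFile <- function(sm, path, proteinModel = "WAG",
                               rnaModel = "GTR") {
    stopifnot(inherits(sm, "Supermatrix"))
    p <- sm$partitions
    model <- ifelse(p$type == "rna", rnaModel, proteinModel)
    writeLines(sprintf("%s, %s = %d-%d", model, p$gene, p$start, p$end),
               path)
    invisible(path)
}

#' Pairwise p-distances over shared non-gap columns
#'
#' @param sm a \code{Supermatrix} or named character vector of aligned
#'   sequences.
#' @return symmetric numeric matrix of fractions of differing sites.
#' @export
pDistance <- function(sm) {
    seqs <- if (inherits(sm, "Supermatrix")) sm$sequences else sm
    chars <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
    n <- length(chars)
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        a <- chars[[i]]; b <- chars[[j]]
        ok <- a != "-" & b != "-" & a != "?" & b != "?"
        d[i, j] <- d[j, i] <- if (any(ok)) mean(a[ok] != b[ok]) else NA_real_
    }
    d
}

#' Neighbor-joining sanity tree
#'
#' Standard neighbor joining (via \link[ape]{nj}) on a distance matrix,
#' with taxa sorted by label beforehand so the result is invariant to input
#' order.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return an unrooted \code{phylo} tree.
#' @export
njTree <- function(d) {
    if (any(!is.finite(d))) stop("non-finite distances")
    if (nrow(d) < 4L) stop("need at least 4 taxa")
    o <- order(rownames(d))
    ape::nj(as.dist(d[o, o]))
}
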