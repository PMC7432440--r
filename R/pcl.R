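#' Intron position classes (Pcls) on a reference cox1 coordinate system
#'
#' A Pcl names an intron insertion site by its nucleotide coordinate in a
#' reference cox1 coding sequence, with a codon-phase annotation: phase 0
#' means insertion at a codon boundary, "+1" between nt 1 and nt 2 of the
#' indicated codon, "+2" between nt 2 and nt 3.  Identical Pcls in
#' different species are treated as homologous introns.
#' @name pcl
NULL

.AA_CHARS <- c(LETTERS, "*", "-")

#' Global protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties (a gap of length L costs \code{gapOpening + L * gapExtension}).
#' Delegates to \link[Biostrings]{pairwiseAlignment}, whose tie-breaking is
#' deterministic.
#'
#' @param query,reference protein sequences (character or \code{AAString}).
#' @param gapOpening,gapExtension positive gap penalties (defaults 10 and 1).
#' @return list of class \code{"ProteinAlignment"}: \code{aligned_query},
#'   \code{aligned_reference} (equal-length strings with \code{"-"} gaps)
#'   and \code{score}.
#' @export
alignProteinGlobal <- function(query, reference, gapOpening = 10,
                               gapExtension = 1) {
    query <- as.character(query); reference <- as.character(reference)
    if (!nzchar(query) || !nzchar(reference))
        stop("both sequences must be non-empty")
    for (s in c(query, reference)) {
        bad <- setdiff(unique(strsplit(s, "")[[1L]]), .AA_CHARS)
        if (length(bad))
            stop("non-amino-acid characters in input: ",
                 paste(bad, collapse = ", "))
    }
    data("BLOSUM62", package = "Biostrings", envir = environment())
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(query), Biostrings::AAString(reference),
        substitutionMatrix = get("BLOSUM62", envir = environment()),
        gapOpening = gapOpening, gapExtension = gapExtension,
        type = "global")
    out <- list(
        aligned_query = as.character(Biostrings::alignedPattern(pa)),
        aligned_reference = as.character(Biostrings::alignedSubject(pa)),
        score = Biostrings::score(pa))
    class(out) <- "ProteinAlignment"
    out
}

#' Coding-sequence offsets of a gene's introns
#'
#' For each intron of the host gene, the number of coding nucleotides
#' preceding the insertion site in the (strand-corrected, exon-concatenated)
#' CDS.  Each intron must lie between two consecutive exons in
#' transcription order.
#'
#' @param mg a \linkS4class{Mitogenome}.
#' @param gene host gene symbol (default \code{"cox1"}).
#' @return data.frame: \code{ordinal}, \code{cds_nt_offset}, sorted by
#'   offset.
#' @export
intronInsertionPoints <- function(mg, gene = "cox1") {
    gene <- normalizeGeneSymbol(gene)
    g <- mg@genes
    gi <- which(g$gene == gene)
    if (!length(gi)) stop("gene '", gene, "' not found")
    gi <- gi[1L]
    ex <- g$exons[[gi]]
    strand <- g$strand[gi]
    o <- order(start(ex))
    if (strand == "-") o <- rev(o)          # transcription order
    exs <- start(ex)[o]; exe <- end(ex)[o]
    w <- exe - exs + 1L
    it <- mg@introns
    ii <- which(it$host == gene)
    if (!length(ii))
        return(data.frame(ordinal = integer(0), cds_nt_offset = integer(0)))
    off <- vapply(ii, function(r) {
        s <- it$start[r]; e <- it$end[r]
        for (j in seq_len(length(o) - 1L)) {
            between <- if (strand == "+")
                (s > exe[j] && e < exs[j + 1L])
            else
                (e < exs[j] && s > exe[j + 1L])
            if (between) return(sum(w[seq_len(j)]))
        }
        stop("intron ", it$ordinal[r], " of '", gene,
             "' does not lie between consecutive exons")
    }, 1L)
    out <- data.frame(ordinal = it$ordinal[ii], cds_nt_offset = off)
    out[order(out$cds_nt_offset), ]
}

#' Project a query insertion offset onto the reference coordinate system
#'
#' The query codon index is \code{ceiling(offset / 3)} and the phase is
#' \code{offset mod 3}.  The query residue is located in the global protein
#' alignment and the reference residue index at that column read off; the
#' reference nucleotide position is \code{3 * (ref_aa - 1) + phase} for
#' phases +1/+2 and \code{3 * ref_aa} at codon boundaries.  An insertion
#' site falling in a reference-gap column takes the nearest reference
#' residue to the left and is flagged inexact.
#'
#' @param cds_nt_offset coding nucleotides preceding the insertion site in
#'   the query CDS (must satisfy \code{0 < offset < CDS length}).
#' @param queryProtein,referenceProtein the translated sequences.
#' @param alignment optional precomputed \code{\link{alignProteinGlobal}}
#'   result.
#' @return list: \code{label} (e.g. \code{"P383"}), \code{label_phased}
#'   (\code{"P383+2"}), \code{ref_nt_position}, \code{phase} (0, 1 or 2),
#'   \code{exact} (logical).
#' @export
projectToReference <- function(cds_nt_offset, queryProtein,
                               referenceProtein, alignment = NULL) {
    stopifnot(cds_nt_offset > 0)
    if (is.null(alignment))
        alignment <- alignProteinGlobal(queryProtein, referenceProtein)
    phase <- cds_nt_offset %% 3L
    qCodon <- ceiling(cds_nt_offset / 3)
    qa <- strsplit(alignment$aligned_query, "")[[1L]]
    ra <- strsplit(alignment$aligned_reference, "")[[1L]]
    qIdx <- cumsum(qa != "-")
    col <- match(qCodon, qIdx)
    if (is.na(col))
        stop("query codon ", qCodon, " beyond aligned query length")
    refCount <- cumsum(ra != "-")
    exact <- ra[col] != "-"
    refIdx <- max(1L, refCount[col])
    pos <- 3L * (refIdx - 1L) + if (phase > 0L) phase else 3L
    list(label = paste0("P", pos),
         label_phased = if (phase > 0L) paste0("P", pos, "+", phase)
                        else paste0("P", pos),
         ref_nt_position = pos, phase = phase, exact = exact)
}

#' Species-by-Pcl presence matrix with common/rare classification
#'
#' Maps every cox1 intron of every species onto the reference coordinate
#' system via protein alignment, merges identical labels across species
#' (homologous introns), and classifies each Pcl common or rare: common
#' means present in strictly more than \code{n/5} of the \code{n} species.
#'
#' @param annotations list of \linkS4class{Mitogenome} objects.
#' @param referenceCds the reference cox1 coding sequence (character or
#'   \code{DNAString}); must translate cleanly under genetic code 4.
#' @param commonFraction prevalence fraction above which (strictly) a Pcl
#'   is called common (default 1/5).
#' @return list of class \code{"PclMatrix"}: \code{presence} (logical
#'   species x Pcl matrix, columns ordered by reference position),
#'   \code{prevalence}, \code{class} (\code{"common"}/\code{"rare"}),
#'   \code{details} (per-intron data.frame: species, ordinal, query offset,
#'   label, phase, exact).
#' @export
buildPclMatrix <- function(annotations, referenceCds,
                           commonFraction = 1 / 5) {
    refProt <- translateCode4(referenceCds)
    if (grepl("*", refProt, fixed = TRUE))
        stop("reference CDS contains internal stop codons under code 4")
    sp <- vapply(annotations, speciesName, "")
    det <- list()
    for (k in seq_along(annotations)) {
        mg <- annotations[[k]]
        if (!("cox1" %in% mg@genes$gene)) {
            warning("species '", sp[k], "' lacks cox1; included with zero introns")
            next
        }
        pts <- intronInsertionPoints(mg, "cox1")
        if (!nrow(pts)) next
        qProt <- suppressWarnings(translateCode4(extractCDS(mg, "cox1")))
        aln <- alignProteinGlobal(qProt, refProt)
        for (r in seq_len(nrow(pts))) {
            pr <- projectToReference(pts$cds_nt_offset[r], qProt, refProt, aln)
            det[[length(det) + 1L]] <- data.frame(
                species = sp[k], ordinal = pts$ordinal[r],
                query_offset = pts$cds_nt_offset[r],
                label = pr$label, label_phased = pr$label_phased,
                ref_nt_position = pr$ref_nt_position,
                phase = pr$phase, exact = pr$exact,
                stringsAsFactors = FALSE)
        }
    }
    details <- if (length(det)) do.call(rbind, det) else
        data.frame(species = character(0), ordinal = integer(0),
                   query_offset = integer(0), label = character(0),
                   label_phased = character(0), ref_nt_position = integer(0),
                   phase = integer(0), exact = logical(0))
    labels <- unique(details$label[order(details$ref_nt_position)])
    presence <- matrix(FALSE, nrow = length(sp), ncol = length(labels),
                       dimnames = list(sp, labels))
    if (nrow(details))
        presence[cbind(match(details$species, sp),
                       match(details$label, labels))] <- TRUE
    prevalence <- colSums(presence)
    n <- length(sp)
    cls <- ifelse(prevalence > n * commonFraction, "common", "rare")
    out <- list(presence = presence, prevalence = prevalence,
                class = cls, details = details, n_species = n,
                common_fraction = commonFraction)
    class(out) <- "PclMatrix"
    out
}

#' @export
print.PclMatrix <- function(x, ...) {
    cat(sprintf("PclMatrix: %d species x %d Pcls (%d common, %d rare)\n",
                x$n_species, ncol(x$presence),
                sum(x$class == "common"), sum(x$class == "rare")))
    if (length(x$prevalence)) {
        top <- sort(x$prevalence, decreasing = TRUE)
        show <- utils::head(top, 5L)
        cat("  top prevalence:",
            paste(sprintf("%s (%d)", names(show), show), collapse = ", "),
            "\n")
    }
    invisible(x)
}

#' Write the Pcl presence matrix as TSV (species rows, Pcl columns, 0/1)
#' @param pm a \code{PclMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePclMatrixTSV <- function(pm, path) {
    m <- pm$presence * 1L
    df <- data.frame(species = rownames(m), m, check.names = FALSE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines("# Pcl labels are nt positions in the reference cox1 CDS (1-based)", con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
        row.names = FALSE))
    invisible(path)
}

#' Pearson correlation between mitogenome size and intron count
#'
#' @param records data.frame with columns \code{size} (bp) and
#'   \code{introns} (count), one row per species.
#' @return Pearson correlation coefficient; \code{NA} with a warning when
#'   either variable has zero variance.
#' @export
pearsonSizeIntron <- function(records) {
    stopifnot(all(c("size", "introns") %in% colnames(records)))
    if (nrow(records) < 3L) stop("need at least 3 records")
    if (stats::var(records$size) == 0 || stats::var(records$introns) == 0) {
        warning("zero variance; correlation undefined")
        return(NA_real_)
    }
    stats::cor(records$size, records$introns, method = "pearson")
}
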