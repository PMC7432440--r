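#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges IRangesList start end width reduce
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
NULL

#' Annotated mitochondrial genome
#'
#' \code{Mitogenome} holds one circular (or linear) mitochondrial genome
#' sequence together with its typed features in a single 1-based, inclusive
#' coordinate frame.  Features that span the origin of a circular molecule are
#' stored in linearized virtual coordinates (\code{end = end + L}); the
#' GenBank writer re-wraps them on output.
#'
#' @slot id single character, record identifier.
#' @slot species single character, species name.
#' @slot taxon single character, free-text order/family labels.
#' @slot seq a \link[Biostrings]{DNAString}, the genome sequence
#'   (uppercase, alphabet A/C/G/T/N).
#' @slot circular single logical.
#' @slot genes a \link[S4Vectors]{DataFrame} with one row per gene:
#'   \code{gene} (symbol), \code{class} (one of \code{core_pcg},
#'   \code{free_orf}, \code{intronic_orf}, \code{trna}, \code{rrna}),
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{product} (free text),
#'   \code{host_intron} (integer row index into \code{introns}, or
#'   \code{NA}), and \code{exons}, an \link[IRanges]{IRangesList} of exon
#'   intervals in increasing genomic order.
#' @slot introns a \link[S4Vectors]{DataFrame} with one row per intron:
#'   \code{host} (gene symbol), \code{ordinal} (1-based, transcription
#'   order), \code{start}, \code{end}, \code{strand}, \code{group}
#'   (\code{"I"}, \code{"II"} or \code{"unknown"}).
#'
#' @seealso \code{\link{readGenBank}}, \code{\link{generateMitogenome}}
#' @export
setClass("Mitogenome",
    representation(
        id = "character",
        species = "character",
        taxon = "character",
        seq = "DNAString",
        circular = "logical",
        genes = "DataFrame",
        introns = "DataFrame"
    )
)

.emptyGeneTable <- function() {
    DataFrame(
        gene = character(0), class = character(0), strand = character(0),
        product = character(0), host_intron = integer(0),
        exons = IRangesList()
    )
}

.emptyIntronTable <- function() {
    DataFrame(
        host = character(0), ordinal = integer(0),
        start = integer(0), end = integer(0),
        strand = character(0), group = character(0)
    )
}

.validMitogenome <- function(object) {
    msg <- character(0)
    L <- length(object@seq)
    if (L < 1L)
        msg <- c(msg, "genome sequence is empty")
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    letters <- unique(strsplit(as.character(object@seq), "")[[1L]])
    if (!all(letters %in% c("A", "C", "G", "T", "N")))
        msg <- c(msg, "genome residues must be uppercase A/C/G/T/N")
    g <- object@genes
    if (nrow(g)) {
        need <- c("gene", "class", "strand", "product", "host_intron", "exons")
        if (!all(need %in% colnames(g)))
            msg <- c(msg, "gene table is missing required columns")
        else {
            if (!all(g$class %in% c("core_pcg", "free_orf", "intronic_orf",
                                    "trna", "rrna")))
                msg <- c(msg, "unknown feature class in gene table")
            if (!all(g$strand %in% c("+", "-")))
                msg <- c(msg, "gene strand must be '+' or '-'")
            for (i in seq_len(nrow(g))) {
                ex <- g$exons[[i]]
                if (length(ex) == 0L) {
                    msg <- c(msg, sprintf("gene '%s' has no exons", g$gene[i]))
                    next
                }
                if (any(start(ex) < 1L) || any(end(ex) > 2L * L))
                    msg <- c(msg, sprintf(
                        "gene '%s': exon outside genome bounds", g$gene[i]))
                if (length(ex) > 1L) {
                    o <- order(start(ex))
                    if (any(end(ex)[o][-length(ex)] >= start(ex)[o][-1L]))
                        msg <- c(msg, sprintf(
                            "gene '%s': overlapping exons", g$gene[i]))
                }
            }
        }
    }
    it <- object@introns
    if (nrow(it)) {
        if (!all(it$host %in% g$gene))
            msg <- c(msg, "intron host gene absent from gene table")
        if (anyDuplicated(paste(it$host, it$ordinal)))
            msg <- c(msg, "duplicate intron ordinal within a host gene")
        if (!all(it$group %in% c("I", "II", "unknown")))
            msg <- c(msg, "intron group must be 'I', 'II' or 'unknown'")
    }
    if (length(msg)) msg else TRUE
}

setValidity("Mitogenome", .validMitogenome)

#' Construct a Mitogenome
#'
#' @param id record identifier.
#' @param seq genome sequence (\code{DNAString} or character).
#' @param species species name.
#' @param taxon free-text taxonomy labels.
#' @param circular logical, circular molecule.
#' @param genes gene table (see \linkS4class{Mitogenome}); defaults to empty.
#' @param introns intron table; defaults to empty.
#' @return a \linkS4class{Mitogenome}.
#' @examples
#' mg <- Mitogenome("toy", "ATGAAATAGCCGGCC")
#' genomeLength(mg)
#' @export
Mitogenome <- function(id, seq, species = id, taxon = "",
                       circular = TRUE,
                       genes = .emptyGeneTable(),
                       introns = .emptyIntronTable()) {
    if (is.character(seq))
        seq <- DNAString(toupper(seq))
    new("Mitogenome", id = id, species = species, taxon = taxon,
        seq = seq, circular = circular,
        genes = genes, introns = introns)
}

setMethod("show", "Mitogenome", function(object) {
    cat(sprintf("Mitogenome '%s' (%s)\n", object@id, object@species))
    cat(sprintf("  %s molecule, %d bp\n",
        if (object@circular) "circular" else "linear",
        length(object@seq)))
    cls <- table(factor(object@genes$class,
        levels = c("core_pcg", "free_orf", "intronic_orf", "trna", "rrna")))
    cat(sprintf(
        "  genes: %d core PCG, %d free ORF, %d intronic ORF, %d tRNA, %d rRNA\n",
        cls["core_pcg"], cls["free_orf"], cls["intronic_orf"],
        cls["trna"], cls["rrna"]))
    cat(sprintf("  introns: %d\n", nrow(object@introns)))
})

#' @rdname Mitogenome-accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname Mitogenome-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname Mitogenome-accessors
#' @export
setGeneric("mitoGenes", function(x) standardGeneric("mitoGenes"))

#' @rdname Mitogenome-accessors
#' @export
setGeneric("mitoIntrons", function(x) standardGeneric("mitoIntrons"))

#' @rdname Mitogenome-accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' Accessors for Mitogenome objects
#'
#' @param x a \linkS4class{Mitogenome}.
#' @return \code{genomeSeq}: the \code{DNAString}; \code{genomeLength}: the
#'   length in bp; \code{mitoGenes} / \code{mitoIntrons}: the feature tables;
#'   \code{speciesName}: the species string.
#' @name Mitogenome-accessors
#' @aliases genomeSeq genomeLength mitoGenes mitoIntrons speciesName
NULL

#' @rdname Mitogenome-accessors
#' @export
setMethod("genomeSeq", "Mitogenome", function(x) x@seq)

#' @rdname Mitogenome-accessors
#' @export
setMethod("genomeLength", "Mitogenome", function(x) length(x@seq))

#' @rdname Mitogenome-accessors
#' @export
setMethod("mitoGenes", "Mitogenome", function(x) x@genes)

#' @rdname Mitogenome-accessors
#' @export
setMethod("mitoIntrons", "Mitogenome", function(x) x@introns)

#' @rdname Mitogenome-accessors
#' @export
setMethod("speciesName", "Mitogenome", function(x) x@species)
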