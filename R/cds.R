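# extract 1-based inclusive interval, wrapping linearized coords (end > L)
.extractInterval <- function(seqchr, s, e, L) {
    if (e <= L) return(substr(seqchr, s, e))
    paste0(substr(seqchr, s, L), substr(seqchr, 1L, e - L))
}

#' Extract the coding sequence of a gene
#'
#' Concatenates the gene's exons in transcription order (excluding introns)
#' and reverse-complements the result for minus-strand genes.  A length not
#' divisible by 3 triggers a warning (expected for protein-coding genes).
#'
#' @param mg a \linkS4class{Mitogenome}.
#' @param gene canonical gene symbol (see \code{\link{normalizeGeneSymbol}}).
#' @return the CDS as a single character string (sense strand).
#' @examples
#' mg <- Mitogenome("toy", "ATGAAATAGCCGGCC")
#' @export
extractCDS <- function(mg, gene) {
    g <- mg@genes
    i <- which(g$gene == normalizeGeneSymbol(gene))
    if (!length(i))
        stop("gene '", gene, "' not found in record '", mg@id, "'")
    i <- i[1L]
    ex <- g$exons[[i]]
    o <- order(start(ex))
    L <- genomeLength(mg)
    s <- as.character(genomeSeq(mg))
    pieces <- vapply(o, function(k)
        .extractInterval(s, start(ex)[k], end(ex)[k], L), "")
    cds <- paste(pieces, collapse = "")
    if (g$strand[i] == "-") cds <- revcompChar(cds)
    if (g$class[i] %in% c("core_pcg", "free_orf", "intronic_orf") &&
        nchar(cds) %% 3L != 0L)
        warning("CDS of '", gene, "' has length ", nchar(cds),
                ", not divisible by 3")
    cds
}
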