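#' The 15 core protein-coding genes conserved across Basidiomycota
#' mitogenomes, plus helpers for gene-symbol normalization and translation
#' under the mold mitochondrial genetic code (NCBI table 4, TGA = Trp).
#' @name genetics
#' @keywords internal
NULL

#' @rdname genetics
#' @format \code{CORE_PCGS}: character vector of 15 gene symbols.
#' @export
CORE_PCGS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
               "rps3")

#' @rdname genetics
#' @format \code{RRNA_GENES}: the two mitochondrial rRNA gene symbols.
#' @export
RRNA_GENES <- c("rnl", "rns")

#' Gene symbols of the 17-gene comparison set (15 core PCGs + 2 rRNAs)
#' @rdname genetics
#' @export
ORDER_GENE_SET <- c(CORE_PCGS, RRNA_GENES)

# synonym -> canonical symbol; keys lowercase
.GENE_SYNONYMS <- c(
    cytb = "cob", cob = "cob", "cob-1" = "cob",
    coxi = "cox1", co1 = "cox1", coi = "cox1",
    coxii = "cox2", co2 = "cox2", coii = "cox2",
    coxiii = "cox3", co3 = "cox3", coiii = "cox3",
    rrnl = "rnl", rrn26 = "rnl", lsu = "rnl", "rrn-l" = "rnl", rnl = "rnl",
    rrns = "rns", rrn16 = "rns", ssu = "rns", "rrn-s" = "rns", rns = "rns",
    nad4l = "nad4L", ndh4l = "nad4L",
    atpase6 = "atp6", atpase8 = "atp8", atpase9 = "atp9"
)

#' Normalize a gene symbol
#'
#' Maps common synonyms (e.g. \code{cytb}, \code{rrnL}) to the canonical
#' symbols used throughout the package so that records from different
#' annotation pipelines are comparable.  Unknown symbols pass through
#' unchanged (lowercased, except the canonical \code{nad4L}).
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @examples
#' normalizeGeneSymbol(c("CYTB", "rrnL", "orf153"))
#' @export
normalizeGeneSymbol <- function(x) {
    lx <- tolower(x)
    hit <- .GENE_SYNONYMS[lx]
    canon <- c(CORE_PCGS, RRNA_GENES)
    ci <- match(lx, tolower(canon))
    out <- ifelse(!is.na(hit), hit,
                  ifelse(!is.na(ci), canon[ci], x))
    unname(out)
}

.code4 <- function() {
    Biostrings::getGeneticCode("4")
}

#' Translate a coding sequence under genetic code 4
#'
#' Translation under the Mold, Protozoan and Coelenterate Mitochondrial Code
#' (NCBI translation table 4), in which TGA encodes tryptophan.  A terminal
#' stop codon is stripped; internal stops are retained as \code{"*"} with a
#' warning.
#'
#' @param cds a \link[Biostrings]{DNAString} or character string; length must
#'   be divisible by 3.
#' @return a single character string (amino acids).
#' @examples
#' translateCode4("ATGTGAGCT")  # "MWA": internal TGA is Trp
#' @export
translateCode4 <- function(cds) {
    if (is(cds, "DNAString")) cds <- as.character(cds)
    cds <- toupper(cds)
    if (nchar(cds) == 0L) return("")
    if (nchar(cds) %% 3L != 0L)
        stop("CDS length (", nchar(cds), ") is not divisible by 3")
    aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), genetic.code = .code4(),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
    n <- nchar(aa)
    if (substr(aa, n, n) == "*")
        aa <- substr(aa, 1L, n - 1L)
    if (grepl("*", aa, fixed = TRUE))
        warning("internal stop codon(s) retained as '*'")
    aa
}

#' Reverse complement of a DNA character string
#' @param x character string over A/C/G/T/N.
#' @return reverse-complemented character string.
#' @keywords internal
revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @keywords internal
complementChar <- function(x) {
    as.character(Biostrings::complement(Biostrings::DNAString(x)))
}

#' @keywords internal
reverseChar <- function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}
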