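# Fixture builders shared across test files.  All fixtures are built in
# code at test time; nothing binary is stored.

suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
})

# a hand-built annotation: explicit genes/introns on a given sequence
makeAnnotation <- function(seq, genes = list(), introns = NULL,
                           id = "fix", species = id, circular = TRUE) {
    gt <- if (length(genes)) DataFrame(
        gene = vapply(genes, `[[`, "", "gene"),
        class = vapply(genes, `[[`, "", "class"),
        strand = vapply(genes, `[[`, "", "strand"),
        product = vapply(genes, function(g)
            if (is.null(g$product)) "" else g$product, ""),
        host_intron = vapply(genes, function(g)
            if (is.null(g$host_intron)) NA_integer_ else g$host_intron, 1L),
        exons = IRangesList(lapply(genes, function(g)
            IRanges(start = g$starts, end = g$ends)))
    ) else NULL
    it <- if (!is.null(introns)) DataFrame(
        host = introns$host, ordinal = as.integer(introns$ordinal),
        start = as.integer(introns$start), end = as.integer(introns$end),
        strand = introns$strand, group = introns$group
    ) else NULL
    args <- list(id = id, seq = seq, species = species, circular = circular)
    if (!is.null(gt)) args$genes <- gt
    if (!is.null(it)) args$introns <- it
    do.call(Mitogenome, args)
}

# small fast synthetic spec: 4-gene complement so whole genomes stay small
smallSpec <- function(seed, genomeLength = 9000L, ...) {
    mitogenomeSpec(seed = seed, genomeLength = genomeLength,
                   geneOrder = c("+cox1", "+cob", "-rnl", "+rns"),
                   tRNACount = 2L, ...)
}

# random uppercase DNA string (test-side, independent of the generator)
randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
}

# mirror-image of an annotation: reverse-complement the genome and remap
# every feature; used as the reflection oracle for gene orders
reflectAnnotation <- function(mg) {
    L <- genomeLength(mg)
    seq2 <- .oRevcomp(as.character(genomeSeq(mg)))
    g <- mitoGenes(mg)
    genes2 <- lapply(seq_len(nrow(g)), function(i) {
        ex <- g$exons[[i]]
        list(gene = g$gene[i], class = g$class[i],
             strand = if (g$strand[i] == "+") "-" else "+",
             product = g$product[i],
             starts = sort(L - end(ex) + 1L),
             ends = sort(L - start(ex) + 1L))
    })
    it <- mitoIntrons(mg)
    introns2 <- if (nrow(it)) data.frame(
        host = it$host, ordinal = it$ordinal,
        start = L - it$end + 1L, end = L - it$start + 1L,
        strand = ifelse(it$strand == "+", "-", "+"), group = it$group
    ) else NULL
    makeAnnotation(seq2, genes2, introns2, id = mg@id,
                   species = speciesName(mg))
}

BLOSUM62m <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})
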