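#' Base composition of a DNA sequence
#'
#' Counts A, C, G, T and N and reports GC percent computed over the
#' unambiguous bases only: \code{100 * (G + C) / (A + C + G + T)}.
#'
#' @param seq a \link[Biostrings]{DNAString}, \linkS4class{Mitogenome} or
#'   character string.
#' @return named list: \code{counts} (named integer vector A/C/G/T/N),
#'   \code{gc_percent}, \code{at_percent}.
#' @examples
#' baseComposition("GGCC")$gc_percent  # 100
#' @export
baseComposition <- function(seq) {
    seq <- .asDNAString(seq)
    if (length(seq) == 0L) stop("empty sequence")
    af <- Biostrings::alphabetFrequency(seq)
    counts <- af[c("A", "C", "G", "T", "N")]
    denom <- sum(counts[c("A", "C", "G", "T")])
    gc <- if (denom > 0) 100 * sum(counts[c("G", "C")]) / denom else NA_real_
    list(counts = counts, gc_percent = gc, at_percent = 100 - gc)
}

.asDNAString <- function(seq) {
    if (is(seq, "Mitogenome")) return(genomeSeq(seq))
    if (is.character(seq)) return(Biostrings::DNAString(toupper(seq)))
    seq
}

#' Strand compositional skew
#'
#' AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C), computed on the
#' direct strand as deposited.  A zero denominator yields \code{NA} with the
#' corresponding \code{*_defined} flag set to \code{FALSE}.
#'
#' @inheritParams baseComposition
#' @return named list: \code{at_skew}, \code{gc_skew}, \code{at_defined},
#'   \code{gc_defined}.
#' @examples
#' strandSkew("AAT")$at_skew   # 1/3
#' strandSkew("GGGC")$gc_skew  # 0.5
#' @export
strandSkew <- function(seq) {
    seq <- .asDNAString(seq)
    af <- Biostrings::alphabetFrequency(seq)
    A <- af[["A"]]; T <- af[["T"]]; G <- af[["G"]]; C <- af[["C"]]
    at <- if (A + T > 0) (A - T) / (A + T) else NA_real_
    gc <- if (G + C > 0) (G - C) / (G + C) else NA_real_
    list(at_skew = at, gc_skew = gc,
         at_defined = (A + T) > 0, gc_defined = (G + C) > 0)
}

# wrap linearized intervals (end may exceed L) into 1..L pieces
.wrapRanges <- function(starts, ends, L) {
    if (!length(starts)) return(IRanges())
    out_s <- integer(0); out_e <- integer(0)
    for (k in seq_along(starts)) {
        s <- starts[k]; e <- ends[k]
        if (e <= L) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
        else { out_s <- c(out_s, s, 1L); out_e <- c(out_e, L, e - L) }
    }
    IRanges(start = out_s, end = out_e)
}

#' Partition the genome into coding / intronic / intergenic / RNA regions
#'
#' Every genomic position is assigned exactly one class with precedence
#' non-intronic protein-coding exon > RNA gene > intron > intergenic.
#' Intron-hosted ORFs count as intronic, so the coding class contains only
#' exons of core PCGs and free-standing ORFs.  tRNA and rRNA genes together
#' form the RNA class.
#'
#' @param mg a \linkS4class{Mitogenome}.
#' @param precedence character vector ordering the classes
#'   \code{c("coding","rna","intronic")} from highest to lowest priority.
#' @return a \code{RegionPartition}: list with \code{coding_bp},
#'   \code{intronic_bp}, \code{intergenic_bp}, \code{rna_bp} and
#'   \code{fractions} (named numeric summing to 1).
#' @export
regionPartition <- function(mg, precedence = c("coding", "rna", "intronic")) {
    stopifnot(is(mg, "Mitogenome"),
              setequal(precedence, c("coding", "rna", "intronic")))
    L <- genomeLength(mg)
    g <- mg@genes
    classRanges <- function(classes) {
        i <- which(g$class %in% classes)
        if (!length(i)) return(IRanges())
        ex <- unlist(g$exons[i])
        .wrapRanges(start(ex), end(ex), L)
    }
    raw <- list(
        coding = classRanges(c("core_pcg", "free_orf")),
        rna = classRanges(c("trna", "rrna")),
        intronic = .wrapRanges(mg@introns$start, mg@introns$end, L))
    if (sum(width(raw$coding)) > sum(width(reduce(raw$coding))))
        warning("overlapping non-intronic coding exons; union taken")
    taken <- IRanges()
    bp <- c(coding = 0L, rna = 0L, intronic = 0L)
    for (cl in precedence) {
        r <- IRanges::setdiff(reduce(raw[[cl]]), taken)
        bp[cl] <- sum(width(r))
        taken <- reduce(c(taken, r))
    }
    intergenic <- L - sum(bp)
    out <- list(coding_bp = unname(bp["coding"]),
                intronic_bp = unname(bp["intronic"]),
                intergenic_bp = intergenic,
                rna_bp = unname(bp["rna"]))
    out$fractions <- c(coding = out$coding_bp, intronic = out$intronic_bp,
                       intergenic = out$intergenic_bp, rna = out$rna_bp) / L
    class(out) <- "RegionPartition"
    out
}

#' Build a RegionPartition from already-known region sizes
#'
#' Convenience constructor for summary rows where the per-class base-pair
#' totals are given (e.g. a published supplementary table) rather than
#' recomputed from an annotation.
#'
#' @param coding_bp,intronic_bp,intergenic_bp,rna_bp region sizes in bp.
#' @return a \code{RegionPartition} (see \code{\link{regionPartition}}).
#' @export
regionPartitionFromBp <- function(coding_bp, intronic_bp, intergenic_bp,
                                  rna_bp) {
    L <- coding_bp + intronic_bp + intergenic_bp + rna_bp
    stopifnot(L > 0)
    out <- list(coding_bp = coding_bp, intronic_bp = intronic_bp,
                intergenic_bp = intergenic_bp, rna_bp = rna_bp,
                fractions = c(coding = coding_bp, intronic = intronic_bp,
                              intergenic = intergenic_bp, rna = rna_bp) / L)
    class(out) <- "RegionPartition"
    out
}

#' @export
print.RegionPartition <- function(x, ...) {
    cat("RegionPartition\n")
    f <- x$fractions
    bp <- c(x$coding_bp, x$intronic_bp, x$intergenic_bp, x$rna_bp)
    for (i in seq_along(f))
        cat(sprintf("  %-10s %10d bp  %6.2f%%\n", names(f)[i], bp[i],
                    100 * f[i]))
    invisible(x)
}

.ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
    c("T", "C", "A", "G"), paste0), c("T", "C", "A", "G"), paste0))

#' Codon usage over the protein-coding genes
#'
#' Tallies codons over the extracted coding sequences.  By default only
#' non-intronic PCGs (core PCGs and free-standing ORFs) are included;
#' \code{include = "all_pcgs"} adds intron-hosted ORFs.  CDSs whose length is
#' not divisible by 3 are skipped with a warning.
#'
#' @param mg a \linkS4class{Mitogenome}.
#' @param include \code{"non_intronic_pcgs"} (default) or \code{"all_pcgs"}.
#' @return data.frame with columns \code{codon}, \code{aa} (genetic code 4),
#'   \code{count}, \code{freq}, sorted by decreasing count.
#' @export
codonUsage <- function(mg, include = c("non_intronic_pcgs", "all_pcgs")) {
    include <- match.arg(include)
    classes <- c("core_pcg", "free_orf")
    if (include == "all_pcgs") classes <- c(classes, "intronic_orf")
    g <- mg@genes
    idx <- which(g$class %in% classes)
    counts <- integer(64); names(counts) <- .ALL_CODONS
    used <- 0L
    for (i in idx) {
        cds <- suppressWarnings(extractCDS(mg, g$gene[i]))
        if (nchar(cds) %% 3L != 0L) {
            warning("skipping '", g$gene[i], "': length not divisible by 3")
            next
        }
        cd <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
        cd <- cd[!grepl("N", cd, fixed = TRUE)]
        tb <- table(cd)
        counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
        used <- used + 1L
    }
    if (used == 0L || sum(counts) == 0L)
        stop("no eligible CDS for codon usage in record '", mg@id, "'")
    gc4 <- .code4()
    data.frame(codon = names(counts),
               aa = unname(gc4[names(counts)]),
               count = unname(counts),
               freq = unname(counts) / sum(counts),
               stringsAsFactors = FALSE)[order(-counts), ]
}
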