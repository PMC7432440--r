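#' Signed circular gene order of the 17-gene comparison set
#'
#' Extracts the order of the 15 core PCGs plus the two rRNA genes
#' (\code{rnl}, \code{rns}) around the circle, ordered by first exon start,
#' and canonicalizes it: the order is rotated so \code{cox1} comes first,
#' and if \code{cox1} lies on the minus strand the whole order is reflected
#' and all signs flipped so \code{cox1} is forward.  tRNA genes are
#' excluded.  Genes absent from the record are listed in
#' \code{attr(, "missing")}.
#'
#' @param mg a \linkS4class{Mitogenome}.
#' @return character vector of signed symbols (e.g. \code{"+cox1"},
#'   \code{"-nad4"}), class \code{"GeneOrder"}, with attributes
#'   \code{species} and \code{missing}.
#' @export
extractGeneOrder <- function(mg) {
    g <- mg@genes
    idx <- which(g$gene %in% ORDER_GENE_SET &
                 g$class %in% c("core_pcg", "rrna"))
    # one entry per gene symbol (first occurrence)
    idx <- idx[!duplicated(g$gene[idx])]
    present <- g$gene[idx]
    if (!("cox1" %in% present))
        stop("cox1 absent from record '", mg@species,
             "'; cannot canonicalize gene order")
    firstStart <- vapply(idx, function(i) min(start(g$exons[[i]])), 1L)
    o <- order(firstStart)
    syms <- present[o]
    signs <- g$strand[idx][o]
    order_ <- paste0(ifelse(signs == "-", "-", "+"), syms)
    order_ <- canonicalizeOrder(order_)
    attr(order_, "species") <- mg@species
    attr(order_, "missing") <- setdiff(ORDER_GENE_SET, present)
    class(order_) <- "GeneOrder"
    order_
}

#' Canonicalize a signed circular gene order
#'
#' Rotates the circular order so \code{cox1} is first; if \code{cox1} is
#' negative, reflects the order (reverse the sequence and flip every sign)
#' before rotating.  Idempotent, and invariant under rotation and
#' whole-genome reflection of the input.
#'
#' @param order_ character vector of signed symbols (\code{"+x"} /
#'   \code{"-x"}).
#' @return canonicalized character vector.
#' @export
canonicalizeOrder <- function(order_) {
    attrs <- attributes(order_)
    order_ <- as.character(order_)
    syms <- substring(order_, 2L)
    i <- match("cox1", syms)
    if (is.na(i)) stop("cox1 absent; cannot canonicalize")
    if (substring(order_[i], 1L, 1L) == "-") {
        order_ <- rev(.flipSigns(order_))
        syms <- substring(order_, 2L)
        i <- match("cox1", syms)
    }
    out <- order_[c(seq(i, length(order_)),
                    if (i > 1L) seq_len(i - 1L) else integer(0))]
    attributes(out) <- attrs
    out
}

.flipSigns <- function(order_) {
    sgn <- substring(order_, 1L, 1L)
    paste0(ifelse(sgn == "-", "+", "-"), substring(order_, 2L))
}

# unordered signed circular adjacencies; adjacency (x, y) == (-y, -x)
.adjacencySet <- function(order_) {
    order_ <- as.character(order_)
    n <- length(order_)
    if (n < 2L) return(character(0))
    nxt <- c(order_[-1L], order_[1L])
    vapply(seq_len(n), function(k) {
        a <- order_[k]; b <- nxt[k]
        alt_a <- .flipSigns(b); alt_b <- .flipSigns(a)
        fwd <- paste(a, b); rev_ <- paste(alt_a, alt_b)
        if (fwd <= rev_) fwd else rev_
    }, "")
}

#' Breakpoint comparison of two canonical gene orders
#'
#' Restricted to the intersection of the two gene sets (missing genes are
#' dropped pairwise), counts shared signed circular adjacencies and
#' breakpoints (adjacencies of \code{a} absent from \code{b}).  An
#' adjacency is an unordered signed pair: \code{(x, y)} is the same
#' adjacency as \code{(-y, -x)}.  Symmetric on equal gene sets.
#'
#' @param a,b \code{GeneOrder} vectors (see \code{\link{extractGeneOrder}}).
#' @param signed compare strand-aware (default) or ignore signs.
#' @return list: \code{shared_adjacencies}, \code{breakpoints},
#'   \code{n_adjacencies}, \code{identical}.
#' @export
breakpointDistance <- function(a, b, signed = TRUE) {
    a <- as.character(a); b <- as.character(b)
    shared <- intersect(substring(a, 2L), substring(b, 2L))
    if (length(shared) < 3L)
        stop("fewer than 3 shared genes; comparison refused")
    a <- a[substring(a, 2L) %in% shared]
    b <- b[substring(b, 2L) %in% shared]
    if (!signed) {
        a <- paste0("+", substring(a, 2L))
        b <- paste0("+", substring(b, 2L))
    }
    adjA <- .adjacencySet(a)
    adjB <- .adjacencySet(b)
    sharedAdj <- sum(adjA %in% adjB)
    bp <- length(adjA) - sharedAdj
    list(shared_adjacencies = sharedAdj, breakpoints = bp,
         n_adjacencies = length(adjA), identical = (bp == 0L))
}

#' Group species by identical canonical gene order
#'
#' @param orders a list of \code{GeneOrder} vectors (named by species, or
#'   carrying a \code{species} attribute).
#' @return data.frame: \code{species}, \code{group} (integer id),
#'   \code{order} (comma-joined signed symbols), \code{unique} (logical,
#'   singleton group).
#' @export
orderGroup <- function(orders) {
    stopifnot(length(orders) >= 1L)
    sp <- names(orders)
    if (is.null(sp))
        sp <- vapply(orders, function(o) {
            s <- attr(o, "species"); if (is.null(s)) NA_character_ else s
        }, "")
    key <- vapply(orders, function(o)
        paste(as.character(canonicalizeOrder(o)), collapse = ","), "")
    grp <- match(key, unique(key))
    counts <- table(grp)
    data.frame(species = sp, group = grp, order = key,
               unique = as.vector(counts[as.character(grp)] == 1L),
               stringsAsFactors = FALSE)
}
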