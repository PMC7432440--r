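# Independent oracles used to cross-check the package implementations.
# These are deliberately written from first principles (plain loops /
# rle over diagonals / textbook DP), not by calling the code under test.

.oRevcomp <- function(x) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(x, "")[[1L]]]), collapse = "")
}
.oComp <- function(x) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(map[strsplit(x, "")[[1L]]], collapse = "")
}
.oRev <- function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = "")

# all maximal exact matches >= k between s and t by explicit diagonal
# scan: for every alignment offset, run-length encode the equality vector
oracleMatchesST <- function(s, t, k, skipDiagonal = FALSE) {
    sv <- strsplit(s, "")[[1L]]; tv <- strsplit(t, "")[[1L]]
    ns <- length(sv); nt <- length(tv)
    out <- NULL
    for (d in (-(nt - 1L)):(ns - 1L)) {
        i0 <- max(1L, 1L + d); j0 <- i0 - d
        len <- min(ns - i0, nt - j0) + 1L
        if (len < k) next
        if (skipDiagonal && d == 0L) next
        eq <- sv[i0:(i0 + len - 1L)] == tv[j0:(j0 + len - 1L)]
        r <- rle(eq)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (q in which(r$values & r$lengths >= k)) {
            out <- rbind(out, data.frame(i = i0 + starts[q] - 1L,
                                         j = j0 + starts[q] - 1L,
                                         len = r$lengths[q]))
        }
    }
    out
}

# brute-force maximal exact repeats in genome coordinates, same hit schema
# as findExactRepeats()
oracleExactRepeats <- function(s, minLen,
                               kinds = c("forward", "reverse",
                                         "complement", "palindromic")) {
    n <- nchar(s)
    res <- NULL
    for (kind in kinds) {
        t <- switch(kind, forward = s, reverse = .oRev(s),
                    complement = .oComp(s), palindromic = .oRevcomp(s))
        mm <- oracleMatchesST(s, t, minLen,
                              skipDiagonal = (kind == "forward"))
        if (is.null(mm)) next
        a_s <- mm$i; a_e <- mm$i + mm$len - 1L
        if (kind %in% c("reverse", "palindromic")) {
            b_e <- n - mm$j + 1L; b_s <- b_e - mm$len + 1L
        } else {
            b_s <- mm$j; b_e <- mm$j + mm$len - 1L
        }
        swap <- (b_s < a_s) | (b_s == a_s & b_e < a_e)
        tmp1 <- a_s[swap]; tmp2 <- a_e[swap]
        a_s[swap] <- b_s[swap]; a_e[swap] <- b_e[swap]
        b_s[swap] <- tmp1; b_e[swap] <- tmp2
        keep <- !(a_s == b_s & a_e == b_e)
        if (any(keep))
            res <- rbind(res, unique(data.frame(
                orientation = kind, a_start = a_s[keep], a_end = a_e[keep],
                b_start = b_s[keep], b_end = b_e[keep])))
    }
    if (is.null(res)) return(res)
    unique(res[order(res$orientation, res$a_start, res$b_start), ])
}

# textbook Gotoh global alignment score with affine gaps:
# a gap of length L costs open + L * ext
oracleGlobalScore <- function(a, b, subMat, open = 10, ext = 1) {
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    n <- length(av); m <- length(bv)
    NEG <- -1e9
    M <- matrix(NEG, n + 1L, m + 1L)
    X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (a aligned to gap)
    Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a
    M[1L, 1L] <- 0
    for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + ext * i)
    for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + ext * j)
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            sc <- subMat[av[i], bv[j]]
            M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + sc
            X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                     X[i, j + 1L] - ext)
            Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                     Y[i + 1L, j] - ext)
        }
    }
    max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# brute-force signed circular breakpoint count: adjacency (x, y) of order
# a is present in b iff y directly follows x in b, or -x directly follows
# -y (reading the same circle from the other strand)
oracleBreakpoints <- function(a, b) {
    shared <- intersect(substring(a, 2L), substring(b, 2L))
    a <- a[substring(a, 2L) %in% shared]
    b <- b[substring(b, 2L) %in% shared]
    flip <- function(x) {
        sg <- substring(x, 1L, 1L)
        paste0(ifelse(sg == "-", "+", "-"), substring(x, 2L))
    }
    n <- length(a)
    follows <- function(ord, x, y) {
        nn <- length(ord)
        for (k in seq_len(nn))
            if (ord[k] == x && ord[k %% nn + 1L] == y) return(TRUE)
        FALSE
    }
    bp <- 0L
    for (k in seq_len(n)) {
        x <- a[k]; y <- a[k %% n + 1L]
        if (!(follows(b, x, y) || follows(b, flip(y), flip(x))))
            bp <- bp + 1L
    }
    bp
}

# random signed circular permutation of the 17-gene set
randomSignedOrder <- function() {
    syms <- sample(mitocompare::ORDER_GENE_SET)
    sgn <- sample(c("+", "-"), length(syms), replace = TRUE)
    paste0(sgn, syms)
}

# independent code-4 codon table: the standard code with TGA -> W
oracleCode4Translate <- function(cds) {
    std <- Biostrings::GENETIC_CODE
    tab <- std; tab[["TGA"]] <- "W"
    n <- nchar(cds)
    cod <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(tab[cod])
    if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste(aa, collapse = "")
}
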