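#' Repeat detection
#'
#' Detectors for the three repeat evidence classes used in mitogenome
#' comparison: maximal exact repeats in four orientation classes
#' (forward / reverse / complement / palindromic), interspersed repeats by
#' seed-and-extend self-alignment with Karlin-Altschul E-values, and tandem
#' repeats (arrays of two or more adjacent motif copies).
#'
#' All coordinates are 1-based inclusive; on circular genomes hits may carry
#' linearized end coordinates (end > genome length) when they span the
#' origin.
#' @name repeats
NULL

# ungapped Karlin-Altschul parameters for match +1 / mismatch -2 on uniform
# base composition: lambda solves 0.25*e^lambda + 0.75*e^(-2*lambda) = 1
.KA <- local({
    lambda <- stats::uniroot(function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1,
                             c(0.1, 3), tol = 1e-12)$root
    list(lambda = lambda, K = 0.621, match = 1L, mismatch = -2L,
         gap_open = 5L, gap_extend = 2L)
})

#' Scoring and E-value configuration for the local-alignment engine
#' @return list with \code{match}, \code{mismatch}, \code{gap_open},
#'   \code{gap_extend}, \code{lambda}, \code{K}.
#' @export
repeatScoringConfig <- function() {
    list(match = .KA$match, mismatch = .KA$mismatch,
         gap_open = .KA$gap_open, gap_extend = .KA$gap_extend,
         lambda = .KA$lambda, K = .KA$K)
}

.seqToInt <- function(x) utf8ToInt(x)

# Shannon entropy (bits) of base composition of a word
.wordEntropy <- function(word) {
    f <- table(strsplit(word, "", fixed = TRUE)[[1L]])
    p <- f / sum(f)
    -sum(p * log2(p))
}

# 0..3 encoding of A/C/G/T; anything else (N) becomes NA
.baseCode <- local({
    code <- rep(NA_integer_, 256L)
    code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
    code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
    code
})

# integer k-mer key per window (base-4 rolling value); NA where the
# window contains a non-ACGT character
.kmerKeys <- function(sv, k) {
    v <- .baseCode[sv]
    n <- length(v)
    np <- n - k + 1L
    if (np < 1L) return(numeric(0))
    key <- numeric(np)
    for (j in seq_len(k))
        key <- key * 4 + v[j:(j + np - 1L)]
    key
}

# per-window base-composition entropy (bits), vectorized via cumsums
.windowEntropy <- function(sv, k) {
    n <- length(sv)
    np <- n - k + 1L
    H <- numeric(np)
    for (b in c("A", "C", "G", "T")) {
        cs0 <- c(0, cumsum(sv == utf8ToInt(b)))
        cnt <- cs0[seq_len(np) + k] - cs0[seq_len(np)]
        p <- cnt / k
        term <- ifelse(p > 0, -p * log2(p), 0)
        H <- H + term
    }
    H
}

# seed-pair index: for each valid position i in s, the positions in t
# sharing its k-mer; returns list(sIdx, jsOf) where jsOf[[m]] are the t
# positions for sIdx[m]
.seedPairs <- function(sv, tv, k, lowComplexityFilter, entropyMin = 1.0) {
    ks <- .kmerKeys(sv, k)
    kt <- .kmerKeys(tv, k)
    okS <- !is.na(ks); okT <- !is.na(kt)
    if (lowComplexityFilter) {
        okS <- okS & .windowEntropy(sv, k) >= entropyMin
        okT <- okT & .windowEntropy(tv, k) >= entropyMin
    }
    tpos <- split(which(okT), kt[okT])
    m <- match(ks, as.numeric(names(tpos)))
    m[!okS] <- NA_integer_
    sIdx <- which(!is.na(m))
    list(sIdx = sIdx, listIdx = m[sIdx], tpos = tpos)
}

.emptyRepeatHits <- function() {
    data.frame(orientation = character(0),
               a_start = integer(0), a_end = integer(0),
               b_start = integer(0), b_end = integer(0),
               length = integer(0), identity = numeric(0),
               score = numeric(0), evalue = numeric(0),
               stringsAsFactors = FALSE)
}

# all maximal exact matches of length >= k between strings s and t,
# returned as (i, j, len) in s/t coordinates; diagonal-run method
.maximalMatchesST <- function(s, t, k, skipDiagonal = FALSE,
                              lowComplexityFilter = FALSE, entropyMin = 1.0) {
    sv <- .seqToInt(s); tv <- .seqToInt(t)
    ns <- length(sv); nt <- length(tv)
    if (ns < k || nt < k)
        return(data.frame(i = integer(0), j = integer(0), len = integer(0)))
    sp <- .seedPairs(sv, tv, k, lowComplexityFilter, entropyMin)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out_i <- integer(0); out_j <- integer(0); out_l <- integer(0)
    for (m in seq_along(sp$sIdx)) {
        i <- sp$sIdx[m]
        js <- sp$tpos[[sp$listIdx[m]]]
        for (j in js) {
            if (skipDiagonal && i == j) next
            # seed interior to an already-extended match on this diagonal?
            dkey <- paste0("d", i - j)
            prev <- get0(dkey, envir = seen)
            if (!is.null(prev) && i >= prev[1L] && i + k - 1L <= prev[2L]) next
            a <- i; b <- j
            while (a > 1L && b > 1L && sv[a - 1L] == tv[b - 1L]) {
                a <- a - 1L; b <- b - 1L
            }
            e1 <- i + k - 1L; e2 <- j + k - 1L
            while (e1 < ns && e2 < nt && sv[e1 + 1L] == tv[e2 + 1L]) {
                e1 <- e1 + 1L; e2 <- e2 + 1L
            }
            assign(dkey, c(a, e1), envir = seen)
            key <- paste(a, b, e1 - a + 1L)
            if (is.null(get0(key, envir = seen))) {
                assign(key, TRUE, envir = seen)
                out_i <- c(out_i, a); out_j <- c(out_j, b)
                out_l <- c(out_l, e1 - a + 1L)
            }
        }
    }
    data.frame(i = out_i, j = out_j, len = out_l)
}

#' Maximal exact repeats in four orientation classes
#'
#' Finds all maximal exact matches of length at least \code{minLen} between
#' the genome and itself under each orientation transform: \emph{forward}
#' (s vs s, off-diagonal), \emph{reverse} (s vs reverse(s)),
#' \emph{complement} (s vs complement(s)) and \emph{palindromic}
#' (s vs reverse-complement(s)).  Maximality means the match cannot be
#' extended in either direction.  Each symmetric pair is reported once,
#' with \code{interval_a} the lexicographically smaller member.
#'
#' @param genome a \linkS4class{Mitogenome}, \code{DNAString} or character.
#' @param minLen minimum repeat length (default 8).
#' @param kinds subset of
#'   \code{c("forward","reverse","complement","palindromic")}.
#' @param lowComplexityFilter drop seeds whose base-composition entropy is
#'   below 1 bit (off by default for exact repeats).
#' @return data.frame of hits: \code{orientation}, \code{a_start},
#'   \code{a_end}, \code{b_start}, \code{b_end}, \code{length},
#'   \code{identity} (always 100), \code{score}, \code{evalue} (\code{NA}).
#' @export
findExactRepeats <- function(genome, minLen = 8L,
                             kinds = c("forward", "reverse", "complement",
                                       "palindromic"),
                             lowComplexityFilter = FALSE) {
    stopifnot(minLen >= 2L)
    kinds <- match.arg(kinds, several.ok = TRUE)
    s <- as.character(.asDNAString(genome))
    n <- nchar(s)
    res <- list()
    for (kind in kinds) {
        t <- switch(kind,
            forward = s,
            reverse = reverseChar(s),
            complement = complementChar(s),
            palindromic = revcompChar(s))
        mm <- .maximalMatchesST(s, t, minLen,
                                skipDiagonal = (kind == "forward"),
                                lowComplexityFilter = lowComplexityFilter)
        if (!nrow(mm)) next
        a_s <- mm$i; a_e <- mm$i + mm$len - 1L
        if (kind %in% c("reverse", "palindromic")) {
            b_e <- n - mm$j + 1L
            b_s <- b_e - mm$len + 1L
        } else {
            b_s <- mm$j; b_e <- mm$j + mm$len - 1L
        }
        # canonical member order; symmetric duplicates collapse
        swap <- (b_s < a_s) | (b_s == a_s & b_e < a_e)
        tmp_s <- a_s[swap]; tmp_e <- a_e[swap]
        a_s[swap] <- b_s[swap]; a_e[swap] <- b_e[swap]
        b_s[swap] <- tmp_s; b_e[swap] <- tmp_e
        keep <- !(a_s == b_s & a_e == b_e)
        if (!any(keep)) next
        df <- unique(data.frame(orientation = kind,
            a_start = a_s[keep], a_end = a_e[keep],
            b_start = b_s[keep], b_end = b_e[keep],
            length = (a_e - a_s + 1L)[keep],
            identity = 100, score = as.numeric((a_e - a_s + 1L)[keep]),
            evalue = NA_real_, stringsAsFactors = FALSE))
        res[[kind]] <- df
    }
    if (!length(res)) return(.emptyRepeatHits())
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out[order(-out$score, out$a_start, out$b_start), ]
}

# gapless X-drop seed-and-extend local alignments between s and t.
# Returns hits in s/t coordinates with score, identity.
.seedExtend <- function(s, t, word, xdrop = 20L, skipDiagonal = FALSE,
                        lowComplexityFilter = TRUE) {
    sv <- .seqToInt(s); tv <- .seqToInt(t)
    ns <- length(sv); nt <- length(tv)
    if (ns < word || nt < word)
        return(data.frame(a_start = integer(0), a_end = integer(0),
                          b_start = integer(0), b_end = integer(0),
                          score = numeric(0), identity = numeric(0)))
    sp <- .seedPairs(sv, tv, word, lowComplexityFilter)
    M <- .KA$match; X <- .KA$mismatch
    done <- new.env(hash = TRUE, parent = emptyenv())
    rows <- list()
    for (m in seq_along(sp$sIdx)) {
        i <- sp$sIdx[m]
        js <- sp$tpos[[sp$listIdx[m]]]
        for (j in js) {
            if (skipDiagonal && i == j) next
            dkey <- paste0("d", i - j)
            prev <- get0(dkey, envir = done)
            if (!is.null(prev) && i >= prev[1L] && i <= prev[2L]) next
            # right extension with X-drop from end of seed
            score <- word * M; best <- score
            e1 <- i + word - 1L; e2 <- j + word - 1L
            be1 <- e1
            p1 <- e1; p2 <- e2
            while (p1 < ns && p2 < nt) {
                p1 <- p1 + 1L; p2 <- p2 + 1L
                score <- score + if (sv[p1] == tv[p2]) M else X
                if (score > best) { best <- score; be1 <- p1 }
                if (best - score > xdrop) break
            }
            # left extension
            score <- best
            a <- i; b <- j; ba <- a
            p1 <- a; p2 <- b
            while (p1 > 1L && p2 > 1L) {
                p1 <- p1 - 1L; p2 <- p2 - 1L
                score <- score + if (sv[p1] == tv[p2]) M else X
                if (score > best) { best <- score; ba <- p1 }
                if (best - score > xdrop) break
            }
            a_start <- ba; a_end <- be1
            b_start <- j - (i - ba); b_end <- (j + word - 1L) + (be1 - e1)
            assign(dkey, c(a_start, a_end), envir = done)
            len <- a_end - a_start + 1L
            nm <- sum(sv[a_start:a_end] == tv[b_start:b_end])
            key <- paste(a_start, b_start, len)
            if (is.null(get0(key, envir = done))) {
                assign(key, TRUE, envir = done)
                rows[[length(rows) + 1L]] <- c(a_start, a_end, b_start, b_end,
                                               best, 100 * nm / len)
            }
        }
    }
    if (!length(rows))
        return(data.frame(a_start = integer(0), a_end = integer(0),
                          b_start = integer(0), b_end = integer(0),
                          score = numeric(0), identity = numeric(0)))
    m <- do.call(rbind, rows)
    data.frame(a_start = m[, 1L], a_end = m[, 2L], b_start = m[, 3L],
               b_end = m[, 4L], score = m[, 5L], identity = m[, 6L])
}

.evalue <- function(score, m, n) {
    .KA$K * as.numeric(m) * as.numeric(n) * exp(-.KA$lambda * score)
}

#' Interspersed repeats by self-comparison
#'
#' Seed-and-extend local alignment (gapless X-drop extension, match +1 /
#' mismatch -2) of the genome against itself and against its reverse
#' complement.  The trivial main diagonal is masked, mirror-duplicate hits
#' collapsed, and hits kept when their Karlin-Altschul E-value is below
#' \code{evalueMax}.  On circular genomes the sequence is extended by
#' \code{word - 1} wrap-around characters so origin-spanning repeats seed
#' once.
#'
#' @param genome a \linkS4class{Mitogenome}, \code{DNAString} or character.
#' @param word seed word size (default 11, minimum 8).
#' @param evalueMax E-value threshold (default 1e-10).
#' @param lowComplexityFilter drop low-entropy seed words (default TRUE;
#'   AT-rich mitogenomes otherwise drown in homopolymer seeds).
#' @return data.frame as in \code{\link{findExactRepeats}}, with
#'   \code{orientation} either \code{"forward"} (direct strand) or
#'   \code{"palindromic"} (reverse-complement strand), sorted by score.
#' @export
findInterspersedRepeats <- function(genome, word = 11L, evalueMax = 1e-10,
                                    lowComplexityFilter = TRUE) {
    stopifnot(word >= 8L)
    circular <- if (is(genome, "Mitogenome")) genome@circular else FALSE
    s <- as.character(.asDNAString(genome))
    n <- nchar(s)
    if (n < word) return(.emptyRepeatHits())
    sx <- if (circular && n > word)
        paste0(s, substr(s, 1L, word - 1L)) else s

    collect <- function(hits, orientation, mapB) {
        if (!nrow(hits)) return(NULL)
        b <- mapB(hits$b_start, hits$b_end)
        df <- data.frame(orientation = orientation,
            a_start = hits$a_start, a_end = hits$a_end,
            b_start = b$start, b_end = b$end,
            length = hits$a_end - hits$a_start + 1L,
            identity = hits$identity, score = hits$score,
            evalue = .evalue(hits$score, n, n),
            stringsAsFactors = FALSE)
        swap <- (df$b_start < df$a_start)
        if (any(swap)) {
            tmp <- df[swap, c("a_start", "a_end")]
            df[swap, c("a_start", "a_end")] <-
                df[swap, c("b_start", "b_end")]
            df[swap, c("b_start", "b_end")] <- tmp
        }
        df[!(df$a_start == df$b_start & df$a_end == df$b_end), ]
    }
    fw <- collect(.seedExtend(sx, sx, word, skipDiagonal = TRUE,
                              lowComplexityFilter = lowComplexityFilter),
                  "forward", function(s1, e1) list(start = s1, end = e1))
    nx <- nchar(sx)
    rc <- collect(.seedExtend(sx, revcompChar(sx), word,
                              lowComplexityFilter = lowComplexityFilter),
                  "palindromic",
                  function(s1, e1) list(start = nx - e1 + 1L,
                                        end = nx - s1 + 1L))
    out <- rbind(fw, rc)
    if (is.null(out) || !nrow(out)) return(.emptyRepeatHits())
    out <- unique(out)
    out <- out[out$evalue < evalueMax, , drop = FALSE]
    rownames(out) <- NULL
    out[order(-out$score, out$a_start), ]
}

#' Aligned fragments shared by the mitochondrial and nuclear genomes
#'
#' Applies the same seed-and-extend local-alignment engine as
#' \code{\link{findInterspersedRepeats}} across genomes (both strands of the
#' nuclear sequence) to locate candidate mitochondrial-to-nuclear transfer
#' fragments, and annotates each fragment with the mitochondrial features
#' (genes and introns) its mitochondrial interval overlaps.
#'
#' @param mito a \linkS4class{Mitogenome} (or plain sequence).
#' @param nuclear nuclear sequence (\code{DNAString} or character).
#' @param evalueMax E-value threshold (default 1e-10).
#' @param word seed word size (default 11).
#' @return data.frame: \code{mito_start}, \code{mito_end},
#'   \code{nuclear_start}, \code{nuclear_end}, \code{strand},
#'   \code{length}, \code{identity}, \code{score}, \code{evalue},
#'   \code{overlapped_features} (comma-joined gene symbols).
#' @export
findTransferFragments <- function(mito, nuclear, evalueMax = 1e-10,
                                  word = 11L) {
    s <- as.character(.asDNAString(mito))
    t <- as.character(.asDNAString(nuclear))
    m <- nchar(s); n <- nchar(t)
    if (m == 0L || n == 0L) stop("both sequences must be non-empty")
    one <- function(tt, strand, mapB) {
        h <- .seedExtend(s, tt, word, lowComplexityFilter = TRUE)
        if (!nrow(h)) return(NULL)
        b <- mapB(h$b_start, h$b_end)
        data.frame(mito_start = h$a_start, mito_end = h$a_end,
                   nuclear_start = b$start, nuclear_end = b$end,
                   strand = strand,
                   length = h$a_end - h$a_start + 1L,
                   identity = h$identity, score = h$score,
                   evalue = .evalue(h$score, m, n),
                   stringsAsFactors = FALSE)
    }
    out <- rbind(
        one(t, "+", function(s1, e1) list(start = s1, end = e1)),
        one(revcompChar(t), "-",
            function(s1, e1) list(start = n - e1 + 1L, end = n - s1 + 1L)))
    if (is.null(out) || !nrow(out)) out <- data.frame(
        mito_start = integer(0), mito_end = integer(0),
        nuclear_start = integer(0), nuclear_end = integer(0),
        strand = character(0), length = integer(0), identity = numeric(0),
        score = numeric(0), evalue = numeric(0), stringsAsFactors = FALSE)
    out <- unique(out[out$evalue < evalueMax, , drop = FALSE])
    out$overlapped_features <- rep("", nrow(out))
    if (nrow(out) && is(mito, "Mitogenome")) {
        L <- genomeLength(mito)
        g <- mito@genes
        feats <- character(0); fr <- IRanges()
        for (i in seq_len(nrow(g))) {
            ex <- g$exons[[i]]
            wr <- .wrapRanges(start(ex), end(ex), L)
            fr <- c(fr, wr); feats <- c(feats, rep(g$gene[i], length(wr)))
        }
        it <- mito@introns
        if (nrow(it)) {
            wr <- .wrapRanges(it$start, it$end, L)
            # count wrapped pieces per intron to label each piece
            npiece <- ifelse(it$end > L, 2L, 1L)
            fr <- c(fr, wr)
            feats <- c(feats, rep(paste0(it$host, ".i", it$ordinal), npiece))
        }
        for (k in seq_len(nrow(out))) {
            q <- .wrapRanges(out$mito_start[k], out$mito_end[k], L)
            ov <- unique(feats[IRanges::overlapsAny(fr, q)])
            out$overlapped_features[k] <- paste(ov, collapse = ",")
        }
    }
    rownames(out) <- NULL
    out[order(-out$score, out$mito_start), ]
}

#' Genome fraction covered by repeat hits
#'
#' Takes the union of all hit intervals (both members of each pair), counts
#' every covered position once, and reports coverage in bp and as a percent
#' of genome length.  Sums of hit lengths would double-count overlapping
#' families; the union reproduces a well-defined percentage.
#'
#' @param hits data.frame from \code{\link{findExactRepeats}} or
#'   \code{\link{findInterspersedRepeats}} (columns \code{a_start},
#'   \code{a_end}, \code{b_start}, \code{b_end}).
#' @param genomeLength genome length in bp.
#' @return list: \code{covered_bp}, \code{percent}.
#' @examples
#' h <- data.frame(a_start = c(1, 201), a_end = c(100, 300),
#'                 b_start = c(501, 701), b_end = c(600, 800))
#' repeatCoverage(h, 10000)  # 400 bp, 4%
#' @export
repeatCoverage <- function(hits, genomeLength) {
    if (!nrow(hits)) return(list(covered_bp = 0L, percent = 0))
    r <- .wrapRanges(c(hits$a_start, hits$b_start),
                     c(hits$a_end, hits$b_end), genomeLength)
    covered <- sum(width(reduce(r)))
    list(covered_bp = covered, percent = 100 * covered / genomeLength)
}
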