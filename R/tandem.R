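#' Tandem repeats
#'
#' Detects arrays of two or more adjacent copies of a period-\code{p} motif.
#' For each candidate period the genome is compared against itself shifted
#' by \code{p}; maximal runs with at least \code{motifIdentity} agreement
#' (exact matches merged across short mismatch gaps while the overall
#' identity stays above the threshold) define arrays of total length
#' run + period.  Overlapping calls with different periods are reduced to
#' the highest-scoring period (score = 2*matches - mismatches; ties prefer
#' the shorter period, then the earlier start).  Copy number is reported to
#' 0.1 resolution.
#'
#' @param genome a \linkS4class{Mitogenome}, \code{DNAString} or character.
#' @param minTotal minimum total array length in bp (default 11, i.e.
#'   arrays longer than 10 bp).
#' @param maxPeriod maximum motif length considered (default 500).
#' @param motifIdentity minimum fraction of matching positions within an
#'   array (default 0.8).
#' @return data.frame: \code{start}, \code{end}, \code{period},
#'   \code{copies}, \code{total_length}, \code{consensus}, \code{score}.
#' @examples
#' findTandemRepeats("ACACACACACAC")  # period 2, 6 copies
#' @export
findTandemRepeats <- function(genome, minTotal = 11L, maxPeriod = 500L,
                              motifIdentity = 0.8) {
    s <- as.character(.asDNAString(genome))
    n <- nchar(s)
    sv <- .seqToInt(s)
    cs <- integer(0); ce <- integer(0); cp <- integer(0)
    ct <- integer(0); csc <- numeric(0)
    for (p in seq_len(min(maxPeriod, n %/% 2L))) {
        eq <- sv[seq_len(n - p)] == sv[seq_len(n - p) + p]
        runs <- .identityRuns(eq, motifIdentity)
        if (!nrow(runs)) next
        total <- (runs$end - runs$start + 1L) + p
        ok <- total >= minTotal & total >= 2L * p
        if (!any(ok)) next
        mism <- (runs$end - runs$start + 1L) - runs$matches
        cs <- c(cs, runs$start[ok])
        ce <- c(ce, runs$start[ok] + total[ok] - 1L)
        cp <- c(cp, rep(p, sum(ok)))
        ct <- c(ct, total[ok])
        csc <- c(csc, (2 * runs$matches - mism)[ok])
    }
    if (!length(cs))
        return(data.frame(start = integer(0), end = integer(0),
                          period = integer(0), copies = numeric(0),
                          total_length = integer(0), consensus = character(0),
                          score = numeric(0), stringsAsFactors = FALSE))
    df <- data.frame(start = cs, end = ce, period = cp,
                     copies = round(ct / cp, 1L), total_length = ct,
                     score = csc)
    df <- df[order(-df$score, df$period, df$start), ]
    # suppress lower-scoring calls overlapping an accepted array
    covered <- logical(n)
    keep <- logical(nrow(df))
    for (k in seq_len(nrow(df))) {
        if (!any(covered[df$start[k]:df$end[k]])) {
            keep[k] <- TRUE
            covered[df$start[k]:df$end[k]] <- TRUE
        }
    }
    df <- df[keep, , drop = FALSE]
    df$consensus <- vapply(seq_len(nrow(df)), function(k) {
        .tandemConsensus(s, df$start[k], df$period[k], df$total_length[k])
    }, "")
    rownames(df) <- NULL
    df[order(df$start), c("start", "end", "period", "copies",
                          "total_length", "consensus", "score")]
}

# maximal runs of TRUE in eq, merged across mismatch gaps only when the
# weaker flanking run outweighs the gap (match +2 / mismatch -7, the
# usual tandem-finder weighting) and the overall identity stays >= thr
.identityRuns <- function(eq, thr) {
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ti <- which(r$values)
    if (!length(ti))
        return(data.frame(start = integer(0), end = integer(0),
                          matches = integer(0)))
    nr <- length(ti)
    out_s <- integer(nr); out_e <- integer(nr); out_m <- integer(nr)
    nOut <- 0L
    k <- 1L
    while (k <= nr) {
        s0 <- starts[ti[k]]; e0 <- ends[ti[k]]; m0 <- r$lengths[ti[k]]
        while (k < nr) {
            nxt <- ti[k + 1L]
            gap <- starts[nxt] - e0 - 1L
            x <- r$lengths[nxt]
            m1 <- m0 + x
            len1 <- ends[nxt] - s0 + 1L
            if (2L * min(m0, x) - 7L * gap > 0L && m1 / len1 >= thr) {
                e0 <- ends[nxt]; m0 <- m1; k <- k + 1L
            } else break
        }
        nOut <- nOut + 1L
        out_s[nOut] <- s0; out_e[nOut] <- e0; out_m[nOut] <- m0
        k <- k + 1L
    }
    data.frame(start = out_s[seq_len(nOut)], end = out_e[seq_len(nOut)],
               matches = out_m[seq_len(nOut)])
}

# per-position majority over the complete copies of the array
.tandemConsensus <- function(s, start, period, total) {
    ncopies <- total %/% period
    mat <- matrix("", nrow = ncopies, ncol = period)
    for (c0 in seq_len(ncopies)) {
        off <- start + (c0 - 1L) * period
        mat[c0, ] <- strsplit(substr(s, off, off + period - 1L), "")[[1L]]
    }
    paste(apply(mat, 2L, function(col)
        names(sort(table(col), decreasing = TRUE))[1L]), collapse = "")
}
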