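# Exact, interspersed, tandem and transfer repeat detection

test_that("the worked forward example finds the single maximal pair", {
    h <- findExactRepeats("AATTCCCCAATT", minLen = 4, kinds = "forward")
    expect_equal(nrow(h), 1L)
    expect_equal(c(h$a_start, h$a_end, h$b_start, h$b_end),
                 c(1L, 4L, 9L, 12L))
    expect_equal(h$identity, 100)
})

test_that("exact repeats equal the brute-force oracle on random sequences", {
    set.seed(77)
    for (rep in 1:50) {
        n <- sample(60:300, 1)
        # two-letter stretches raise repeat density
        s <- if (rep %% 3 == 0) randomSeq(n, c("A", "T"))
             else randomSeq(n)
        minLen <- sample(6:10, 1)
        got <- findExactRepeats(s, minLen = minLen)
        got <- got[order(got$orientation, got$a_start, got$a_end,
                         got$b_start, got$b_end),
                   c("orientation", "a_start", "a_end", "b_start", "b_end")]
        rownames(got) <- NULL
        want <- oracleExactRepeats(s, minLen)
        if (is.null(want)) {
            expect_equal(nrow(got), 0L, info = paste("rep", rep))
        } else {
            want <- want[order(want$orientation, want$a_start, want$a_end,
                               want$b_start, want$b_end), ]
            rownames(want) <- NULL
            expect_equal(got, want, info = paste("rep", rep))
        }
    }
})

test_that("the low-complexity filter suppresses homopolymer forward hits", {
    s <- paste0(strrep("A", 60), randomSeq(100))
    noisy <- findExactRepeats(s, minLen = 10, kinds = "forward")
    expect_gt(nrow(noisy), 0L)
    clean <- findExactRepeats(s, minLen = 10, kinds = "forward",
                              lowComplexityFilter = TRUE)
    expect_lt(nrow(clean), nrow(noisy))
})

test_that("a planted exact duplication is recovered at 100% identity", {
    set.seed(101)
    s <- randomSeq(1000)
    seg <- substr(s, 101, 180)
    s <- paste0(substr(s, 1, 600), seg, substr(s, 681, 1000))
    h <- findInterspersedRepeats(s, evalueMax = 1e-10)
    exact <- h[h$identity == 100 & h$length >= 80, ]
    expect_gte(nrow(exact), 1L)
    expect_true(any(exact$a_start <= 101 & exact$a_end >= 180 &
                    exact$b_start <= 601 & exact$b_end >= 680))
})

test_that("random sequence yields no interspersed hits at E < 1e-10", {
    set.seed(102)
    clean <- 0L
    for (rep in 1:100) {
        s <- randomSeq(1000)
        h <- findInterspersedRepeats(s, evalueMax = 1e-10)
        if (nrow(h) == 0L) clean <- clean + 1L
    }
    expect_gte(clean, 99L)
})

test_that("a duplication with 10% mutations is recovered near 90% identity", {
    set.seed(103)
    hitIds <- numeric(0)
    for (rep in 1:10) {
        s <- randomSeq(1000)
        seg <- substr(s, 101, 200)
        ch <- strsplit(seg, "")[[1L]]
        pos <- sample(100, 10)
        for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
        s <- paste0(substr(s, 1, 600), paste(ch, collapse = ""),
                    substr(s, 701, 1000))
        h <- findInterspersedRepeats(s, evalueMax = 1e-6)
        h <- h[h$a_start <= 110 & h$b_start >= 560, ]
        expect_gte(nrow(h), 1L)
        hitIds <- c(hitIds, h$identity[1L])
    }
    expect_true(all(hitIds >= 85 & hitIds <= 95))
    expect_true(mean(hitIds) > 88 && mean(hitIds) < 92)
})

test_that("every repeat pair is reported once, in canonical member order", {
    set.seed(104)
    res <- generateMitogenome(smallSpec(104,
        repeatPlan = data.frame(kind = "forward", length = 90, copies = 3,
                                identity = 95)))
    h <- findInterspersedRepeats(res$annotation)
    expect_true(all(h$a_start <= h$b_start))
    key <- paste(h$a_start, h$a_end, h$b_start, h$b_end)
    expect_false(any(duplicated(key)))
})

test_that("tandem arrays report period, copies and threshold edges", {
    td <- findTandemRepeats("ACACACACACAC")
    expect_equal(nrow(td), 1L)
    expect_equal(td$period, 2L)
    expect_equal(td$copies, 6.0)
    expect_equal(td$total_length, 12L)
    expect_equal(td$consensus, "AC")
    # 9 bp total is at or below the >10 bp cutoff
    expect_equal(nrow(findTandemRepeats("ACGACGACG")), 0L)
})

test_that("planted tandem arrays are recovered with exact period and copies", {
    for (sd in 1:20) {
        res <- generateMitogenome(smallSpec(600 + sd,
            repeatPlan = data.frame(kind = "tandem", length = 7,
                                    copies = 5, identity = 100)))
        tt <- res$truth$tandems
        td <- findTandemRepeats(res$annotation, maxPeriod = 30)
        hit <- td[td$start == tt$start & td$end == tt$end, ]
        expect_equal(nrow(hit), 1L, info = paste("seed", sd))
        expect_equal(hit$period, tt$period, info = paste("seed", sd))
        expect_equal(hit$copies, 5.0, info = paste("seed", sd))
    }
})

test_that("transfer fragments recover planted segments with feature overlap", {
    res <- generateMitogenome(smallSpec(700))
    mg <- res$annotation
    spec <- smallSpec(700, transferPlan = list(
        n = 3, length_range = c(300, 600), identity = 95,
        nuclearLength = 40000))
    nt <- generateNuclearWithTransfer(mg, spec)
    expect_equal(nrow(nt$truth), 3L)
    h <- findTransferFragments(mg, nt$nuclear)
    expect_equal(nrow(h), 3L)
    expect_true(all(h$identity >= 93 & h$identity <= 97))
    for (k in seq_len(3)) {
        expect_true(any(h$mito_start <= nt$truth$mito_start[k] + 15 &
                        h$mito_end >= nt$truth$mito_end[k] - 15))
    }
})

test_that("identical sequences give one full-length 100% fragment", {
    set.seed(106)
    s <- randomSeq(800)
    h <- findTransferFragments(s, s)
    expect_equal(nrow(h), 1L)
    expect_equal(c(h$mito_start, h$mito_end), c(1L, 800L))
    expect_equal(h$identity, 100)
})

test_that("unrelated random sequences give zero fragments at 1e-10", {
    set.seed(107)
    for (rep in 1:5) {
        h <- findTransferFragments(randomSeq(2000), randomSeq(2000))
        expect_equal(nrow(h), 0L)
    }
})

test_that("a fragment overlapping an annotated gene names it", {
    res <- generateMitogenome(smallSpec(108))
    mg <- res$annotation
    g <- mitoGenes(mg)
    i <- which(g$gene == "trnA")
    ex <- g$exons[[i]]
    s <- as.character(genomeSeq(mg))
    set.seed(108)
    nuc <- paste0(randomSeq(5000),
                  substr(s, start(ex) - 60, end(ex) + 60),
                  randomSeq(5000))
    h <- findTransferFragments(mg, nuc)
    expect_gte(nrow(h), 1L)
    expect_true(any(grepl("trnA", h$overlapped_features)))
})

test_that("repeat coverage is the union of hit intervals", {
    h <- data.frame(a_start = c(1, 201), a_end = c(100, 300),
                    b_start = c(501, 701), b_end = c(600, 800))
    cov <- repeatCoverage(h, 10000)
    expect_equal(cov$covered_bp, 400L)
    expect_equal(cov$percent, 4)

    # nested and overlapping hits are not double counted
    set.seed(109)
    for (rep in 1:20) {
        n <- 40L
        hs <- data.frame(a_start = sample(500, n), b_start = sample(500, n))
        hs$a_end <- hs$a_start + sample(5:80, n, replace = TRUE)
        hs$b_end <- hs$b_start + sample(5:80, n, replace = TRUE)
        cov2 <- repeatCoverage(hs, 600)
        mask <- logical(600)
        for (k in seq_len(n)) {
            mask[hs$a_start[k]:min(600, hs$a_end[k])] <- TRUE
            mask[hs$b_start[k]:min(600, hs$b_end[k])] <- TRUE
        }
        # intervals running past the end wrap around the circle
        wrapA <- hs$a_end[hs$a_end > 600] - 600
        wrapB <- hs$b_end[hs$b_end > 600] - 600
        for (w in c(wrapA, wrapB)) mask[1:w] <- TRUE
        expect_equal(cov2$covered_bp, sum(mask))
        expect_lte(cov2$covered_bp, 600L)
    }
})

test_that("scoring configuration exposes the Karlin-Altschul parameters", {
    cfg <- repeatScoringConfig()
    expect_equal(cfg$match, 1L)
    expect_equal(cfg$mismatch, -2L)
    # lambda solves 0.25 e^l + 0.75 e^(-2l) = 1
    expect_equal(0.25 * exp(cfg$lambda) + 0.75 * exp(-2 * cfg$lambda), 1,
                 tolerance = 1e-8)
})
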