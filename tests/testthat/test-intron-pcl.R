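# Protein alignment, intron insertion points, Pcl projection and matrix

test_that("identical sequences align gaplessly with the diagonal score", {
    p <- "MKVLANDWQ"
    al <- alignProteinGlobal(p, p)
    expect_equal(al$aligned_query, p)
    expect_equal(al$aligned_reference, p)
    ch <- strsplit(p, "")[[1L]]
    expect_equal(al$score, sum(BLOSUM62m[cbind(ch, ch)]))
})

test_that("MKV vs MV aligns with a single deletion column", {
    al <- alignProteinGlobal("MKV", "MV")
    expect_equal(nchar(al$aligned_query), 3L)
    expect_equal(al$aligned_query, "MKV")
    expect_equal(sum(strsplit(al$aligned_reference, "")[[1L]] == "-"), 1L)
})

test_that("alignment scores equal an independent Gotoh DP oracle", {
    set.seed(55)
    aas <- rownames(BLOSUM62m)[1:20]
    for (rep in 1:6) {
        a <- paste(sample(aas, 100, replace = TRUE), collapse = "")
        b <- paste(sample(aas, sample(80:120, 1), replace = TRUE),
                   collapse = "")
        al <- alignProteinGlobal(a, b)
        expect_equal(al$score, oracleGlobalScore(a, b, BLOSUM62m))
    }
})

test_that("non-amino-acid characters are rejected", {
    expect_error(alignProteinGlobal("MK1", "MK"), "non-amino-acid")
})

test_that("insertion offsets count coding nucleotides before each intron", {
    set.seed(56)
    s <- randomSeq(2000)
    # exon CDS lengths 120 and 300 with one intron between
    mg <- makeAnnotation(s, list(
        list(gene = "cox1", class = "core_pcg", strand = "+",
             starts = c(101L, 621L), ends = c(220L, 920L))),
        introns = data.frame(host = "cox1", ordinal = 1L, start = 221L,
                             end = 620L, strand = "+", group = "I"))
    pts <- intronInsertionPoints(mg)
    expect_equal(pts$cds_nt_offset, 120L)

    # minus strand: transcription runs right to left
    mgR <- makeAnnotation(s, list(
        list(gene = "cox1", class = "core_pcg", strand = "-",
             starts = c(101L, 621L), ends = c(220L, 920L))),
        introns = data.frame(host = "cox1", ordinal = 1L, start = 221L,
                             end = 620L, strand = "-", group = "I"))
    ptsR <- intronInsertionPoints(mgR)
    expect_equal(ptsR$cds_nt_offset, 300L)   # downstream exon comes first
})

test_that("multi-intron offsets are strictly increasing", {
    res <- generateMitogenome(smallSpec(57, genomeLength = 12000L,
        intronPlan = data.frame(host = "cox1",
                                ref_position = c(200, 800, 1300),
                                length = c(500, 400, 600),
                                with_orf = FALSE)))
    pts <- intronInsertionPoints(res$annotation)
    expect_equal(pts$cds_nt_offset, c(200L, 800L, 1300L))
    expect_true(all(diff(pts$cds_nt_offset) > 0))
})

test_that("projection reproduces printed labels when query == reference", {
    refProt <- translateCode4(referenceCox1CDS())
    for (case in list(list(off = 383, label = "P383", phase = 2),
                      list(off = 1107, label = "P1107", phase = 0),
                      list(off = 1281, label = "P1281", phase = 0))) {
        pr <- projectToReference(case$off, refProt, refProt)
        expect_equal(pr$label, case$label)
        expect_equal(pr$phase, case$phase)
        expect_true(pr$exact)
    }
    pr <- projectToReference(383, refProt, refProt)
    expect_equal(pr$label_phased, "P383+2")
})

test_that("an N-terminal query extension does not shift the label", {
    refProt <- translateCode4(referenceCox1CDS())
    qProt <- paste0("MSTAPQRKLV", refProt)
    pr <- projectToReference(30 + 383, qProt, refProt)
    expect_equal(pr$label, "P383")
    expect_equal(pr$phase, 2L %% 3L)
})

test_that("phase suffix always agrees with position mod 3", {
    refProt <- translateCode4(referenceCox1CDS())
    set.seed(58)
    for (off in sample(seq_len(1580), 30)) {
        pr <- projectToReference(off, refProt, refProt)
        expect_equal(pr$ref_nt_position, off)
        expect_equal(pr$phase, off %% 3L)
        if (off %% 3L == 0L) expect_equal(pr$label_phased, pr$label)
        else expect_equal(pr$label_phased,
                          paste0(pr$label, "+", off %% 3L))
    }
})

test_that("the Pcl matrix merges labels and applies the strict >n/5 rule", {
    base <- mitogenomeSpec(seed = 61, genomeLength = 40000,
        geneOrder = c("+cox1", "+cob", "+nad5", "-rnl", "+rns"),
        tRNACount = 4,
        intronPlan = data.frame(host = c("cox1", "cox1"),
                                ref_position = c(383, 1107),
                                length = c(1000, 900),
                                with_orf = c(TRUE, FALSE)))
    cl <- generateClade(10, base, intronGainLoss = 0, rearrangementRate = 0,
                        divergence = 0.05,
                        intronMembership = list("383" = 1:7,
                                                "1107" = c(3, 8)))
    anns <- lapply(cl, `[[`, "annotation")
    pm <- buildPclMatrix(anns, referenceCox1CDS())
    expect_equal(ncol(pm$presence), 2L)
    expect_equal(unname(pm$prevalence[c("P383", "P1107")]), c(7L, 2L))
    # 7 > 10/5 -> common; 2 <= 2 -> rare under the strict rule
    expect_equal(unname(pm$class[c("P383", "P1107")]), c("common", "rare"))
    expect_equal(unname(colSums(pm$presence)), unname(pm$prevalence))
    expect_equal(sum(pm$class == "common") + sum(pm$class == "rare"),
                 ncol(pm$presence))
})

test_that("species without cox1 or without introns give all-false rows", {
    res1 <- generateMitogenome(smallSpec(62))     # no introns
    anns <- list(res1$annotation)
    pmWarn <- NULL
    mgNoCox <- makeAnnotation(randomSeq(500), list(
        list(gene = "cob", class = "core_pcg", strand = "+",
             starts = 1L, ends = 300L)), id = "nocox")
    expect_warning(pmWarn <- buildPclMatrix(c(anns, list(mgNoCox)),
                                            referenceCox1CDS()),
                   "lacks cox1")
    expect_equal(ncol(pmWarn$presence), 0L)
    expect_equal(nrow(pmWarn$presence), 2L)
})

test_that("a Pcl carried by one species is rare once n reaches 6", {
    base <- mitogenomeSpec(seed = 63, genomeLength = 30000,
        geneOrder = c("+cox1", "+cob", "-rnl", "+rns"), tRNACount = 2,
        intronPlan = data.frame(host = "cox1", ref_position = 383,
                                length = 900, with_orf = FALSE))
    cl <- generateClade(6, base, intronGainLoss = 0, rearrangementRate = 0,
                        divergence = 0,
                        intronMembership = list("383" = 1L))
    pm <- buildPclMatrix(lapply(cl, `[[`, "annotation"), referenceCox1CDS())
    expect_equal(unname(pm$prevalence[["P383"]]), 1L)
    expect_true(all(pm$class == "rare"))   # 1 > 6/5 is false
})

test_that("labels survive 30% substitution divergence without indels", {
    set.seed(64)
    refCds <- referenceCox1CDS()
    refProt <- translateCode4(refCds)
    n <- nchar(refProt)
    aas <- setdiff(rownames(BLOSUM62m)[1:20], "*")
    recovered <- 0L; total <- 0L
    for (rep in 1:20) {
        ch <- strsplit(refProt, "")[[1L]]
        pos <- sample(n, round(0.3 * n))
        for (p in pos) ch[p] <- sample(setdiff(aas, ch[p]), 1)
        qProt <- paste(ch, collapse = "")
        for (off in sample(seq_len(3 * n - 1), 10)) {
            pr <- projectToReference(off, qProt, refProt)
            total <- total + 1L
            if (pr$label == paste0("P", off)) recovered <- recovered + 1L
        }
    }
    expect_equal(recovered, total)
})

test_that("labels survive indels away from the insertion site", {
    set.seed(65)
    refProt <- translateCode4(referenceCox1CDS())
    n <- nchar(refProt)
    aas <- rownames(BLOSUM62m)[1:20]
    recovered <- 0L; total <- 0L
    while (total < 200L) {
        refCodon <- sample(20:(n - 20), 1)
        phase <- sample(0:2, 1)
        off <- 3 * (refCodon - 1) + if (phase > 0) phase else 3
        # indels restricted to > 5 codons away from the insertion codon
        ch <- strsplit(refProt, "")[[1L]]
        sub <- sample(n, round(0.1 * n))
        for (p in sub) ch[p] <- sample(setdiff(aas, ch[p]), 1)
        nIndel <- sample(1:3, 1)
        qOff <- off
        for (k in seq_len(nIndel)) {
            at <- sample(setdiff(5:(length(ch) - 5),
                                 (refCodon - 6):(refCodon + 6)), 1)
            if (runif(1) < 0.5) {            # insertion of 1-3 residues
                ins <- sample(aas, sample(1:3, 1), replace = TRUE)
                ch <- append(ch, ins, after = at)
                if (at < refCodon) {
                    refCodon <- refCodon + length(ins)
                    qOff <- qOff + 3 * length(ins)
                }
            } else {                         # deletion of 1-2 residues
                del <- at:(at + sample(0:1, 1))
                ch <- ch[-del]
                if (max(del) < refCodon) {
                    refCodon <- refCodon - length(del)
                    qOff <- qOff - 3 * length(del)
                }
            }
        }
        qProt <- paste(ch, collapse = "")
        pr <- projectToReference(qOff, qProt, refProt)
        total <- total + 1L
        if (pr$label == paste0("P", off)) recovered <- recovered + 1L
    }
    expect_gte(recovered / total, 0.95)
})

test_that("pearson correlation behaves on linear and degenerate input", {
    rec <- data.frame(size = c(30000, 60000, 90000, 120000),
                      introns = c(1, 3, 5, 7))
    expect_equal(pearsonSizeIntron(rec), 1.0)
    recC <- data.frame(size = c(1, 2, 3), introns = c(4, 4, 4))
    expect_warning(r <- pearsonSizeIntron(recC), "zero variance")
    expect_true(is.na(r))
    expect_error(pearsonSizeIntron(rec[1:2, ]), "at least 3")
})
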