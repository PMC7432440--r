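# GenBank parsing/writing, CDS extraction and code-4 translation

writeGbText <- function(lines, seq, path, length = nchar(seq),
                        circular = TRUE) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf(
        "LOCUS       testrec          %d bp    DNA     %s   UNA 01-JAN-2026",
        length, if (circular) "circular" else "linear"), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(lines, con)
    if (!is.null(seq)) {
        writeLines("ORIGIN", con)
        pos <- seq(1L, nchar(seq), by = 60L)
        for (p in pos)
            writeLines(sprintf("%9d %s", p,
                tolower(substr(seq, p, min(p + 59L, nchar(seq))))), con)
    }
    writeLines("//", con)
}

test_that("a CDS with a join() location becomes a two-exon gene", {
    set.seed(1)
    s <- randomSeq(90)
    f <- withr::local_tempfile(fileext = ".gb")
    writeGbText(c("     CDS             join(1..30,61..90)",
                  "                     /gene=\"cox1\"",
                  "     intron          31..60",
                  "                     /gene=\"cox1\"",
                  "                     /number=1"), s, f)
    mg <- readGenBank(f)
    g <- mitoGenes(mg)
    expect_equal(nrow(g), 1L)
    expect_equal(g$gene, "cox1")
    expect_equal(g$class, "core_pcg")
    ex <- g$exons[[1L]]
    expect_equal(width(ex), c(30L, 30L))
    expect_equal(start(ex), c(1L, 61L))
    it <- mitoIntrons(mg)
    expect_equal(nrow(it), 1L)
    expect_equal(c(it$start, it$end), c(31L, 60L))
})

test_that("complement() locations give minus-strand single-exon genes", {
    set.seed(2)
    s <- randomSeq(100)
    f <- withr::local_tempfile(fileext = ".gb")
    writeGbText(c("     CDS             complement(10..60)",
                  "                     /gene=\"nad3\""), s, f)
    mg <- readGenBank(f)
    g <- mitoGenes(mg)
    expect_equal(g$strand, "-")
    expect_equal(start(g$exons[[1L]]), 10L)
    expect_equal(end(g$exons[[1L]]), 60L)
})

test_that("origin-spanning joins are linearized on read and re-wrapped on write", {
    set.seed(3)
    s <- randomSeq(120)
    f <- withr::local_tempfile(fileext = ".gb")
    writeGbText(c("     CDS             join(100..120,1..30)",
                  "                     /gene=\"atp9\""), s, f)
    mg <- readGenBank(f)
    ex <- mitoGenes(mg)$exons[[1L]]
    expect_equal(length(ex), 1L)
    expect_equal(start(ex), 100L)
    expect_equal(end(ex), 150L)          # linearized: 120 + 30
    f2 <- withr::local_tempfile(fileext = ".gb")
    writeGenBank(mg, f2)
    expect_true(any(grepl("join(100..120,1..30)", readLines(f2),
                          fixed = TRUE)))
    mg2 <- readGenBank(f2)
    expect_equal(as.data.frame(mitoGenes(mg2)$exons[[1L]]),
                 as.data.frame(ex))
})

test_that("a record without an ORIGIN block is a format error", {
    f <- withr::local_tempfile(fileext = ".gb")
    writeLines(c("LOCUS       x          10 bp    DNA   circular",
                 "FEATURES             Location/Qualifiers",
                 "     source          1..10", "//"), f)
    expect_error(readGenBank(f), "ORIGIN")
})

test_that("feature coordinates beyond the sequence are a validation error", {
    set.seed(4)
    s <- randomSeq(50)
    f <- withr::local_tempfile(fileext = ".gb")
    writeGbText(c("     CDS             90..120",
                  "                     /gene=\"cob\""), s, f)
    expect_error(readGenBank(f), "outside the sequence")
})

test_that("synthetic records round-trip losslessly through write + read", {
    for (sd in c(5, 21)) {
        res <- generateMitogenome(smallSpec(sd,
            intronPlan = data.frame(host = "cox1", ref_position = 383,
                                    length = 900, with_orf = TRUE)))
        mg <- res$annotation
        f <- withr::local_tempfile(fileext = ".gb")
        writeGenBank(mg, f)
        mg2 <- readGenBank(f)
        expect_equal(as.character(genomeSeq(mg2)), as.character(genomeSeq(mg)))
        expect_identical(as.data.frame(mitoGenes(mg2))[, 1:5],
                         as.data.frame(mitoGenes(mg))[, 1:5])
        expect_identical(lapply(mitoGenes(mg2)$exons, as.data.frame),
                         lapply(mitoGenes(mg)$exons, as.data.frame))
        expect_identical(as.data.frame(mitoIntrons(mg2)),
                         as.data.frame(mitoIntrons(mg)))
    }
})

test_that("an annotation without genes still writes and re-reads", {
    mg <- makeAnnotation(randomSeq(80), id = "bare")
    f <- withr::local_tempfile(fileext = ".gb")
    writeGenBank(mg, f)
    mg2 <- readGenBank(f)
    expect_equal(genomeLength(mg2), 80L)
    expect_equal(nrow(mitoGenes(mg2)), 0L)
})

test_that("extractCDS concatenates exons and honours strand", {
    s <- paste0("ATGAAATAG", randomSeq(91))
    mg <- makeAnnotation(s, list(
        list(gene = "atp9", class = "core_pcg", strand = "+",
             starts = 1L, ends = 9L)))
    expect_equal(extractCDS(mg, "atp9"), "ATGAAATAG")

    # two-exon gene: the intron is excluded
    mg2 <- makeAnnotation(s, list(
        list(gene = "cob", class = "core_pcg", strand = "+",
             starts = c(1L, 40L), ends = c(9L, 45L))),
        introns = data.frame(host = "cob", ordinal = 1L, start = 10L,
                             end = 39L, strand = "+", group = "I"))
    expect_equal(extractCDS(mg2, "cob"),
                 paste0(substr(s, 1, 9), substr(s, 40, 45)))

    # minus strand: reverse complement of the concatenated template
    mg3 <- makeAnnotation(s, list(
        list(gene = "nad1", class = "core_pcg", strand = "-",
             starts = c(11L, 31L), ends = c(19L, 36L))))
    expected <- .oRevcomp(paste0(substr(s, 11, 19), substr(s, 31, 36)))
    expect_equal(extractCDS(mg3, "nad1"), expected)

    expect_error(extractCDS(mg, "nosuch"), "not found")
})

test_that("extractCDS length equals the sum of exon widths", {
    res <- generateMitogenome(smallSpec(8,
        intronPlan = data.frame(host = "cox1", ref_position = c(200, 800),
                                length = c(500, 700),
                                with_orf = c(FALSE, FALSE))))
    mg <- res$annotation
    g <- mitoGenes(mg)
    for (i in which(g$class %in% c("core_pcg", "rrna"))) {
        cds <- suppressWarnings(extractCDS(mg, g$gene[i]))
        expect_equal(nchar(cds), sum(width(g$exons[[i]])),
                     info = g$gene[i])
    }
})

test_that("translation uses genetic code 4 (internal TGA is tryptophan)", {
    expect_equal(translateCode4("ATGTGAGCT"), "MWA")
    expect_equal(translateCode4(""), "")
    expect_error(translateCode4("ATGA"), "divisible by 3")
    # terminal stop is stripped
    expect_equal(translateCode4("ATGTAA"), "M")
    # internal stop retained with a warning
    expect_warning(out <- translateCode4("ATGTAAGCTTAA"), "internal stop")
    expect_equal(out, "M*A")
})

test_that("translation matches an independent table-4 lookup on random CDS", {
    set.seed(42)
    for (rep in 1:5) {
        cds <- paste0("ATG", randomSeq(294), "TAA")
        got <- suppressWarnings(translateCode4(cds))
        expect_equal(got, suppressWarnings(oracleCode4Translate(cds)))
    }
})

test_that("code 4 differs from the standard code only at TGA codons", {
    set.seed(9)
    cds <- paste(sample(names(Biostrings::GENETIC_CODE), 200, replace = TRUE),
                 collapse = "")
    aa4 <- strsplit(suppressWarnings(translateCode4(
        paste0(cds, "TAA"))), "")[[1L]]
    aaStd <- unname(Biostrings::GENETIC_CODE[
        substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))])
    diffs <- which(aa4 != aaStd)
    cods <- substring(cds, 3 * (diffs - 1) + 1, 3 * diffs)
    expect_true(all(cods == "TGA"))
    expect_true(all(aa4[diffs] == "W"))
})

test_that("gene symbols normalize through the synonym table", {
    expect_equal(normalizeGeneSymbol(c("CYTB", "rrnL", "NAD4l", "COX1")),
                 c("cob", "rnl", "nad4L", "cox1"))
    expect_equal(normalizeGeneSymbol("trnA"), "trnA")  # unknowns untouched
})
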