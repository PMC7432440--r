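#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses a GenBank flat-file record (LOCUS / FEATURES / ORIGIN) into a
#' \linkS4class{Mitogenome}.  Supported location forms are \code{x},
#' \code{x..y}, \code{join(...)}, \code{complement(...)} and
#' \code{complement(join(...))}; on circular records an origin-spanning
#' \code{join(x..L,1..y)} is normalized to the linearized virtual
#' coordinate \code{(x, L+y)}.
#'
#' Feature classes are assigned from the normalized gene symbol (the 15
#' core-PCG table), with CDS features contained in an annotated intron
#' classified \code{intronic_orf} and the rest \code{free_orf}.
#' Unparseable qualifiers are skipped with a message, never fatal.
#'
#' @param path path to a GenBank flat file containing one record.
#' @return a \linkS4class{Mitogenome}.
#' @seealso \code{\link{writeGenBank}}
#' @export
readGenBank <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^LOCUS", lines[1L]))
        stop("not a GenBank flat file (no LOCUS line): ", path)
    loc <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    id <- loc[2L]
    L <- suppressWarnings(as.integer(loc[3L]))
    circular <- any(tolower(loc) == "circular")

    org <- id
    oi <- grep("^  ORGANISM", lines)
    if (length(oi))
        org <- trimws(sub("^  ORGANISM", "", lines[oi[1L]]))

    fstart <- grep("^FEATURES", lines)
    ostart <- grep("^ORIGIN", lines)
    if (!length(ostart))
        stop("format error: record has no ORIGIN sequence block")
    seqlines <- lines[(ostart[1L] + 1L):length(lines)]
    seqlines <- seqlines[!grepl("^//", seqlines)]
    seqchr <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
    if (!nchar(seqchr))
        stop("format error: ORIGIN block contains no sequence")
    if (!is.na(L) && nchar(seqchr) != L)
        warning("LOCUS length (", L, ") differs from ORIGIN length (",
                nchar(seqchr), "); using ORIGIN")
    L <- nchar(seqchr)

    feats <- list()
    if (length(fstart)) {
        flines <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
        cur <- NULL
        for (ln in flines) {
            if (grepl("^     [^ ]", ln)) {           # new feature
                if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
                key <- trimws(substr(ln, 1L, 20L))
                cur <- list(key = key, loc = trimws(substr(ln, 21L, nchar(ln))),
                            quals = character(0))
            } else if (!is.null(cur)) {
                txt <- trimws(ln)
                if (startsWith(txt, "/")) {
                    cur$quals <- c(cur$quals, txt)
                } else if (length(cur$quals)) {      # continuation of qualifier
                    n <- length(cur$quals)
                    cur$quals[n] <- paste0(cur$quals[n], txt)
                } else {                             # continuation of location
                    cur$loc <- paste0(cur$loc, txt)
                }
            }
        }
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
    }

    q <- function(f, name) {
        pat <- paste0("^/", name, "=")
        hit <- grep(pat, f$quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        v <- sub(pat, "", hit[1L])
        gsub("\"", "", v)
    }

    genes <- list(); introns <- list()
    for (f in feats) {
        if (f$key %in% c("source", "gene", "misc_feature")) next
        pl <- tryCatch(.parseLocation(f$loc, L, circular),
                       error = function(e) {
            message("skipping feature ", f$key, " with unparseable location '",
                    f$loc, "': ", conditionMessage(e))
            NULL
        })
        if (is.null(pl)) next
        if (any(pl$ranges$start < 1L) || any(pl$ranges$end > 2L * L) ||
            any(pl$ranges$start > L))
            stop("validation error: feature ", f$key, " '", q(f, "gene"),
                 "' has coordinates outside the sequence")
        gname <- q(f, "gene")
        if (f$key == "intron") {
            introns[[length(introns) + 1L]] <- list(
                host = normalizeGeneSymbol(if (is.na(gname)) "unknown" else gname),
                ordinal = suppressWarnings(as.integer(q(f, "number"))),
                start = pl$ranges$start[1L],
                end = pl$ranges$end[nrow(pl$ranges)],
                strand = pl$strand,
                group = .intronGroupFromNote(q(f, "note")))
        } else if (f$key %in% c("CDS", "tRNA", "rRNA")) {
            if (is.na(gname)) gname <- q(f, "product")
            if (is.na(gname)) gname <- paste0("feat", length(genes) + 1L)
            genes[[length(genes) + 1L]] <- list(
                gene = normalizeGeneSymbol(gname),
                key = f$key,
                strand = pl$strand,
                product = ifelse(is.na(q(f, "product")), "", q(f, "product")),
                exons = pl$ranges)
        }
    }

    it <- if (length(introns)) {
        DataFrame(
            host = vapply(introns, `[[`, "", "host"),
            ordinal = vapply(introns, function(x)
                if (is.null(x$ordinal) || is.na(x$ordinal)) NA_integer_
                else x$ordinal, 1L),
            start = vapply(introns, `[[`, 1L, "start"),
            end = vapply(introns, `[[`, 1L, "end"),
            strand = vapply(introns, `[[`, "", "strand"),
            group = vapply(introns, `[[`, "", "group"))
    } else .emptyIntronTable()

    gt <- if (length(genes)) {
        cls <- character(length(genes)); host_intron <- rep(NA_integer_, length(genes))
        for (i in seq_along(genes)) {
            g <- genes[[i]]
            if (g$key == "tRNA") cls[i] <- "trna"
            else if (g$key == "rRNA") cls[i] <- "rrna"
            else if (g$gene %in% CORE_PCGS) cls[i] <- "core_pcg"
            else {
                s <- min(g$exons$start); e <- max(g$exons$end)
                hi <- which(it$start <= s & it$end >= e)
                if (length(hi)) {
                    cls[i] <- "intronic_orf"; host_intron[i] <- hi[1L]
                } else cls[i] <- "free_orf"
            }
        }
        DataFrame(
            gene = vapply(genes, `[[`, "", "gene"),
            class = cls,
            strand = vapply(genes, `[[`, "", "strand"),
            product = vapply(genes, `[[`, "", "product"),
            host_intron = host_intron,
            exons = IRangesList(lapply(genes, function(g)
                IRanges(start = g$exons$start, end = g$exons$end))))
    } else .emptyGeneTable()

    it <- .assignIntronOrdinals(it)
    Mitogenome(id = id, seq = seqchr, species = org, circular = circular,
               genes = gt, introns = it)
}

.intronGroupFromNote <- function(note) {
    if (is.na(note)) return("unknown")
    if (grepl("group[ _]?II", note, ignore.case = TRUE)) return("II")
    if (grepl("group[ _]?I", note, ignore.case = TRUE)) return("I")
    "unknown"
}

# fill missing ordinals: transcription order within host
.assignIntronOrdinals <- function(it) {
    if (!nrow(it) || !anyNA(it$ordinal)) return(it)
    for (h in unique(it$host)) {
        i <- which(it$host == h)
        if (!anyNA(it$ordinal[i])) next
        o <- order(it$start[i])
        if (it$strand[i][1L] == "-") o <- rev(o)
        it$ordinal[i[o]] <- seq_along(i)
    }
    it
}

# location string -> list(strand, ranges = data.frame(start, end))
.parseLocation <- function(loc, L, circular) {
    loc <- gsub("[<>[:space:]]", "", loc)
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("^join\\(", loc))
        loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
    se <- lapply(parts, function(p) {
        if (grepl("\\.\\.", p)) {
            ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
        } else ab <- rep(as.integer(p), 2L)
        if (anyNA(ab)) stop("bad location part: ", p)
        ab
    })
    rng <- data.frame(start = vapply(se, `[`, 1L, 1L),
                      end = vapply(se, `[`, 1L, 2L))
    # merge origin-spanning adjacent parts (… x..L, 1..y …)
    if (circular && nrow(rng) > 1L) {
        i <- 2L
        while (i <= nrow(rng)) {
            if (rng$start[i] == 1L && rng$end[i - 1L] == L) {
                rng$end[i - 1L] <- L + rng$end[i]
                rng <- rng[-i, , drop = FALSE]
            } else i <- i + 1L
        }
    }
    if (any(rng$end < rng$start)) stop("location has end < start")
    list(strand = strand, ranges = rng)
}

#' Write a Mitogenome as a GenBank flat file
#'
#' Emits a record re-readable by \code{\link{readGenBank}} with a lossless
#' feature round-trip.  The ORIGIN block is written 60 nt per line in 10-nt
#' groups; origin-spanning features are re-wrapped to
#' \code{join(x..L,1..y)} form.
#'
#' @param mg a \linkS4class{Mitogenome}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(mg, path) {
    stopifnot(is(mg, "Mitogenome"))
    L <- genomeLength(mg)
    con <- file(path, "w"); on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("LOCUS       %-16s %d bp    DNA     %s   UNA 01-JAN-2026",
      mg@id, L, if (mg@circular) "circular" else "linear")
    w("DEFINITION  %s mitochondrion.", mg@species)
    w("ACCESSION   %s", mg@id)
    w("SOURCE      %s", mg@species)
    w("  ORGANISM  %s", mg@species)
    w("FEATURES             Location/Qualifiers")
    w("     source          1..%d", L)
    w("                     /organism=\"%s\"", mg@species)

    feat <- function(key, locstr, quals) {
        w("     %-15s %s", key, locstr)
        for (qq in quals) w("                     %s", qq)
    }
    g <- mg@genes
    it <- mg@introns
    for (i in seq_len(nrow(g))) {
        ex <- g$exons[[i]]
        locstr <- .formatLocation(start(ex), end(ex), g$strand[i], L)
        key <- switch(g$class[i], trna = "tRNA", rrna = "rRNA", "CDS")
        quals <- sprintf("/gene=\"%s\"", g$gene[i])
        if (nzchar(g$product[i]))
            quals <- c(quals, sprintf("/product=\"%s\"", g$product[i]))
        if (g$class[i] == "intronic_orf")
            quals <- c(quals, "/note=\"intronic ORF\"")
        feat(key, locstr, quals)
    }
    for (i in seq_len(nrow(it))) {
        locstr <- .formatLocation(it$start[i], it$end[i], it$strand[i], L)
        feat("intron", locstr,
             c(sprintf("/gene=\"%s\"", it$host[i]),
               sprintf("/number=%d", it$ordinal[i]),
               sprintf("/note=\"group %s intron\"",
                       if (it$group[i] == "unknown") "?" else it$group[i])))
    }
    w("ORIGIN")
    s <- as.character(genomeSeq(mg))
    pos <- seq(1L, L, by = 60L)
    for (p in pos) {
        chunk <- substr(s, p, min(p + 59L, L))
        grp <- gsub("(.{10})", "\\1 ", tolower(chunk))
        w("%9d %s", p, trimws(grp))
    }
    w("//")
    invisible(path)
}

# intervals may be linearized (end > L): re-wrap for output
.formatLocation <- function(starts, ends, strand, L) {
    parts <- character(0)
    for (k in seq_along(starts)) {
        s <- starts[k]; e <- ends[k]
        if (e > L) {
            parts <- c(parts, sprintf("%d..%d", s, L),
                       sprintf("%d..%d", 1L, e - L))
        } else parts <- c(parts, sprintf("%d..%d", s, e))
    }
    locstr <- if (length(parts) > 1L)
        sprintf("join(%s)", paste(parts, collapse = ",")) else parts
    if (strand == "-") locstr <- sprintf("complement(%s)", locstr)
    locstr
}

#' Export the feature table as TSV
#'
#' Columns: species, gene, class, strand, exon_coords (1-based inclusive,
#' \code{start-end} joined by \code{;}), length (sum of exon widths).
#'
#' @param mg a \linkS4class{Mitogenome}.
#' @param path output TSV path.
#' @return the data.frame written, invisibly.
#' @export
writeFeatureTSV <- function(mg, path) {
    g <- mg@genes
    df <- data.frame(
        species = rep(mg@species, nrow(g)),
        gene = g$gene, class = g$class, strand = g$strand,
        exon_coords = vapply(seq_len(nrow(g)), function(i) {
            ex <- g$exons[[i]]
            paste(sprintf("%d-%d", start(ex), end(ex)), collapse = ";")
        }, ""),
        length = vapply(seq_len(nrow(g)), function(i)
            sum(width(g$exons[[i]])), 1L),
        stringsAsFactors = FALSE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines("# coordinates are 1-based inclusive", con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
        row.names = FALSE))
    invisible(df)
}

#' Read/write FASTA (wrapped at 60 columns)
#'
#' Thin wrappers over \link[Biostrings]{readDNAStringSet} and
#' \link[Biostrings]{writeXStringSet}.
#'
#' @param path file path.
#' @param x a named character vector or \code{XStringSet}.
#' @return \code{readFasta}: a \code{DNAStringSet}.
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname readFasta
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = 60L)
    invisible(path)
}
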