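#' Synthetic annotated mitogenomes with known planted structure
#'
#' The generator emulates the salient properties of Basidiomycota
#' mitogenomes: a circular AT-rich molecule, the 15 core PCGs plus two
#' rRNAs laid out in a chosen signed circular order with intergenic
#' spacers, tRNA genes scattered between them, group I introns planted at
#' chosen reference-CDS positions (optionally carrying an intronic ORF),
#' planted repeat families (interspersed, palindromic, tandem), and a
#' paired nuclear sequence carrying diverged copies of mitogenome
#' segments.  Every planted feature's final coordinates are recorded in a
#' ground-truth object so each detector can be validated end-to-end.
#' @name synthetic_data
NULL

# evaluate expr under a fixed RNG state without disturbing the caller's
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

.subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

.randomDNA <- function(n, gc) {
    if (n <= 0L) return("")
    paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
}

.STOPS4 <- c("TAA", "TAG")

# random CDS: ATG start, TAA stop, no internal stops under code 4
.randomCDS <- function(len, gc) {
    stopifnot(len %% 3L == 0L, len >= 9L)
    k <- len %/% 3L
    s <- .randomDNA(len, gc)
    cod <- substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
    cod[1L] <- "ATG"; cod[k] <- "TAA"
    bad <- which(cod[2:(k - 1L)] %in% .STOPS4) + 1L
    while (length(bad)) {
        cod[bad] <- vapply(bad, function(i) .randomDNA(3L, gc), "")
        bad <- bad[cod[bad] %in% .STOPS4]
    }
    paste(cod, collapse = "")
}

# protein-level divergence: substitute a fraction of residues, keep codons
# of unchanged residues; changed residues get a random code-4 codon
.divergeCDS <- function(cds, d) {
    if (d <= 0) return(cds)
    k <- nchar(cds) %/% 3L
    cod <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    gc4 <- .code4()
    aaOf <- gc4[cod]
    byAA <- split(names(gc4), gc4)
    byAA <- byAA[setdiff(names(byAA), "*")]
    internal <- 2:(k - 1L)                      # keep start and stop codons
    nmut <- round(d * length(internal))
    if (nmut == 0L) return(cds)
    pos <- sample(internal, nmut)
    for (p in pos) {
        newaa <- sample(setdiff(names(byAA), aaOf[p]), 1L)
        cod[p] <- sample(byAA[[newaa]], 1L)
    }
    paste(cod, collapse = "")
}

# TRUE if the string has a period shorter than its length
.hasSmallerPeriod <- function(motif) {
    v <- strsplit(motif, "")[[1L]]
    p <- length(v)
    if (p == 1L) return(FALSE)
    for (q in seq_len(p - 1L)) {
        if (all(v[seq_len(p - q)] == v[seq_len(p - q) + q])) return(TRUE)
    }
    FALSE
}

# mutate a DNA segment to approximately the given percent identity
.mutateToIdentity <- function(seg, identity) {
    n <- nchar(seg)
    k <- round((100 - identity) / 100 * n)
    if (k == 0L) return(seg)
    ch <- strsplit(seg, "")[[1L]]
    pos <- sample(n, k)
    for (p in pos)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
}

.DEFAULT_GENE_LENGTHS <- c(
    atp6 = 774L, atp8 = 147L, atp9 = 222L, cob = 1158L, cox1 = 1593L,
    cox2 = 750L, cox3 = 810L, nad1 = 954L, nad2 = 1500L, nad3 = 360L,
    nad4 = 1467L, nad4L = 270L, nad5 = 1980L, nad6 = 600L, rps3 = 1200L,
    rnl = 3000L, rns = 1500L)

#' Default signed gene order (all genes on the plus strand, cox1 first)
#' @return character vector of 17 signed symbols.
#' @export
defaultGeneOrder <- function() {
    paste0("+", c("cox1", "nad1", "atp9", "rns", "cox2", "nad4L", "nad5",
                  "cob", "atp8", "atp6", "rps3", "rnl", "nad2", "nad3",
                  "nad4", "cox3", "nad6"))
}

#' The synthetic reference cox1 coding sequence
#'
#' A deterministic, package-generated stand-in for a real reference cox1
#' CDS (the coordinate system onto which intron position classes are
#' projected): 1,593 nt (530 amino acids plus stop), AT-rich, free of
#' internal stops under genetic code 4.  It is synthetic: its residues are
#' arbitrary, and only its coordinate frame matters for Pcl naming.
#'
#' @return a character string of length 1593.
#' @export
referenceCox1CDS <- function() {
    withSeed(20200811L, .randomCDS(1593L, 0.27))
}

#' Specification for one synthetic mitogenome
#'
#' @param seed integer RNG seed; the whole genome is a deterministic
#'   function of the spec.
#' @param genomeLength total size in bp.
#' @param targetGC target GC fraction in (0, 1); Basidiomycota mitogenomes
#'   run ~0.25-0.30.
#' @param geneOrder signed 17-symbol circular order (see
#'   \code{\link{defaultGeneOrder}}).
#' @param geneLengths named integer vector of per-gene lengths (defaults
#'   provided for all 17 genes).
#' @param intronPlan data.frame with columns \code{host},
#'   \code{ref_position} (nt offset in the host CDS; for cox1 this is the
#'   reference coordinate, i.e. the expected Pcl), \code{length},
#'   \code{with_orf} (logical).
#' @param repeatPlan data.frame with columns \code{kind}
#'   (\code{"forward"}, \code{"palindromic"} or \code{"tandem"}),
#'   \code{length} (unit/period length), \code{copies}, \code{identity}
#'   (percent, copies vs source).
#' @param transferPlan list: \code{n}, \code{length_range} (2-vector),
#'   \code{identity} (percent), \code{nuclearLength}.
#' @param tRNACount number of tRNA genes (default 26).
#' @param cdsDivergence protein-level substitution fraction applied to
#'   every PCG (cox1 diverges away from the reference CDS; default 0).
#' @param cdsOverride optional named list of CDS sequences that replace the
#'   generated ones (used by \code{\link{generateClade}}).
#' @param species species label.
#' @return a list of class \code{"SyntheticSpec"}.
#' @export
mitogenomeSpec <- function(seed = 1L, genomeLength = 60000L,
                           targetGC = 0.27,
                           geneOrder = defaultGeneOrder(),
                           geneLengths = .DEFAULT_GENE_LENGTHS,
                           intronPlan = NULL, repeatPlan = NULL,
                           transferPlan = list(n = 0L,
                                               length_range = c(200L, 800L),
                                               identity = 95,
                                               nuclearLength = 100000L),
                           tRNACount = 26L, cdsDivergence = 0,
                           cdsOverride = NULL,
                           species = paste0("synthetic_sp", seed)) {
    stopifnot(targetGC > 0, targetGC < 1, genomeLength > 0)
    if (is.null(intronPlan))
        intronPlan <- data.frame(host = character(0),
                                 ref_position = integer(0),
                                 length = integer(0), with_orf = logical(0))
    if (is.null(repeatPlan))
        repeatPlan <- data.frame(kind = character(0), length = integer(0),
                                 copies = integer(0), identity = numeric(0))
    spec <- list(seed = as.integer(seed), genomeLength = as.integer(genomeLength),
                 targetGC = targetGC, geneOrder = geneOrder,
                 geneLengths = geneLengths, intronPlan = intronPlan,
                 repeatPlan = repeatPlan, transferPlan = transferPlan,
                 tRNACount = as.integer(tRNACount),
                 cdsDivergence = cdsDivergence, cdsOverride = cdsOverride,
                 species = species)
    class(spec) <- "SyntheticSpec"
    spec
}

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic given the spec's seed.  Background sequence is i.i.d. at
#' the target GC; genes are laid out in the specified signed circular
#' order with intergenic spacers; introns are inserted at the stated
#' host-CDS offsets (for cox1, homologous to the reference coordinate);
#' repeats and tandem arrays are planted in intergenic space.
#'
#' @param spec a \code{\link{mitogenomeSpec}}.
#' @return list: \code{annotation} (a \linkS4class{Mitogenome}) and
#'   \code{truth} (ground-truth list with final coordinates of every
#'   planted gene, intron and repeat).
#' @export
generateMitogenome <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    withSeed(spec$seed, .generateMitogenomeImpl(spec))
}

.generateMitogenomeImpl <- function(spec) {
    gc <- spec$targetGC
    L <- spec$genomeLength
    syms <- substring(spec$geneOrder, 2L)
    signs <- substring(spec$geneOrder, 1L, 1L)
    glen <- spec$geneLengths

    # coding / RNA sequences
    cds <- list()
    for (g in syms) {
        if (!is.null(spec$cdsOverride[[g]])) {
            cds[[g]] <- spec$cdsOverride[[g]]
        } else if (g %in% RRNA_GENES) {
            cds[[g]] <- .randomDNA(glen[[g]], gc)
        } else if (g == "cox1") {
            cds[[g]] <- .divergeCDS(referenceCox1CDS(), spec$cdsDivergence)
        } else {
            cds[[g]] <- .divergeCDS(.randomCDS(glen[[g]], gc),
                                    spec$cdsDivergence)
        }
    }

    # per-gene blocks: exons/introns in block-local '+' coordinates
    blocks <- list()
    orfCounter <- 0L
    for (gi in seq_along(syms)) {
        g <- syms[gi]
        ip <- spec$intronPlan[spec$intronPlan$host == g, , drop = FALSE]
        ip <- ip[order(ip$ref_position), , drop = FALSE]
        cs <- cds[[g]]
        n <- nchar(cs)
        if (nrow(ip) && (any(ip$ref_position <= 0L) ||
                         any(ip$ref_position >= n)))
            stop("intron plan position outside CDS of ", g)
        offs <- ip$ref_position
        bounds <- c(0L, offs, n)
        pieces <- character(0); exons <- NULL; introns <- NULL; orfs <- NULL
        pos <- 0L
        for (k in seq_len(length(bounds) - 1L)) {
            ex <- substr(cs, bounds[k] + 1L, bounds[k + 1L])
            pieces <- c(pieces, ex)
            exons <- rbind(exons, data.frame(start = pos + 1L,
                                             end = pos + nchar(ex)))
            pos <- pos + nchar(ex)
            if (k < length(bounds) - 1L) {
                ilen <- ip$length[k]
                iseq <- .randomDNA(ilen, gc * 0.8)
                orf_row <- NULL
                if (isTRUE(ip$with_orf[k]) && ilen >= 420L) {
                    orfLen <- 300L
                    orfOff <- 60L
                    orfSeq <- .randomCDS(orfLen, gc)
                    iseq <- paste0(substr(iseq, 1L, orfOff),
                                   orfSeq,
                                   substr(iseq, orfOff + orfLen + 1L, ilen))
                    orfCounter <- orfCounter + 1L
                    orf_row <- data.frame(
                        name = paste0("orf", 100L + orfCounter),
                        start = pos + orfOff + 1L,
                        end = pos + orfOff + orfLen,
                        intron_ordinal = k)
                }
                pieces <- c(pieces, iseq)
                introns <- rbind(introns, data.frame(
                    ordinal = k, start = pos + 1L, end = pos + ilen,
                    ref_position = ip$ref_position[k]))
                orfs <- rbind(orfs, orf_row)
                pos <- pos + ilen
            }
        }
        blocks[[g]] <- list(seq = paste(pieces, collapse = ""),
                            len = pos, sign = signs[gi],
                            exons = exons, introns = introns, orfs = orfs)
    }

    # tRNA blocks
    tlen <- 72L
    tnames <- paste0("trn", LETTERS)[seq_len(min(spec$tRNACount, 26L))]
    if (spec$tRNACount > 26L)
        tnames <- c(tnames, paste0("trn", LETTERS, "2")[
            seq_len(spec$tRNACount - 26L)])
    tseqs <- vapply(tnames, function(x) .randomDNA(tlen, gc), "")

    featLen <- sum(vapply(blocks, function(b) as.integer(b$len), 1L)) +
        spec$tRNACount * tlen
    nSlots <- length(syms) + 1L
    minSpacer <- 40L
    free <- L - featLen - nSlots * minSpacer
    if (free < 0L)
        stop("capacity error: planted features (", featLen,
             " bp + spacers) exceed genome length ", L)
    extra <- stats::rmultinom(1L, free, rep(1, nSlots))[, 1L]
    spacerLen <- minSpacer + extra

    # assign tRNAs to slots round-robin
    tSlot <- rep(seq_len(nSlots), length.out = spec$tRNACount)

    segs <- character(0)
    geneRows <- list(); intronRows <- list(); spacerIv <- NULL
    cursor <- 0L
    addSpacer <- function(slot) {
        parts <- character(0)
        tIdx <- which(tSlot == slot)
        budget <- spacerLen[slot]
        nT <- length(tIdx)
        cuts <- if (nT > 0L)
            sort(sample(seq_len(max(budget - 1L, 1L)), min(nT, budget - 1L)))
        else integer(0)
        bounds <- c(0L, cuts, budget)
        for (q in seq_len(length(bounds) - 1L)) {
            gap <- bounds[q + 1L] - bounds[q]
            if (gap > 0L) {
                parts <- c(parts, .randomDNA(gap, gc))
                spacerIv <<- rbind(spacerIv, data.frame(
                    start = cursor + 1L, end = cursor + gap))
                cursor <<- cursor + gap
            }
            if (q <= nT) {
                ti <- tIdx[q]
                geneRows[[length(geneRows) + 1L]] <<- list(
                    gene = tnames[ti], class = "trna", strand = "+",
                    product = paste0("tRNA-", substring(tnames[ti], 4L)),
                    host_intron = NA_integer_,
                    exons = IRanges(cursor + 1L, cursor + tlen))
                parts <- c(parts, tseqs[ti])
                cursor <<- cursor + tlen
            }
        }
        segs <<- c(segs, parts)
    }

    truthIntrons <- NULL; truthOrfs <- NULL
    for (gi in seq_along(syms)) {
        addSpacer(gi)
        g <- syms[gi]
        b <- blocks[[g]]
        bstart <- cursor + 1L
        blen <- b$len
        mapFwd <- function(s, e) c(bstart + s - 1L, bstart + e - 1L)
        mapRev <- function(s, e) c(bstart + (blen - e), bstart + (blen - s))
        map <- if (b$sign == "-") mapRev else mapFwd
        exg <- t(apply(b$exons, 1L, function(r) map(r[["start"]], r[["end"]])))
        segs <- c(segs, if (b$sign == "-") revcompChar(b$seq) else b$seq)
        cls <- if (g %in% RRNA_GENES) "rrna" else "core_pcg"
        geneRows[[length(geneRows) + 1L]] <- list(
            gene = g, class = cls, strand = if (b$sign == "-") "-" else "+",
            product = g, host_intron = NA_integer_,
            exons = IRanges(start = sort(exg[, 1L]),
                            end = sort(exg[, 2L])))
        if (!is.null(b$introns)) {
            for (r in seq_len(nrow(b$introns))) {
                iv <- map(b$introns$start[r], b$introns$end[r])
                intronRows[[length(intronRows) + 1L]] <- data.frame(
                    host = g, ordinal = b$introns$ordinal[r],
                    start = iv[1L], end = iv[2L],
                    strand = if (b$sign == "-") "-" else "+", group = "I")
                truthIntrons <- rbind(truthIntrons, data.frame(
                    host = g, ordinal = b$introns$ordinal[r],
                    ref_position = b$introns$ref_position[r],
                    start = iv[1L], end = iv[2L]))
            }
            if (b$sign == "-") {
                # ordinals follow transcription order regardless of strand
            }
        }
        if (!is.null(b$orfs)) {
            for (r in seq_len(nrow(b$orfs))) {
                iv <- map(b$orfs$start[r], b$orfs$end[r])
                geneRows[[length(geneRows) + 1L]] <- list(
                    gene = b$orfs$name[r], class = "intronic_orf",
                    strand = if (b$sign == "-") "-" else "+",
                    product = "LAGLIDADG homing endonuclease",
                    host_intron = NA_integer_,
                    exons = IRanges(iv[1L], iv[2L]))
                truthOrfs <- rbind(truthOrfs, data.frame(
                    name = b$orfs$name[r], host = g,
                    start = iv[1L], end = iv[2L]))
            }
        }
        cursor <- cursor + blen
    }
    addSpacer(nSlots)
    genome <- paste(segs, collapse = "")
    stopifnot(nchar(genome) == L)

    # plant repeats/tandems in intergenic space
    used <- IRanges()
    truthRepeats <- NULL; truthTandems <- NULL
    gch <- NULL
    pickWindow <- function(len) {
        cand <- spacerIv[(spacerIv$end - spacerIv$start + 1L) >= len, ,
                         drop = FALSE]
        for (tries in seq_len(200L)) {
            if (!nrow(cand)) break
            r <- cand[sample(nrow(cand), 1L), ]
            room <- r$end - r$start + 1L - len
            s <- r$start + if (room > 0L) sample.int(room + 1L, 1L) - 1L else 0L
            iv <- IRanges(s, s + len - 1L)
            if (!any(IRanges::overlapsAny(iv, used))) {
                used <<- c(used, iv)
                return(c(s, s + len - 1L))
            }
        }
        stop("capacity error: no intergenic room for a planted repeat of ",
             len, " bp")
    }
    writeSeg <- function(s, e, seg) {
        substr(genome, s, e) <<- seg
    }
    rp <- spec$repeatPlan
    for (r in seq_len(nrow(rp))) {
        kind <- rp$kind[r]
        if (kind == "tandem") {
            p <- rp$length[r]; cpy <- rp$copies[r]
            total <- p * cpy
            w <- pickWindow(total)
            motif <- .randomDNA(p, gc)
            # plant a primitive motif: no internal period < p, so the
            # detector's period is well defined
            while (.hasSmallerPeriod(motif)) motif <- .randomDNA(p, gc)
            writeSeg(w[1L], w[2L], strrep(motif, cpy))
            # break the period in the flanks so the planted array is
            # exactly delimited (no accidental extension)
            for (k in 0:2) {
                i <- w[1L] - 1L - k
                if (i >= 1L)
                    writeSeg(i, i, sample(setdiff(c("A", "C", "G", "T"),
                        substr(genome, i + p, i + p)), 1L))
                j <- w[2L] + 1L + k
                if (j <= L)
                    writeSeg(j, j, sample(setdiff(c("A", "C", "G", "T"),
                        substr(genome, j - p, j - p)), 1L))
            }
            truthTandems <- rbind(truthTandems, data.frame(
                start = w[1L], end = w[2L], period = p, copies = cpy))
        } else {
            len <- rp$length[r]; cpy <- max(2L, rp$copies[r])
            src <- pickWindow(len)
            seg <- .randomDNA(len, gc)
            writeSeg(src[1L], src[2L], seg)
            prev <- src
            for (cc in seq_len(cpy - 1L)) {
                dst <- pickWindow(len)
                seg2 <- .mutateToIdentity(seg, rp$identity[r])
                if (kind == "palindromic") seg2 <- revcompChar(seg2)
                writeSeg(dst[1L], dst[2L], seg2)
                truthRepeats <- rbind(truthRepeats, data.frame(
                    kind = kind, a_start = src[1L], a_end = src[2L],
                    b_start = dst[1L], b_end = dst[2L],
                    length = len, identity = rp$identity[r]))
            }
        }
    }

    genes <- DataFrame(
        gene = vapply(geneRows, `[[`, "", "gene"),
        class = vapply(geneRows, `[[`, "", "class"),
        strand = vapply(geneRows, `[[`, "", "strand"),
        product = vapply(geneRows, `[[`, "", "product"),
        host_intron = vapply(geneRows, `[[`, 1L, "host_intron"),
        exons = IRangesList(lapply(geneRows, `[[`, "exons")))
    introns <- if (length(intronRows)) {
        d <- do.call(rbind, intronRows)
        DataFrame(host = d$host, ordinal = as.integer(d$ordinal),
                  start = as.integer(d$start), end = as.integer(d$end),
                  strand = d$strand, group = d$group)
    } else .emptyIntronTable()
    # intronic ORFs: resolve host_intron indices by containment
    if (nrow(introns)) {
        io <- which(genes$class == "intronic_orf")
        for (i in io) {
            ex <- genes$exons[[i]]
            hi <- which(introns$start <= min(start(ex)) &
                        introns$end >= max(end(ex)))
            if (length(hi)) genes$host_intron[i] <- hi[1L]
        }
    }
    mg <- Mitogenome(id = spec$species, seq = genome,
                     species = spec$species, circular = TRUE,
                     genes = genes, introns = introns)
    truth <- list(spec = spec, introns = truthIntrons, orfs = truthOrfs,
                  repeats = truthRepeats, tandems = truthTandems,
                  gene_order = spec$geneOrder)
    list(annotation = mg, truth = truth)
}

#' Generate a paired nuclear sequence carrying diverged mitogenome segments
#'
#' A random nuclear background into which \code{n} segments of the
#' mitochondrial genome are copied at the planned identity (substitutions
#' only), emulating mitochondrial-to-nuclear transfer.  Positions and
#' identities are recorded in the ground truth.
#'
#' @param mito a \linkS4class{Mitogenome}.
#' @param spec the \code{\link{mitogenomeSpec}} whose \code{transferPlan}
#'   drives the simulation (seed reused, offset).
#' @return list: \code{nuclear} (character sequence) and \code{truth}
#'   (data.frame: mito_start, mito_end, nuclear_start, nuclear_end,
#'   identity, length).
#' @export
generateNuclearWithTransfer <- function(mito, spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    tp <- spec$transferPlan
    withSeed(.subSeed(spec$seed, 77L), {
        NL <- as.integer(tp$nuclearLength)
        nuc <- .randomDNA(NL, 0.5)
        truth <- NULL
        used <- IRanges()
        L <- genomeLength(mito)
        s <- as.character(genomeSeq(mito))
        n <- if (is.null(tp$n)) 0L else as.integer(tp$n)
        for (k in seq_len(n)) {
            len <- sample(seq(tp$length_range[1L], tp$length_range[2L]), 1L)
            stopifnot(len <= L)
            ms <- sample.int(L - len + 1L, 1L)
            seg <- .mutateToIdentity(substr(s, ms, ms + len - 1L),
                                     tp$identity)
            for (tries in seq_len(200L)) {
                ns <- sample.int(NL - len + 1L, 1L)
                iv <- IRanges(ns, ns + len - 1L)
                if (!any(IRanges::overlapsAny(iv, used))) {
                    used <- c(used, iv)
                    substr(nuc, ns, ns + len - 1L) <- seg
                    truth <- rbind(truth, data.frame(
                        mito_start = ms, mito_end = ms + len - 1L,
                        nuclear_start = ns, nuclear_end = ns + len - 1L,
                        identity = tp$identity, length = len))
                    break
                }
            }
        }
        list(nuclear = nuc, truth = truth)
    })
}

#' Generate a clade of related synthetic mitogenomes
#'
#' Species evolve along a random tree from a common ancestral state:
#' coding sequences accumulate protein-level substitutions, introns are
#' gained and lost per position class, and the gene order is perturbed by
#' random block inversions.  Ground truth records every tip's realized
#' intron set and order.
#'
#' @param nSpecies number of species (>= 2).
#' @param baseSpec ancestral \code{\link{mitogenomeSpec}}; its
#'   \code{intronPlan} is both the root state and the gain pool.
#' @param intronGainLoss per-branch probability that a position class
#'   toggles (present introns lost, absent pool introns gained).
#' @param rearrangementRate expected number of block inversions per branch
#'   (Poisson).
#' @param divergence protein substitutions per site per unit branch
#'   length.
#' @param intronMembership optional named list mapping a cox1 reference
#'   position (as character) to the integer indices of species that must
#'   carry it; overrides gain/loss for those positions (planted-truth
#'   mode).
#' @return list of per-species results as from
#'   \code{\link{generateMitogenome}} (elements named by species).
#' @export
generateClade <- function(nSpecies, baseSpec, intronGainLoss = 0.1,
                          rearrangementRate = 0.5, divergence = 0.05,
                          intronMembership = NULL) {
    stopifnot(nSpecies >= 2L, inherits(baseSpec, "SyntheticSpec"))
    withSeed(baseSpec$seed, {
        tree <- ape::rtree(nSpecies, tip.label = paste0("sp", seq_len(nSpecies)))
        syms <- substring(baseSpec$geneOrder, 2L)
        rootCDS <- list()
        for (g in syms) {
            if (g %in% RRNA_GENES)
                rootCDS[[g]] <- .randomDNA(baseSpec$geneLengths[[g]],
                                           baseSpec$targetGC)
            else if (g == "cox1") rootCDS[[g]] <- referenceCox1CDS()
            else rootCDS[[g]] <- .randomCDS(baseSpec$geneLengths[[g]],
                                            baseSpec$targetGC)
        }
        pool <- baseSpec$intronPlan
        rootState <- list(cds = rootCDS, introns = baseSpec$intronPlan,
                          order = baseSpec$geneOrder)
        nTip <- nSpecies
        states <- vector("list", nTip + tree$Nnode)
        root <- nTip + 1L
        states[[root]] <- rootState
        evolve <- function(st, t) {
            for (g in names(st$cds)) {
                if (g %in% RRNA_GENES) next
                st$cds[[g]] <- .divergeCDS(st$cds[[g]],
                                           min(0.9, divergence * t))
            }
            if (nrow(pool)) {
                have <- paste(st$introns$host, st$introns$ref_position)
                all_ <- paste(pool$host, pool$ref_position)
                toggle <- stats::runif(nrow(pool)) < intronGainLoss
                keep <- (all_ %in% have) != toggle
                st$introns <- pool[keep, , drop = FALSE]
            }
            nInv <- stats::rpois(1L, rearrangementRate * t)
            for (k in seq_len(nInv)) st$order <- .invertBlock(st$order)
            st
        }
        ord <- rev(ape::postorder(tree))          # parent-before-child edges
        for (e in ord) {
            par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
            states[[child]] <- evolve(states[[par]], tree$edge.length[e])
        }
        out <- list()
        for (i in seq_len(nTip)) {
            st <- states[[i]]
            sp <- tree$tip.label[i]
            introns <- st$introns
            if (!is.null(intronMembership)) {
                for (posKey in names(intronMembership)) {
                    members <- intronMembership[[posKey]]
                    pos <- as.integer(posKey)
                    rowIn <- which(introns$host == "cox1" &
                                   introns$ref_position == pos)
                    if (i %in% members && !length(rowIn)) {
                        introns <- rbind(introns, data.frame(
                            host = "cox1", ref_position = pos,
                            length = 1200L, with_orf = FALSE))
                    } else if (!(i %in% members) && length(rowIn)) {
                        introns <- introns[-rowIn, , drop = FALSE]
                    }
                }
            }
            sp_spec <- mitogenomeSpec(
                seed = .subSeed(baseSpec$seed, i),
                genomeLength = baseSpec$genomeLength,
                targetGC = baseSpec$targetGC,
                geneOrder = st$order,
                geneLengths = baseSpec$geneLengths,
                intronPlan = introns,
                tRNACount = baseSpec$tRNACount,
                cdsOverride = st$cds,
                species = sp)
            out[[sp]] <- generateMitogenome(sp_spec)
        }
        out
    })
}

# invert a random contiguous block of 2-4 genes (not containing position 1
# restriction unnecessary; canonicalization handles any block)
.invertBlock <- function(order_) {
    n <- length(order_)
    blen <- sample(2:min(4L, n - 1L), 1L)
    s <- sample.int(n - blen + 1L, 1L)
    idx <- s:(s + blen - 1L)
    order_[idx] <- rev(.flipSigns(order_[idx]))
    order_
}
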