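#' A synthetic 75-species Basidiomycota-like cohort
#'
#' Builds a full synthetic survey cohort emulating the published summary
#' regime of Basidiomycota mitogenomes: sizes spanning 24,874-235,849 bp
#' with mean 77,184 bp, 0-46 introns per species with intron count rising
#' with genome size (size-intron Pearson correlation about 0.81), and 43
#' cox1 intron position classes whose prevalence profile has P383 in 40
#' species, P1107 in 35, eleven singleton Pcls (P166, P193, P218, P309,
#' P318, P623, P701, P726, P1058, P1117, P1281) and a 13-common /
#' 30-rare split under the strictly-more-than-one-fifth rule.  All
#' sequences are synthetic; the cohort is a planted-truth stand-in for an
#' accession-scale survey, not real data.
#'
#' @param nSpecies number of species (default 75).
#' @param seed RNG seed; the cohort is deterministic given it.
#' @param fullGenomes if \code{TRUE} (default) every species' annotated
#'   genome is generated at its planted size; if \code{FALSE} only the
#'   design (sizes, membership) is returned, which is much faster.
#' @return list: \code{results} (per-species \code{annotation} +
#'   \code{truth}, when \code{fullGenomes}), \code{records} (data.frame
#'   \code{species}, \code{size}, \code{introns}), \code{design} (list
#'   with the Pcl table and membership), \code{referenceCds}.
#' @export
basidioCohort <- function(nSpecies = 75L, seed = 1L, fullGenomes = TRUE) {
    withSeed(.subSeed(seed, 9L), {
        design <- .cohortDesign(nSpecies)
        refCds <- referenceCox1CDS()
        results <- NULL
        if (fullGenomes) {
            results <- vector("list", nSpecies)
            names(results) <- design$species
            for (i in seq_len(nSpecies)) {
                sp_spec <- mitogenomeSpec(
                    seed = .subSeed(seed, 100L + i),
                    genomeLength = design$sizes[i],
                    targetGC = 0.27,
                    geneOrder = design$orders[[i]],
                    intronPlan = design$intronPlans[[i]],
                    tRNACount = sample(20:35, 1L),
                    cdsDivergence = 0.10,
                    species = design$species[i])
                results[[i]] <- generateMitogenome(sp_spec)
            }
        }
        records <- data.frame(
            species = design$species,
            size = design$sizes,
            introns = vapply(design$intronPlans, nrow, 1L))
        list(results = results, records = records, design = design,
             referenceCds = refCds)
    })
}

# the planted design: sizes, intron counts, Pcl membership, gene orders
.cohortDesign <- function(n) {
    species <- sprintf("synth_sp%02d", seq_len(n))
    sizeMin <- 24874L; sizeMax <- 235849L; sizeMean <- 77184L

    # deterministic lognormal size profile; extremes planted exactly and
    # the interior rescaled so the mean lands on the survey mean
    q <- stats::qlnorm(stats::ppoints(n - 2L), meanlog = log(70000),
                       sdlog = 0.45)
    q <- q - min(q)
    interiorTarget <- sizeMean * n - sizeMin - sizeMax
    floor_ <- sizeMin + 500
    interior <- floor_ + q * (interiorTarget - (n - 2L) * floor_) / sum(q)
    stopifnot(all(interior > sizeMin), all(interior < sizeMax))
    sizes <- as.integer(round(c(sizeMin, sort(interior), sizeMax)))
    sizes <- sample(sizes)                        # shuffle species order

    # intron counts rise linearly with size; noise sd set so that the
    # size-count correlation sits near the survey's 0.81
    beta <- 46 / (sizeMax - sizeMin)
    signal <- beta * (sizes - sizeMin)
    # the 1.2 factor compensates for the variance removed by the capacity
    # clamp below, so the realized size-count correlation sits near 0.81
    noiseSD <- stats::sd(signal) * sqrt(1 / 0.81^2 - 1) * 1.2
    counts <- round(signal + stats::rnorm(n, 0, noiseSD))
    maxcap <- pmin(46L, pmax(0L, (sizes - 24000L) %/% 1800L))
    counts <- pmin(pmax(counts, 0L), maxcap)

    # 43 Pcls: 13 common (> n/5) incl. P383 (40) and P1107 (35),
    # 30 rare incl. the 11 singletons
    named <- c(P383 = 40L, P1107 = 35L)
    singles <- c(166L, 193L, 218L, 309L, 318L, 623L, 701L, 726L, 1058L,
                 1117L, 1281L)
    commonPrev <- c(40L, 35L, 30L, 28L, 26L, 24L, 22L, 21L, 20L, 19L,
                    18L, 17L, 16L)
    rarePrev <- c(rep(1L, 11L),
                  c(15L, 14L, 13L, 12L, 11L, 10L, 9L, 8L, 7L, 6L, 5L,
                    4L, 3L, 2L, 2L, 2L, 3L, 3L, 4L))
    usedPos <- c(383L, 1107L, singles)
    extraN <- (length(commonPrev) - 2L) + (length(rarePrev) - 11L)
    candidates <- setdiff(seq(30L, 1560L, by = 1L), usedPos)
    extraPos <- sort(sample(candidates, extraN))
    positions <- c(383L, 1107L, extraPos[seq_len(length(commonPrev) - 2L)],
                   singles,
                   extraPos[-seq_len(length(commonPrev) - 2L)])
    prevalence <- c(commonPrev, rarePrev)
    stopifnot(length(positions) == length(prevalence),
              !anyDuplicated(positions))
    pcls <- data.frame(label = paste0("P", positions),
                       position = positions, prevalence = prevalence)

    # membership: species weighted by remaining intron capacity so large
    # genomes collect more position classes
    assigned <- integer(n)
    membership <- vector("list", nrow(pcls))
    for (k in order(-pcls$prevalence)) {
        w <- pmax(maxcap - assigned, 0) + 1e-3
        members <- sample.int(n, pcls$prevalence[k], prob = w)
        membership[[k]] <- sort(members)
        assigned[members] <- assigned[members] + 1L
    }
    names(membership) <- pcls$label

    intronPlans <- vector("list", n)
    hosts <- c("cob", "nad5", "nad4", "nad2", "cox2", "cox3", "nad1")
    hostLen <- .DEFAULT_GENE_LENGTHS[hosts]
    for (i in seq_len(n)) {
        mine <- which(vapply(membership, function(m) i %in% m, TRUE))
        plan <- if (length(mine)) data.frame(
            host = "cox1", ref_position = pcls$position[mine],
            length = sample(seq(800L, 1800L, by = 50L), length(mine),
                            replace = TRUE),
            with_orf = stats::runif(length(mine)) < 0.5) else
            data.frame(host = character(0), ref_position = integer(0),
                       length = integer(0), with_orf = logical(0))
        extra <- min(max(0L, counts[i] - nrow(plan)),
                     max(0L, maxcap[i] - nrow(plan)))
        if (extra > 0L) {
            h <- sample(hosts, extra, replace = TRUE)
            off <- vapply(h, function(g)
                3L * sample.int(hostLen[[g]] %/% 3L - 2L, 1L), 1L)
            dup <- duplicated(paste(h, off))
            plan <- rbind(plan, data.frame(
                host = h[!dup], ref_position = off[!dup],
                length = sample(seq(800L, 1800L, by = 50L), sum(!dup),
                                replace = TRUE),
                with_orf = stats::runif(sum(!dup)) < 0.5))
        }
        intronPlans[[i]] <- plan
    }

    orders <- lapply(seq_len(n), function(i) {
        o <- defaultGeneOrder()
        for (k in seq_len(sample(0:3, 1L))) o <- .invertBlock(o)
        o
    })

    list(species = species, sizes = sizes, counts = counts,
         maxcap = maxcap, pcls = pcls, membership = membership,
         intronPlans = intronPlans, orders = orders)
}
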