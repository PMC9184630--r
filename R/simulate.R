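#' Simulate hierarchically structured SSR genotypes
#'
#' Generates diploid multilocus genotypes under a two-level island model:
#' ancestral allele frequencies per locus are drawn from a symmetric
#' Dirichlet; regional frequencies follow a Balding-Nichols (Dirichlet)
#' distribution around the ancestral frequencies with coancestry
#' \code{thetaRegion}; population frequencies likewise around their region
#' with \code{thetaPop}. Each individual is autozygous with probability
#' \code{fInbreed} (one allele drawn from the population frequencies and
#' duplicated), otherwise its two alleles are drawn independently. Loci are
#' unlinked; any linkage disequilibrium in the output arises from structure
#' and inbreeding only.
#'
#' Allele labels are plausible fragment sizes (\code{100 + 2k} bp, dinucleotide
#' spacing).
#'
#' @param nRegions number of regions.
#' @param popsPerRegion populations per region (scalar or per-region vector).
#' @param nPerPop diploid individuals per population.
#' @param nLoci number of unlinked loci.
#' @param allelesPerLocus alleles per locus (scalar or length-\code{nLoci}).
#' @param thetaRegion coancestry of regions around the ancestral pool, in
#'   [0, 1); 0 copies the ancestral frequencies exactly.
#' @param thetaPop coancestry of populations within their region, in [0, 1).
#' @param fInbreed within-population inbreeding coefficient, in [0, 1).
#' @param missingRate per-(individual, locus) missing-call probability.
#' @param dirichletShape symmetric Dirichlet shape for ancestral frequencies
#'   (larger = more even allele frequencies).
#' @param seed integer seed; identical seeds give identical tables.
#' @return a \linkS4class{GenotypeTable} with region labels set.
#' @export
simulateHierarchicalSSR <- function(nRegions = 2, popsPerRegion = 5,
                                    nPerPop = 30, nLoci = 10,
                                    allelesPerLocus = 10,
                                    thetaRegion = 0.05, thetaPop = 0.05,
                                    fInbreed = 0.08, missingRate = 0,
                                    dirichletShape = 1, seed = 1) {
    stopifnot(nRegions >= 1, all(popsPerRegion >= 1), nPerPop >= 1,
              nLoci >= 1, all(allelesPerLocus >= 1),
              thetaRegion >= 0, thetaRegion < 1,
              thetaPop >= 0, thetaPop < 1,
              fInbreed >= 0, fInbreed < 1,
              missingRate >= 0, missingRate < 1)
    if (length(popsPerRegion) == 1L)
        popsPerRegion <- rep(popsPerRegion, nRegions)
    stopifnot(length(popsPerRegion) == nRegions)
    if (length(allelesPerLocus) == 1L)
        allelesPerLocus <- rep(allelesPerLocus, nLoci)
    stopifnot(length(allelesPerLocus) == nLoci)

    withr_seed <- .with_seed(seed)
    on.exit(withr_seed())

    loci <- sprintf("L%02d", seq_len(nLoci))
    regionNames <- sprintf("R%s", LETTERS[seq_len(nRegions)])
    popNames <- unlist(lapply(seq_len(nRegions), function(r)
        sprintf("%s_P%02d", regionNames[r], seq_len(popsPerRegion[r]))))
    popRegion <- rep(regionNames, popsPerRegion)
    names(popRegion) <- popNames

    nPops <- length(popNames)
    nInd <- nPops * nPerPop
    popOf <- rep(popNames, each = nPerPop)
    ids <- sprintf("%s_i%03d", popOf,
                   unlist(lapply(seq_len(nPops), function(i) seq_len(nPerPop))))

    a <- array(NA_integer_, c(nInd, nLoci, 2L),
               dimnames = list(ids, loci, NULL))
    for (l in seq_len(nLoci)) {
        K <- allelesPerLocus[l]
        labels <- as.integer(100 + 2 * seq_len(K))
        anc <- .rdirichlet(rep(dirichletShape, K))
        popFreq <- matrix(0, nPops, K)
        for (r in seq_len(nRegions)) {
            regFreq <- .balding_nichols(anc, thetaRegion)
            for (p in which(popRegion == regionNames[r]))
                popFreq[p, ] <- .balding_nichols(regFreq, thetaPop)
        }
        for (p in seq_len(nPops)) {
            rows <- which(popOf == popNames[p])
            n <- length(rows)
            auto <- stats::runif(n) < fInbreed
            a1 <- sample.int(K, n, replace = TRUE, prob = popFreq[p, ])
            a2 <- sample.int(K, n, replace = TRUE, prob = popFreq[p, ])
            a2[auto] <- a1[auto]
            a[rows, l, 1] <- labels[pmin(a1, a2)]
            a[rows, l, 2] <- labels[pmax(a1, a2)]
        }
    }
    if (missingRate > 0) {
        drop <- matrix(stats::runif(nInd * nLoci) < missingRate, nInd, nLoci)
        a[, , 1][drop] <- NA_integer_
        a[, , 2][drop] <- NA_integer_
    }
    GenotypeTable(a, data.frame(sample_id = ids, population = popOf,
                                region = unname(popRegion[popOf]),
                                stringsAsFactors = FALSE))
}

## Balding-Nichols draw: Dirichlet around parent with concentration
## (1 - theta)/theta; theta = 0 returns the parent exactly.
.balding_nichols <- function(parent, theta) {
    if (theta == 0) return(parent)
    conc <- (1 - theta) / theta
    ## alleles locally lost (zero parent frequency) stay lost
    out <- numeric(length(parent))
    pos <- parent > 0
    out[pos] <- .rdirichlet(conc * parent[pos])
    out
}

.rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
}

## set the RNG seed, returning a restore function
.with_seed <- function(seed) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    function() {
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    }
}

#' Simulate region-structured cpDNA alignments
#'
#' Builds per-marker alignments in which each region carries one dominant
#' chloroplast haplotype plus rare region-endemic variants. Haplotypes differ
#' by single-base substitutions and by deletion events (maximal gap runs of
#' one or more columns); every simulated variant event is polymorphic among
#' the sampled haplotypes and every pair of haplotypes differs somewhere, so
#' the truth is recoverable.
#'
#' @param regions character vector of region names.
#' @param popsPerRegion populations per region.
#' @param nPerPop sampled individuals per population.
#' @param markerLengths integer vector of marker (spacer) alignment lengths.
#' @param substitutionSites total substitution events across markers.
#' @param deletionEvents total deletion events (gap runs) across markers.
#' @param deletionLengthRange run length range for deletion events, in bp.
#' @param nHaplotypesPerRegion haplotypes per region (1 dominant + rares).
#' @param rareHaplotypeRate probability a sample carries a rare endemic
#'   haplotype instead of its region's dominant one.
#' @param seed integer seed.
#' @return list with \code{alignments} (named list of \code{DNAStringSet},
#'   one per marker), \code{meta} (data.frame sample_id, population, region)
#'   and \code{truth} (named character sample -> true haplotype id).
#' @export
simulateCpDNA <- function(regions = c("RA", "RB"), popsPerRegion = 4,
                          nPerPop = 8,
                          markerLengths = c(atpB_rbcL = 573, petG_trnP = 487,
                                            trnL1_trnL2 = 500, psbM_trnD = 593),
                          substitutionSites = 21, deletionEvents = 7,
                          deletionLengthRange = c(1, 6),
                          nHaplotypesPerRegion = 3,
                          rareHaplotypeRate = 0.08, seed = 1) {
    nReg <- length(regions)
    nHap <- nReg * nHaplotypesPerRegion
    nEvents <- substitutionSites + deletionEvents
    if (nEvents < nHap)
        stop("substitutionSites + deletionEvents must be >= total haplotypes ",
             "for haplotypes to be distinguishable")
    stopifnot(nHaplotypesPerRegion >= 1, all(markerLengths > 10),
              rareHaplotypeRate >= 0, rareHaplotypeRate < 1)
    restore <- .with_seed(seed)
    on.exit(restore())

    if (is.null(names(markerLengths)))
        names(markerLengths) <- sprintf("marker%d", seq_along(markerLengths))
    markers <- names(markerLengths)

    ## ancestral sequence per marker
    anc <- lapply(markerLengths, function(len)
        sample(c("A", "C", "G", "T"), len, replace = TRUE))

    ## place events on the concatenated coordinate system, keeping deletion
    ## runs inside one marker and separated by >= 2 intact columns so each
    ## run stays a distinct maximal gap run
    totalLen <- sum(markerLengths)
    offsets <- cumsum(c(0, markerLengths[-length(markerLengths)]))
    names(offsets) <- markers
    maxDel <- deletionLengthRange[2]
    used <- rep(FALSE, totalLen)           # columns unavailable for new events
    pad <- function(s, e) max(1, s - 2):min(totalLen, e + 2)

    delRuns <- vector("list", deletionEvents)
    for (d in seq_len(deletionEvents)) {
        repeat {
            m <- sample(markers, 1)
            len <- sample(seq(deletionLengthRange[1], maxDel), 1)
            s <- offsets[m] + sample(seq_len(markerLengths[m] - len - 2), 1) + 1
            e <- s + len - 1
            if (!any(used[pad(s, e)])) break
        }
        used[pad(s, e)] <- TRUE
        delRuns[[d]] <- c(s, e)
    }
    subSites <- integer(substitutionSites)
    for (s in seq_len(substitutionSites)) {
        repeat {
            x <- sample.int(totalLen, 1)
            if (!any(used[pad(x, x)])) break
        }
        used[pad(x, x)] <- TRUE
        subSites[s] <- x
    }
    subSites <- sort(subSites)

    ## carrier matrix: haplotype x event, rows distinct, columns polymorphic
    repeat {
        M <- matrix(stats::runif(nHap * nEvents) < 0.4, nHap, nEvents)
        ok <- !anyDuplicated(split(M, row(M))) &&
            all(colSums(M) >= 1) && all(colSums(M) < nHap)
        if (ok) break
    }

    ## alternate base per substitution site
    concatAnc <- unlist(anc, use.names = FALSE)
    altBase <- vapply(subSites, function(x)
        sample(setdiff(c("A", "C", "G", "T"), concatAnc[x]), 1), character(1))

    hapSeq <- matrix(rep(concatAnc, each = nHap), nrow = nHap)
    for (ev in seq_len(nEvents)) {
        carriers <- which(M[, ev])
        if (ev <= substitutionSites) {
            hapSeq[carriers, subSites[ev]] <- altBase[ev]
        } else {
            run <- delRuns[[ev - substitutionSites]]
            hapSeq[carriers, run[1]:run[2]] <- "-"
        }
    }

    ## region assignment: haplotype h belongs to region ceiling(h / perRegion);
    ## first haplotype of each region is dominant
    hapRegion <- rep(regions, each = nHaplotypesPerRegion)
    dominant <- seq(1, nHap, by = nHaplotypesPerRegion)

    pops <- unlist(lapply(seq_len(nReg), function(r)
        sprintf("%s_P%02d", regions[r], seq_len(popsPerRegion))))
    popReg <- rep(regions, each = popsPerRegion)
    names(popReg) <- pops
    ids <- character(0); popOf <- character(0); hapOf <- integer(0)
    for (p in pops) {
        r <- match(popReg[p], regions)
        cand <- which(hapRegion == regions[r])
        rare <- setdiff(cand, dominant[r])
        h <- ifelse(stats::runif(nPerPop) < rareHaplotypeRate &
                        length(rare) > 0,
                    sample(rep(rare, 2), nPerPop, replace = TRUE),
                    dominant[r])
        ids <- c(ids, sprintf("%s_s%02d", p, seq_len(nPerPop)))
        popOf <- c(popOf, rep(p, nPerPop))
        hapOf <- c(hapOf, h)
    }

    ## ensure every haplotype is observed at least once (replace dominants)
    for (h in seq_len(nHap)) {
        if (!any(hapOf == h)) {
            inReg <- which(popReg[popOf] == hapRegion[h] &
                               hapOf == dominant[match(hapRegion[h], regions)])
            hapOf[inReg[1]] <- h
        }
    }

    alignments <- stats::setNames(vector("list", length(markers)), markers)
    for (m in markers) {
        cols <- (offsets[m] + 1):(offsets[m] + markerLengths[m])
        seqs <- apply(hapSeq[hapOf, cols, drop = FALSE], 1, paste, collapse = "")
        alignments[[m]] <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    }
    list(alignments = alignments,
         meta = data.frame(sample_id = ids, population = popOf,
                           region = unname(popReg[popOf]),
                           stringsAsFactors = FALSE),
         truth = stats::setNames(sprintf("hap%02d", hapOf), ids))
}
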