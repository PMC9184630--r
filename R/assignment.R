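#' Rannala-Mountain genotype log-likelihood
#'
#' Bayesian posterior-predictive probability of a multilocus genotype given
#' a candidate population's allele counts, with a uniform Dirichlet prior of
#' total mass 1 (pseudo-count 1/K per allele, K = number of alleles observed
#' at the locus across the whole reference table). For a locus with
#' population counts n (total 2N alleles): heterozygote (i, j):
#' 2 (n_i + 1/K)(n_j + 1/K) / ((2N + 1)(2N + 2)); homozygote (i, i):
#' (n_i + 1/K)(n_i + 1 + 1/K) / ((2N + 1)(2N + 2)) (a Polya urn on the
#' posterior). Loci missing from the profile are skipped.
#'
#' @param profile loci x 2 matrix of allele labels (NA rows skipped)
#' @param counts named list per locus: named integer vector of the
#'   population's allele counts
#' @param K named integer: total number of alleles per locus across all
#'   reference populations (sets the prior pseudo-count 1/K)
#' @return log10 likelihood of the profile
#' @export
rannalaMountainLoglik <- function(profile, counts, K) {
    profile <- .as_profile(profile)
    ll <- 0
    for (l in rownames(profile)) {
        g <- profile[l, ]
        if (any(is.na(g))) next
        if (is.null(counts[[l]])) {
            warning("locus '", l, "' absent from reference counts; skipped")
            next
        }
        cnt <- counts[[l]]
        k <- K[[l]]
        tot <- sum(cnt)
        ni <- function(a) {
            a <- as.character(a)
            if (a %in% names(cnt)) unname(cnt[a]) else 0
        }
        pri <- 1 / k
        if (g[1] == g[2]) {
            num <- (ni(g[1]) + pri) * (ni(g[1]) + 1 + pri)
        } else {
            num <- 2 * (ni(g[1]) + pri) * (ni(g[2]) + pri)
        }
        ll <- ll + log10(num) - log10((tot + 1) * (tot + 2))
    }
    ll
}

## reference allele counts per population x locus, plus global K per locus
.ref_counts <- function(gt) {
    pops <- unique(populations(gt))
    loci <- lociNames(gt)
    K <- stats::setNames(integer(length(loci)), loci)
    counts <- stats::setNames(vector("list", length(pops)), pops)
    for (p in pops) counts[[p]] <- stats::setNames(vector("list",
                                                          length(loci)), loci)
    for (l in loci) {
        m <- locusGenotypes(gt, l)
        ok <- !is.na(m[, 1])
        K[l] <- length(unique(c(m[ok, 1], m[ok, 2])))
        for (p in pops) {
            sel <- ok & populations(gt) == p
            tab <- table(c(m[sel, 1], m[sel, 2]))
            counts[[p]][[l]] <- stats::setNames(as.integer(tab), names(tab))
        }
    }
    list(counts = counts, K = K)
}

#' Leave-one-out self-assignment test
#'
#' Each individual is removed from its own population's allele counts and
#' scored against every population with the Rannala-Mountain criterion; it
#' is assigned to the highest-likelihood population (ties broken by input
#' order, with a warning). Population accuracy is the percentage assigned
#' back to the true population; region accuracy the percentage whose
#' assigned population lies in the true region.
#'
#' @param gt a \linkS4class{GenotypeTable} (>= 2 populations)
#' @return list: \code{assignments} data.frame (sample_id, true/assigned
#'   population and region, correct flags), \code{population_summary},
#'   \code{region_summary}, \code{mean_population_accuracy},
#'   \code{mean_region_accuracy}
#' @export
selfAssignment <- function(gt) {
    pops <- unique(populations(gt))
    if (length(pops) < 2L) stop("need at least 2 populations")
    ref <- .ref_counts(gt)
    loci <- lociNames(gt)
    popRegion <- stats::setNames(
        sampleData(gt)$region[match(pops, populations(gt))], pops)
    n <- nSamples(gt)
    assigned <- character(n)
    ties <- 0L
    for (i in seq_len(n)) {
        prof <- ssrProfile(gt, i)
        own <- populations(gt)[i]
        ## leave-one-out: subtract this individual's alleles from its own pop
        ownCounts <- ref$counts[[own]]
        looCounts <- ownCounts
        for (l in loci) {
            g <- prof[l, ]
            if (any(is.na(g))) next
            for (a in as.character(g)) {
                looCounts[[l]][a] <- looCounts[[l]][a] - 1L
            }
        }
        scores <- vapply(pops, function(p) {
            cts <- if (p == own) looCounts else ref$counts[[p]]
            rannalaMountainLoglik(prof, cts, ref$K)
        }, numeric(1))
        best <- which(scores == max(scores))
        if (length(best) > 1L) ties <- ties + 1L
        assigned[i] <- pops[best[1]]
    }
    if (ties > 0L)
        warning(ties, " tie(s) broken by population input order")
    truePop <- populations(gt)
    trueReg <- regions(gt)
    assignedReg <- unname(popRegion[assigned])
    df <- data.frame(sample_id = sampleIDs(gt),
                     true_population = truePop,
                     assigned_population = assigned,
                     correct_population = truePop == assigned,
                     true_region = trueReg,
                     assigned_region = assignedReg,
                     correct_region = !is.na(trueReg) & trueReg == assignedReg,
                     stringsAsFactors = FALSE)
    popSum <- do.call(rbind, lapply(pops, function(p) {
        sel <- df$true_population == p
        data.frame(population = p, n = sum(sel),
                   correct = sum(df$correct_population[sel]),
                   accuracy = 100 * mean(df$correct_population[sel]))
    }))
    regSum <- if (any(!is.na(trueReg))) {
        regs <- unique(trueReg)
        do.call(rbind, lapply(regs, function(r) {
            sel <- df$true_region == r
            data.frame(region = r, n = sum(sel),
                       correct = sum(df$correct_region[sel]),
                       accuracy = 100 * mean(df$correct_region[sel]))
        }))
    } else NULL
    list(assignments = df,
         population_summary = popSum,
         region_summary = regSum,
         mean_population_accuracy = 100 * mean(df$correct_population),
         mean_region_accuracy = if (is.null(regSum)) NA_real_
                                else 100 * mean(df$correct_region))
}
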