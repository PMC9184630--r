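#' Per-locus descriptive and forensic parameters
#'
#' For one locus within one group computes the number of alleles (A),
#' observed heterozygosity (Ho), unbiased expected heterozygosity
#' He = (2n/(2n-1)) (1 - sum p_i^2), polymorphic information content
#' PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2, matching probability
#' MP = sum of squared observed genotype proportions, and power of
#' discrimination PD = 1 - MP. Missing calls are dropped per locus
#' (pairwise deletion).
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param locus locus name
#' @param group group label (a population, a region, or \code{"combined"})
#' @param grouping which label set \code{group} refers to
#' @return one-row data.frame: locus, group, n, A, Ho, He, PIC, MP, PD
#' @export
locusSummary <- function(gt, locus, group,
                         grouping = c("population", "region", "combined")) {
    grouping <- match.arg(grouping)
    idx <- .group_index(gt, group, grouping)
    m <- locusGenotypes(gt, locus)[idx, , drop = FALSE]
    m <- m[!is.na(m[, 1]), , drop = FALSE]
    n <- nrow(m)
    if (n == 0L)
        stop("no non-missing genotypes at locus '", locus, "' in group '",
             group, "'")
    p <- as.numeric(table(c(m[, 1], m[, 2]))) / (2 * n)
    sum2 <- sum(p^2)
    He <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum2) else NA_real_
    PIC <- 1 - sum2 - (sum(outer(p^2, p^2))- sum(p^4))  # 2*sum_{i<j} p_i^2 p_j^2
    geno <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    fg <- as.numeric(table(geno)) / n
    MP <- sum(fg^2)
    data.frame(locus = locus, group = group, n = n,
               A = length(p),
               Ho = mean(m[, 1] != m[, 2]),
               He = He, PIC = PIC, MP = MP, PD = 1 - MP,
               stringsAsFactors = FALSE)
}

## He and PIC directly from an allele-frequency vector (no genotype data);
## n gives the unbiased correction, NULL for the uncorrected 1 - sum p^2.
#' Expected heterozygosity and PIC from allele frequencies
#'
#' @param p allele-frequency vector (sums to 1)
#' @param n number of individuals for the unbiased (2n/(2n-1)) correction of
#'   He; \code{NULL} for the uncorrected gene diversity
#' @return named vector with \code{He} and \code{PIC}
#' @export
freqDiversity <- function(p, n = NULL) {
    stopifnot(abs(sum(p) - 1) < 1e-6)
    sum2 <- sum(p^2)
    He <- 1 - sum2
    if (!is.null(n)) He <- He * (2 * n) / (2 * n - 1)
    PIC <- 1 - sum2 - (sum(outer(p^2, p^2)) - sum(p^4))
    c(He = He, PIC = PIC)
}

.group_index <- function(gt, group, grouping) {
    lab <- switch(grouping,
        population = populations(gt),
        region = regions(gt),
        combined = rep("combined", nSamples(gt)))
    idx <- which(lab == group)
    if (length(idx) == 0L) stop("unknown group '", group, "'")
    idx
}

#' Forensic parameter table for all loci
#'
#' Assembles the per-locus forensic summary (A, Ho, He, PIC, HWE p-value,
#' MP, PD) for each group, in the shape of a published forensic
#' characterisation table.
#'
#' @inheritParams locusSummary
#' @param groups group labels to summarise (default: all in the grouping)
#' @param nPerm HWE Monte-Carlo permutations (0 to skip the HWE column)
#' @param seed seed for the HWE permutations
#' @return data.frame, loci x groups rows
#' @export
forensicStats <- function(gt, grouping = c("region", "population", "combined"),
                          groups = NULL, nPerm = 10000, seed = 1) {
    grouping <- match.arg(grouping)
    lab <- switch(grouping, population = populations(gt),
                  region = regions(gt),
                  combined = rep("combined", nSamples(gt)))
    if (is.null(groups)) groups <- unique(lab)
    out <- list()
    for (g in groups) for (l in lociNames(gt)) {
        row <- locusSummary(gt, l, g, grouping)
        row$HWE <- if (nPerm > 0)
            hweExactTest(gt, l, g, grouping, nPerm = nPerm, seed = seed)$p
        else NA_real_
        out[[length(out) + 1L]] <- row
    }
    res <- do.call(rbind, out)
    res[, c("group", "locus", "n", "A", "Ho", "He", "PIC", "HWE", "MP", "PD")]
}

#' Hardy-Weinberg exact test (Monte Carlo)
#'
#' Guo-Thompson-style Monte-Carlo exact test: the 2n observed alleles at the
#' locus are repeatedly shuffled into n random diploid genotypes and each
#' shuffled genotype array is ranked against the observed one by its
#' conditional probability given the allele counts (computed up to the
#' shared constant as h log 2 - sum log(n_gt!), h = number of
#' heterozygotes). The p-value is (number of arrays as or less probable
#' than observed + 1) / (nPerm + 1).
#'
#' @inheritParams locusSummary
#' @param nPerm number of Monte-Carlo shuffles
#' @param seed integer seed (deterministic results for a fixed seed)
#' @return list: \code{p}, \code{nPerm}, \code{monomorphic} flag
#' @export
hweExactTest <- function(gt, locus, group,
                         grouping = c("population", "region", "combined"),
                         nPerm = 10000, seed = 1) {
    grouping <- match.arg(grouping)
    idx <- .group_index(gt, group, grouping)
    m <- locusGenotypes(gt, locus)[idx, , drop = FALSE]
    m <- m[!is.na(m[, 1]), , drop = FALSE]
    alleles <- c(m[, 1], m[, 2])
    if (length(unique(alleles)) < 2L)
        return(list(p = 1, nPerm = 0L, monomorphic = TRUE))
    restore <- .with_seed(seed)
    on.exit(restore())
    n <- nrow(m)
    statObs <- .hwe_stat(m[, 1], m[, 2])
    hits <- 0L
    for (b in seq_len(nPerm)) {
        perm <- sample(alleles)
        a1 <- perm[seq_len(n)]
        a2 <- perm[n + seq_len(n)]
        if (.hwe_stat(a1, a2) <= statObs + 1e-12) hits <- hits + 1L
    }
    list(p = (hits + 1) / (nPerm + 1), nPerm = as.integer(nPerm),
         monomorphic = FALSE)
}

## log conditional probability of a genotype array given allele counts,
## up to a constant: h*log(2) - sum over genotype cells of log(count!)
.hwe_stat <- function(a1, a2) {
    h <- sum(a1 != a2)
    cnt <- table(paste(pmin(a1, a2), pmax(a1, a2)))
    h * log(2) - sum(lfactorial(as.numeric(cnt)))
}

#' Linkage-disequilibrium exact test (permutation)
#'
#' Permutation test of genotypic association between two loci: the second
#' locus's single-locus genotypes are shuffled among individuals, and the
#' G statistic (log-likelihood-ratio) of the two-locus genotype contingency
#' table is compared with its permutation distribution. Individuals missing
#' at either locus are dropped (pairwise deletion).
#'
#' @inheritParams locusSummary
#' @param locusA,locusB locus names
#' @param nPerm permutations
#' @param seed integer seed
#' @return list: \code{p}, \code{G}, \code{n}; \code{p} is NA with a
#'   message when fewer than 5 individuals are available
#' @export
ldExactTest <- function(gt, locusA, locusB, group,
                        grouping = c("population", "region", "combined"),
                        nPerm = 5000, seed = 1) {
    grouping <- match.arg(grouping)
    idx <- .group_index(gt, group, grouping)
    ma <- locusGenotypes(gt, locusA)[idx, , drop = FALSE]
    mb <- locusGenotypes(gt, locusB)[idx, , drop = FALSE]
    ok <- !is.na(ma[, 1]) & !is.na(mb[, 1])
    if (sum(ok) < 5L)
        return(list(p = NA_real_, G = NA_real_, n = sum(ok)))
    ga <- factor(paste(ma[ok, 1], ma[ok, 2]))
    gb <- factor(paste(mb[ok, 1], mb[ok, 2]))
    if (nlevels(ga) < 2L || nlevels(gb) < 2L)
        return(list(p = NA_real_, G = NA_real_, n = sum(ok)))
    restore <- .with_seed(seed)
    on.exit(restore())
    gObs <- .g_stat(table(ga, gb))
    hits <- 0L
    for (b in seq_len(nPerm)) {
        if (.g_stat(table(ga, sample(gb))) >= gObs - 1e-12) hits <- hits + 1L
    }
    list(p = (hits + 1) / (nPerm + 1), G = gObs, n = sum(ok))
}

.g_stat <- function(tab) {
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    o <- as.numeric(tab)
    e <- as.numeric(e)
    pos <- o > 0
    2 * sum(o[pos] * log(o[pos] / e[pos]))
}

#' All pairwise LD tests within a group
#'
#' @inheritParams ldExactTest
#' @return data.frame with one row per unordered locus pair
#' @export
ldAllPairs <- function(gt, group,
                       grouping = c("region", "population", "combined"),
                       nPerm = 5000, seed = 1) {
    grouping <- match.arg(grouping)
    loci <- lociNames(gt)
    pairs <- utils::combn(loci, 2)
    out <- lapply(seq_len(ncol(pairs)), function(k) {
        r <- ldExactTest(gt, pairs[1, k], pairs[2, k], group, grouping,
                         nPerm = nPerm, seed = seed + k)
        data.frame(locusA = pairs[1, k], locusB = pairs[2, k],
                   G = r$G, n = r$n, p = r$p, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Bonferroni correction
#'
#' Flags p-values significant at the Bonferroni-adjusted threshold
#' alpha / k. With 10 tests at alpha = 0.05 the threshold is 0.0050.
#'
#' @param pvals vector of p-values
#' @param alpha familywise significance level
#' @return list: \code{threshold}, logical \code{significant}, \code{k}
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
    stopifnot(length(pvals) >= 1)
    k <- length(pvals)
    thr <- alpha / k
    list(threshold = thr, significant = !is.na(pvals) & pvals < thr, k = k)
}
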