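#' Weir-Cockerham variance components for one locus
#'
#' Per-allele components a (among populations), b (among individuals within
#' populations) and c (within individuals) of the 1984 analysis-of-variance
#' estimator, summed over alleles. Populations with no non-missing call at
#' the locus are dropped for that locus.
#'
#' @param m integer matrix n x 2 of allele pairs (NA rows = missing)
#' @param pop character/factor of population labels, length n
#' @return named vector \code{c(a =, b =, c =)}; all zero when the locus is
#'   monomorphic among the genotyped individuals
#' @keywords internal
.wc_components <- function(m, pop) {
    ok <- !is.na(m[, 1])
    m <- m[ok, , drop = FALSE]
    pop <- factor(pop[ok])
    pop <- droplevels(pop)
    r <- nlevels(pop)
    if (r < 2L) return(c(a = 0, b = 0, c = 0))
    ni <- as.numeric(table(pop))
    nbar <- mean(ni)
    nC <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(m[, 1], m[, 2])))
    if (length(alleles) < 2L) return(c(a = 0, b = 0, c = 0))
    A <- B <- C <- 0
    for (al in alleles) {
        x <- (m[, 1] == al) + (m[, 2] == al)       # allele dosage per ind
        het <- (m[, 1] == al) != (m[, 2] == al)    # heterozygous for al
        pi <- tapply(x, pop, sum) / (2 * ni)
        hi <- tapply(het, pop, mean)
        pbar <- sum(ni * pi) / (r * nbar)
        s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(ni * hi) / (r * nbar)
        a <- (nbar / nC) *
            (s2 - (1 / (nbar - 1)) *
                 (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
        b <- (nbar / (nbar - 1)) *
            (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                 ((2 * nbar - 1) / (4 * nbar)) * hbar)
        cc <- hbar / 2
        A <- A + a; B <- B + b; C <- C + cc
    }
    c(a = A, b = B, c = C)
}

#' Weir-Cockerham coancestry and inbreeding coefficients
#'
#' Multi-locus, multi-allelic estimates of theta (coancestry, F_ST),
#' f (inbreeding within populations, F_IS) and F (overall, F_IT) by summing
#' the variance components over alleles and loci (ratio of sums, never an
#' average of per-locus ratios). Missing genotypes enter through per-locus
#' sample sizes.
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param populations population label per sample; defaults to the table's
#'   population column
#' @param loci loci to use (default all)
#' @return an \linkS4class{FStatResult} without confidence intervals
#'   (see \code{\link{fstatBootstrap}})
#' @export
weirCockerham <- function(gt, populations = NULL, loci = NULL) {
    if (is.null(populations)) populations <- populations(gt)
    stopifnot(length(populations) == nSamples(gt))
    if (length(unique(populations)) < 2L)
        stop("need at least 2 populations")
    if (is.null(loci)) loci <- lociNames(gt)
    comp <- vapply(loci, function(l)
        .wc_components(locusGenotypes(gt, l), populations), numeric(3))
    tot <- rowSums(comp)
    denom <- sum(tot)
    if (denom == 0)
        stop("all loci monomorphic: F-statistics undefined")
    new("FStatResult", level = "all",
        theta = unname(tot["a"] / denom),
        f = unname(1 - tot["c"] / (tot["b"] + tot["c"])),
        Fit = unname(1 - tot["c"] / denom),
        ci = matrix(NA_real_, 2, 2,
                    dimnames = list(c("theta", "f"), c("2.5%", "97.5%"))),
        nBoot = 0L)
}

#' Bootstrap confidence intervals for theta and f
#'
#' Resamples loci with replacement (the locus is the bootstrap unit) and
#' recomputes the Weir-Cockerham estimates, reporting percentile 2.5/97.5
#' bounds. An estimate is flagged significantly greater than zero when its
#' 95\% interval excludes 0.
#'
#' @inheritParams weirCockerham
#' @param nBoot bootstrap replicates
#' @param seed integer seed
#' @param level label stored on the result
#' @return an \linkS4class{FStatResult} with percentile CIs
#' @export
fstatBootstrap <- function(gt, populations = NULL, nBoot = 1000, seed = 1,
                           level = "all") {
    if (is.null(populations)) populations <- populations(gt)
    loci <- lociNames(gt)
    if (length(loci) < 2L) stop("need at least 2 loci to bootstrap")
    point <- weirCockerham(gt, populations)
    ## per-locus components computed once, resampled many times
    comp <- vapply(loci, function(l)
        .wc_components(locusGenotypes(gt, l), populations), numeric(3))
    restore <- .with_seed(seed)
    on.exit(restore())
    reps <- matrix(NA_real_, nBoot, 2, dimnames = list(NULL, c("theta", "f")))
    for (b in seq_len(nBoot)) {
        tot <- rowSums(comp[, sample.int(length(loci), replace = TRUE),
                            drop = FALSE])
        if (sum(tot) > 0) {
            reps[b, "theta"] <- tot["a"] / sum(tot)
            reps[b, "f"] <- 1 - tot["c"] / (tot["b"] + tot["c"])
        }
    }
    ci <- rbind(theta = stats::quantile(reps[, "theta"], c(.025, .975),
                                        na.rm = TRUE, names = FALSE),
                f = stats::quantile(reps[, "f"], c(.025, .975),
                                    na.rm = TRUE, names = FALSE))
    colnames(ci) <- c("2.5%", "97.5%")
    methods::initialize(point, level = level, ci = ci,
                        nBoot = as.integer(nBoot))
}

#' Is an estimate significantly greater than zero?
#' @param x an \linkS4class{FStatResult} with bootstrap CIs
#' @return named logical for theta and f (CI excludes 0)
#' @export
significantlyPositive <- function(x) {
    stopifnot(methods::is(x, "FStatResult"))
    c(theta = unname(x@ci["theta", 1] > 0), f = unname(x@ci["f", 1] > 0))
}
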