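# in-code fixture builders shared across test files

# genotype table from a list of per-locus n x 2 allele matrices
makeGT <- function(locusList, populations, regions = NULL, ids = NULL) {
    n <- nrow(locusList[[1]])
    if (is.null(names(locusList)))
        names(locusList) <- sprintf("L%02d", seq_along(locusList))
    if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
    a <- array(NA_integer_, c(n, length(locusList), 2L),
               dimnames = list(ids, names(locusList), NULL))
    for (k in seq_along(locusList)) {
        m <- locusList[[k]]
        a[, k, 1] <- pmin(m[, 1], m[, 2])
        a[, k, 2] <- pmax(m[, 1], m[, 2])
    }
    sd <- data.frame(sample_id = ids, population = populations,
                     stringsAsFactors = FALSE)
    if (!is.null(regions)) sd$region <- regions
    GenotypeTable(a, sd)
}

# single-group allele-frequency db straight from named frequency vectors
makeFreqDb <- function(freqsByLocus, group = "G", n = 100, floor = NA_real_) {
    rows <- do.call(rbind, lapply(names(freqsByLocus), function(l) {
        p <- freqsByLocus[[l]]
        data.frame(group = group, locus = l,
                   allele = as.integer(names(p)),
                   count = as.integer(round(p * 2 * n)),
                   frequency = as.numeric(p),
                   freq_floored = if (is.na(floor)) as.numeric(p)
                                  else pmax(as.numeric(p), floor),
                   n_individuals = n, stringsAsFactors = FALSE)
    }))
    new("AlleleFreqDB", grouping = "combined", freqTable = rows,
        groupSizes = stats::setNames(as.integer(n), group),
        floor = stats::setNames(floor, group))
}

# exact two-allele Hardy-Weinberg test by enumeration of heterozygote counts
# (independent of the package's Monte-Carlo path)
hweExact2 <- function(n11, n12, n22) {
    n <- n11 + n12 + n22
    n1 <- 2 * n11 + n12
    n2 <- 2 * n22 + n12
    hs <- seq(n1 %% 2, min(n1, n2), by = 2)
    logp <- vapply(hs, function(h) {
        a <- (n1 - h) / 2; b <- (n2 - h) / 2
        lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
            h * log(2) + lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n)
    }, numeric(1))
    p <- exp(logp)
    sum(p[p <= p[match(n12, hs)] * (1 + 1e-9)])
}
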