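#' Build an allele-frequency database
#'
#' Counts alleles per locus within each group (population, region, or the
#' whole table combined). Individuals missing at a locus are excluded from
#' that locus's denominator only; frequencies are allele count divided by
#' twice the number of non-missing individuals.
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param grouping \code{"population"}, \code{"region"} or \code{"combined"}
#' @return an \linkS4class{AlleleFreqDB} (no floor applied;
#'   see \code{\link{applyFloor}})
#' @export
buildAlleleDb <- function(gt, grouping = c("population", "region", "combined")) {
    grouping <- match.arg(grouping)
    stopifnot(nSamples(gt) >= 1)
    grp <- switch(grouping,
        population = populations(gt),
        region = {
            if (all(is.na(regions(gt))))
                stop("no region labels; supply a regionMap when reading")
            regions(gt)
        },
        combined = rep("combined", nSamples(gt)))
    loci <- lociNames(gt)
    rows <- list()
    for (g in unique(grp)) {
        idx <- which(grp == g)
        for (l in loci) {
            m <- locusGenotypes(gt, l)[idx, , drop = FALSE]
            ok <- !is.na(m[, 1])
            if (!any(ok)) {
                warning("group '", g, "' has no non-missing calls at locus '",
                        l, "'")
                next
            }
            cnt <- table(c(m[ok, 1], m[ok, 2]))
            rows[[length(rows) + 1L]] <- data.frame(
                group = g, locus = l,
                allele = as.integer(names(cnt)),
                count = as.integer(cnt),
                frequency = as.numeric(cnt) / (2 * sum(ok)),
                n_individuals = sum(ok),
                stringsAsFactors = FALSE)
        }
    }
    ft <- do.call(rbind, rows)
    ft$freq_floored <- ft$frequency
    gs <- vapply(unique(grp), function(g) sum(grp == g), integer(1))
    new("AlleleFreqDB", grouping = grouping, freqTable = ft,
        groupSizes = gs,
        floor = stats::setNames(rep(NA_real_, length(gs)), names(gs)))
}

#' Minimum allele frequency floor
#'
#' The 5/(2N) rule for the smallest allele frequency a forensic database of N
#' diploid individuals should report, rounded half-up to 4 decimal places.
#' For the two regional databases of the reference study (N = 381 and
#' N = 1029) this gives 0.0066 and 0.0024.
#'
#' @param nIndividuals database sample size (diploid individuals)
#' @return the floor frequency, rounded to 4 decimals
#' @export
minAlleleFloor <- function(nIndividuals) {
    stopifnot(length(nIndividuals) >= 1, all(nIndividuals >= 1))
    raw <- 5 / (2 * nIndividuals)
    ## round half-up at the 4th decimal
    floor(raw * 1e4 + 0.5) / 1e4
}

#' Apply a minimum-allele-frequency floor
#'
#' Replaces every frequency below the floor by the floor in the
#' \code{freq_floored} column; raw frequencies are kept unchanged. Floored
#' frequencies are deliberately not renormalised (conservative forensic
#' convention). Idempotent; never lowers a frequency.
#'
#' @param db an \linkS4class{AlleleFreqDB}
#' @param floor numeric floor, or \code{"auto"} for 5/(2N) per group
#' @return the db with floors applied
#' @export
applyFloor <- function(db, floor = "auto") {
    ft <- db@freqTable
    if (identical(floor, "auto")) {
        fl <- minAlleleFloor(groupSizes(db))
    } else {
        stopifnot(is.numeric(floor), all(floor > 0))
        if (any(floor >= 1)) stop("floor must be < 1")
        fl <- stats::setNames(rep(floor, length.out = length(groupSizes(db))),
                              groupNames(db))
    }
    ft$freq_floored <- pmax(ft$frequency, unname(fl[ft$group]))
    methods::initialize(db, freqTable = ft, floor = fl)
}
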