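#' d statistic for one profile
#'
#' Compares the full-profile frequency of an individual computed from its
#' cognate (own-population) database, P_origin, with the frequency computed
#' from the pooled regional database, P_combined:
#' d = log10(P_origin / P_combined). Negative d means the regional database
#' overstates the profile frequency for this individual, i.e. it is
#' conservative (it understates the weight of evidence).
#'
#' By default P_origin treats the cognate population as the subpopulation
#' itself (theta = 0) while keeping the regional inbreeding estimate, and
#' P_combined uses the regional frequencies with the calibration theta.
#'
#' @param profile loci x 2 matrix (see \code{\link{ssrProfile}})
#' @param cognateDb \linkS4class{AlleleFreqDB} holding the individual's own
#'   population frequencies (floored)
#' @param cognateGroup group name in \code{cognateDb}
#' @param combinedDb regional \linkS4class{AlleleFreqDB} (floored)
#' @param combinedGroup group name in \code{combinedDb}
#' @param thetaOrigin,fOrigin params for P_origin (default theta 0)
#' @param thetaCombined,fCombined params for P_combined
#' @param mode genotype-frequency mode for both sides
#' @return list: \code{P_origin}, \code{P_combined}, \code{d}
#' @export
dStatistic <- function(profile, cognateDb, cognateGroup,
                       combinedDb, combinedGroup,
                       thetaOrigin = 0, fOrigin = 0,
                       thetaCombined = 0, fCombined = 0,
                       mode = c("conditional-match",
                                "unconditional-frequency")) {
    mode <- match.arg(mode)
    po <- profileFrequency(profile, cognateDb, cognateGroup,
                           theta = thetaOrigin, f = fOrigin, mode = mode)
    pc <- profileFrequency(profile, combinedDb, combinedGroup,
                           theta = thetaCombined, f = fCombined, mode = mode)
    if (po <= 0 || pc <= 0)
        stop("zero profile probability; apply a frequency floor first")
    list(P_origin = po, P_combined = pc, d = log10(po) - log10(pc))
}

#' Conservativeness evaluation of a regional database
#'
#' Computes the d statistic for every individual with a complete profile:
#' P_origin from the individual's own population database, P_combined from
#' the pooled regional database. Individuals with any missing locus are
#' excluded (and reported).
#'
#' @param gt a \linkS4class{GenotypeTable} restricted to one region
#' @param popDb population-grouping \linkS4class{AlleleFreqDB} (floored)
#' @param regionalDb \linkS4class{AlleleFreqDB} with the pooled group
#' @param regionalGroup pooled group name in \code{regionalDb}
#' @param theta calibration coancestry used in P_combined
#' @param f inbreeding coefficient (applied on both sides in unconditional
#'   mode; ignored by the conditional-match formulas)
#' @param mode genotype-frequency mode
#' @return list: \code{records} data.frame (sample_id, population, P_origin,
#'   P_combined, d), \code{n_excluded}, \code{n_nonconservative},
#'   \code{frac_nonconservative}
#' @export
evaluateConservativeness <- function(gt, popDb, regionalDb, regionalGroup,
                                     theta, f = 0,
                                     mode = c("conditional-match",
                                              "unconditional-frequency")) {
    mode <- match.arg(mode)
    stopifnot(nSamples(gt) >= 1)
    complete <- !apply(is.na(gt@alleles[, , 1, drop = FALSE]), 1, any)
    recs <- vector("list", sum(complete))
    k <- 0L
    for (i in which(complete)) {
        prof <- ssrProfile(gt, i)
        r <- dStatistic(prof, popDb, populations(gt)[i],
                        regionalDb, regionalGroup,
                        thetaOrigin = 0, fOrigin = f,
                        thetaCombined = theta, fCombined = f, mode = mode)
        k <- k + 1L
        recs[[k]] <- data.frame(sample_id = sampleIDs(gt)[i],
                                population = populations(gt)[i],
                                P_origin = r$P_origin,
                                P_combined = r$P_combined, d = r$d,
                                stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    list(records = records,
         n_excluded = sum(!complete),
         n_nonconservative = sum(records$d >= 0),
         frac_nonconservative = mean(records$d >= 0))
}

#' Calibrate theta until the database is conservative
#'
#' Walks theta up a fixed grid (\code{thetaInit + k * step}) recomputing
#' P_combined until every individual's d is negative, returning the smallest
#' such theta. In conditional-match mode P_combined is non-decreasing in
#' theta for homozygous and all but very-common-allele heterozygous loci, so
#' in practice the non-conservative set shrinks essentially monotonically and
#' the walk terminates or hits \code{thetaMax}. In
#' unconditional mode monotonicity is not guaranteed (all-heterozygote
#' profiles get rarer with theta); the walk is still performed but
#' non-convergence is reported rather than looping.
#'
#' @inheritParams evaluateConservativeness
#' @param thetaInit starting coancestry (e.g. the Weir-Cockerham estimate)
#' @param step grid step (default 0.005, reported at 4 decimals)
#' @param thetaMax upper bound of the search grid
#' @return list: \code{theta_initial}, \code{theta_adjusted}, \code{step},
#'   \code{n_positive_d_at_initial}, \code{converged}, \code{trace}
#'   (data.frame theta vs number of non-conservative individuals)
#' @export
adjustTheta <- function(gt, popDb, regionalDb, regionalGroup,
                        thetaInit, f = 0, step = 0.005, thetaMax = 0.5,
                        mode = c("conditional-match",
                                 "unconditional-frequency")) {
    mode <- match.arg(mode)
    stopifnot(step > 0, thetaMax < 1, thetaInit >= 0)
    grid <- seq(thetaInit, thetaMax, by = step)
    trace <- data.frame(theta = round(grid, 4), n_nonconservative = NA_integer_)
    nPosInit <- NA_integer_
    for (k in seq_along(grid)) {
        ev <- evaluateConservativeness(gt, popDb, regionalDb, regionalGroup,
                                       theta = grid[k], f = f, mode = mode)
        trace$n_nonconservative[k] <- ev$n_nonconservative
        if (k == 1L) nPosInit <- ev$n_nonconservative
        if (ev$n_nonconservative == 0L) {
            return(list(theta_initial = thetaInit,
                        theta_adjusted = round(grid[k], 4), step = step,
                        n_positive_d_at_initial = nPosInit,
                        converged = TRUE, trace = trace[seq_len(k), ]))
        }
        if (mode == "unconditional-frequency" && k > 1L &&
                ev$n_nonconservative > trace$n_nonconservative[k - 1L]) {
            warning("non-monotone behaviour in unconditional mode; ",
                    "reporting non-convergence")
            return(list(theta_initial = thetaInit, theta_adjusted = NA_real_,
                        step = step, n_positive_d_at_initial = nPosInit,
                        converged = FALSE, trace = trace[seq_len(k), ]))
        }
    }
    list(theta_initial = thetaInit, theta_adjusted = NA_real_, step = step,
         n_positive_d_at_initial = nPosInit, converged = FALSE, trace = trace)
}
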