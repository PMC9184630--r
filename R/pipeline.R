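#' Run the full database-construction and evaluation pipeline
#'
#' Orchestrates the standard analysis over a genotype table: regional and
#' population allele-frequency databases with 5/(2N) floors, per-locus
#' forensic statistics with HWE tests, pairwise LD tests, Weir-Cockerham
#' theta/f with locus bootstraps per level, extreme-profile frequencies and
#' random match probabilities, conservativeness calibration of theta per
#' region, leave-one-out self-assignment, and the Nei DA / UPGMA population
#' tree with bootstrap support. Results are returned as a list and, when
#' \code{outDir} is given, written as CSV / Newick / plain-text files with
#' the seed and settings recorded in a provenance file.
#'
#' @param gt a \linkS4class{GenotypeTable} with region labels
#' @param outDir output directory (NULL: return results only)
#' @param nPermHWE Monte-Carlo permutations for the HWE tests
#' @param nPermLD permutations per LD test (0 skips the LD stage)
#' @param nBoot bootstrap replicates for F-statistics and the tree
#' @param thetaStep calibration grid step
#' @param seed integer seed governing every stochastic stage
#' @return named list of stage results
#' @export
runPipeline <- function(gt, outDir = NULL, nPermHWE = 2000, nPermLD = 0,
                        nBoot = 200, thetaStep = 0.005, seed = 1) {
    stopifnot(methods::is(gt, "GenotypeTable"))
    if (all(is.na(regions(gt))))
        stop("region labels required: supply a regionMap when reading the ",
             "genotype table")
    res <- list(seed = seed)

    popDb <- applyFloor(buildAlleleDb(gt, "population"), "auto")
    regDb <- applyFloor(buildAlleleDb(gt, "region"), "auto")
    res$population_db <- popDb
    res$regional_db <- regDb
    res$floors <- floorValues(regDb)

    res$forensic_stats <- forensicStats(gt, "region", nPerm = nPermHWE,
                                        seed = seed)
    if (nPermLD > 0) {
        res$ld <- do.call(rbind, lapply(unique(regions(gt)), function(r) {
            data.frame(region = r,
                       ldAllPairs(gt, r, "region", nPerm = nPermLD,
                                  seed = seed))
        }))
    }

    regs <- unique(regions(gt))
    res$fstats <- list(
        combined = fstatBootstrap(gt, nBoot = nBoot, seed = seed,
                                  level = "combined"))
    for (r in regs) {
        sub <- gt[regions(gt) == r]
        if (length(unique(populations(sub))) >= 2L)
            res$fstats[[r]] <- fstatBootstrap(sub, nBoot = nBoot,
                                              seed = seed, level = r)
    }

    res$extreme <- lapply(stats::setNames(regs, regs), function(r) {
        th <- res$fstats[[r]]@theta
        fh <- res$fstats[[r]]@f
        ex <- extremeProfiles(regDb, r, theta = th, f = fh)
        list(theta = th, f = fh,
             most_common = ex$most_common, rarest = ex$rarest,
             rmp_most_common = randomMatchProbability(ex$most_common)$text,
             rmp_rarest = randomMatchProbability(ex$rarest)$text)
    })

    res$calibration <- lapply(stats::setNames(regs, regs), function(r) {
        sub <- gt[regions(gt) == r]
        adjustTheta(sub, popDb, regDb, r,
                    thetaInit = res$fstats[[r]]@theta,
                    f = res$fstats[[r]]@f, step = thetaStep)
    })

    res$assignment <- selfAssignment(gt)
    res$tree <- bootstrapTree(gt, nBoot = nBoot, seed = seed)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeAlleleFreqTable(regDb, file.path(outDir, "regional_freqs.csv"))
        writeAlleleFreqTable(popDb, file.path(outDir, "population_freqs.csv"))
        utils::write.csv(res$forensic_stats,
                         file.path(outDir, "forensic_stats.csv"),
                         row.names = FALSE)
        if (!is.null(res$ld))
            utils::write.csv(res$ld, file.path(outDir, "ld_tests.csv"),
                             row.names = FALSE)
        utils::write.csv(res$assignment$population_summary,
                         file.path(outDir, "assignment_populations.csv"),
                         row.names = FALSE)
        ape::write.tree(res$tree$tree, file.path(outDir, "upgma.nwk"))
        .write_summary(res, file.path(outDir, "summary.txt"))
    }
    res
}

.write_summary <- function(res, path) {
    ln <- c(sprintf("seed: %d", res$seed),
            sprintf("floor[%s] = %.4f", names(res$floors), res$floors))
    for (lv in names(res$fstats)) {
        x <- res$fstats[[lv]]
        ln <- c(ln, sprintf(
            "fstats %s: theta=%.4f [%.4f,%.4f] f=%.4f [%.4f,%.4f]",
            lv, x@theta, x@ci["theta", 1], x@ci["theta", 2],
            x@f, x@ci["f", 1], x@ci["f", 2]))
    }
    for (r in names(res$extreme)) {
        e <- res$extreme[[r]]
        ln <- c(ln, sprintf(
            "extreme %s: most common %.3g (%s), rarest %.3g (%s)",
            r, e$most_common, e$rmp_most_common, e$rarest, e$rmp_rarest))
        cal <- res$calibration[[r]]
        ln <- c(ln, sprintf(
            "calibration %s: theta %.4f -> %s (converged: %s)",
            r, cal$theta_initial,
            ifelse(is.na(cal$theta_adjusted), "none",
                   sprintf("%.4f", cal$theta_adjusted)),
            cal$converged))
    }
    ln <- c(ln, sprintf("assignment: population %.1f%%, region %.1f%%",
                        res$assignment$mean_population_accuracy,
                        res$assignment$mean_region_accuracy))
    writeLines(ln, path)
    invisible(path)
}
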