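test_that("d is zero against itself, matches hand arithmetic, antisymmetric", {
    db <- makeFreqDb(list(LA = c(`120` = 0.3, `124` = 0.7),
                          LB = c(`150` = 0.6, `154` = 0.4)))
    prof <- rbind(LA = c(120, 124), LB = c(150, 150))
    same <- dStatistic(prof, db, "G", db, "G",
                       thetaOrigin = 0.1, fOrigin = 0,
                       thetaCombined = 0.1, fCombined = 0)
    expect_equal(same$d, 0)

    dbB <- makeFreqDb(list(LA = c(`120` = 0.5, `124` = 0.5),
                           LB = c(`150` = 0.2, `154` = 0.8)), group = "H")
    r <- dStatistic(prof, db, "G", dbB, "H")
    po <- (2 * .3 * .7) * .6^2
    pc <- (2 * .5 * .5) * .2^2
    expect_equal(r$d, log10(po) - log10(pc))

    # antisymmetry under swapping the databases with their parameters
    fwd <- dStatistic(prof, db, "G", dbB, "H", thetaOrigin = 0,
                      thetaCombined = 0.05)
    rev <- dStatistic(prof, dbB, "H", db, "G", thetaOrigin = 0.05,
                      thetaCombined = 0)
    expect_equal(fwd$d, -rev$d)

    # alleles rare in the cognate database but common regionally push d down
    rare <- makeFreqDb(list(LA = c(`120` = 0.02, `124` = 0.98)), group = "pop")
    common <- makeFreqDb(list(LA = c(`120` = 0.60, `124` = 0.40)),
                         group = "reg")
    r2 <- dStatistic(rbind(LA = c(120, 120)), rare, "pop", common, "reg")
    expect_lt(r2$d, 0)
})

test_that("conservativeness evaluation is per-individual and deterministic", {
    gt <- simulateHierarchicalSSR(nRegions = 1, popsPerRegion = 4,
                                  nPerPop = 15, nLoci = 5,
                                  allelesPerLocus = 6, thetaPop = 0.08,
                                  fInbreed = 0.05, missingRate = 0.03,
                                  seed = 12)
    popDb <- applyFloor(buildAlleleDb(gt, "population"), "auto")
    regDb <- applyFloor(buildAlleleDb(gt, "combined"), "auto")
    ev1 <- evaluateConservativeness(gt, popDb, regDb, "combined",
                                    theta = 0.05, f = 0.05)
    ev2 <- evaluateConservativeness(gt, popDb, regDb, "combined",
                                    theta = 0.05, f = 0.05)
    expect_identical(ev1$records, ev2$records)
    # incomplete individuals excluded, the rest all scored
    expect_equal(nrow(ev1$records) + ev1$n_excluded, nSamples(gt))
    expect_true(all(ev1$records$P_origin > 0 & ev1$records$P_combined > 0))
    expect_equal(ev1$records$d,
                 log10(ev1$records$P_origin) - log10(ev1$records$P_combined))
})

test_that("raising theta shrinks the non-conservative set monotonically", {
    gt <- simulateHierarchicalSSR(nRegions = 1, popsPerRegion = 5,
                                  nPerPop = 20, nLoci = 6,
                                  allelesPerLocus = 6, thetaPop = 0.06,
                                  fInbreed = 0.08, seed = 23)
    popDb <- applyFloor(buildAlleleDb(gt, "population"), "auto")
    regDb <- applyFloor(buildAlleleDb(gt, "combined"), "auto")
    ns <- vapply(seq(0.05, 0.30, by = 0.05), function(th)
        evaluateConservativeness(gt, popDb, regDb, "combined", theta = th,
                                 f = 0.08)$n_nonconservative, numeric(1))
    expect_true(all(diff(ns) <= 0))
    # structured data at a low theta typically leaves non-conservative cases
    expect_gt(ns[1], 0)
})

test_that("theta calibration finds the grid-minimal conservative value", {
    gt <- simulateHierarchicalSSR(nRegions = 1, popsPerRegion = 5,
                                  nPerPop = 20, nLoci = 6,
                                  allelesPerLocus = 6, thetaPop = 0.06,
                                  fInbreed = 0.08, seed = 23)
    popDb <- applyFloor(buildAlleleDb(gt, "population"), "auto")
    regDb <- applyFloor(buildAlleleDb(gt, "combined"), "auto")
    cal <- adjustTheta(gt, popDb, regDb, "combined", thetaInit = 0.05,
                       f = 0.08, step = 0.005, thetaMax = 0.5)
    expect_true(cal$converged)
    expect_gte(cal$theta_adjusted, cal$theta_initial)
    atAdj <- evaluateConservativeness(gt, popDb, regDb, "combined",
                                      theta = cal$theta_adjusted, f = 0.08)
    expect_equal(atAdj$n_nonconservative, 0L)
    # minimality: one grid step below is still non-conservative
    below <- evaluateConservativeness(gt, popDb, regDb, "combined",
                                      theta = cal$theta_adjusted - 0.005,
                                      f = 0.08)
    expect_gt(below$n_nonconservative, 0)

    # already conservative: returns the starting value
    calHigh <- adjustTheta(gt, popDb, regDb, "combined",
                           thetaInit = cal$theta_adjusted, f = 0.08)
    expect_equal(calHigh$theta_adjusted, cal$theta_adjusted)
    expect_equal(calHigh$n_positive_d_at_initial, 0L)

    # no room to move: honest non-convergence
    calStuck <- adjustTheta(gt, popDb, regDb, "combined", thetaInit = 0.05,
                            f = 0.08, thetaMax = 0.05)
    expect_false(calStuck$converged)
    expect_true(is.na(calStuck$theta_adjusted))
})
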