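test_that("genotype frequencies reduce to the product rule and closed forms", {
    fr <- c(`120` = 0.2, `124` = 0.3, `128` = 0.5)
    expect_equal(genotypeFrequency(c(120, 124), fr, theta = 0, f = 0), 0.12)
    expect_equal(genotypeFrequency(c(120, 120), fr, theta = 0, f = 0.1),
                 0.1 * 0.2 + 0.9 * 0.04)
    # conditional-match mode at theta 0 is plain Hardy-Weinberg
    expect_equal(genotypeFrequency(c(120, 124), fr, theta = 0,
                                   mode = "conditional-match"), 0.12)
    expect_error(genotypeFrequency(c(120, 999), fr), "floor")
})

test_that("unconditional genotype frequencies sum to 1 over the genotype space", {
    fr <- c(`100` = 0.35, `102` = 0.25, `104` = 0.2, `106` = 0.15,
            `108` = 0.05)
    lab <- as.integer(names(fr))
    genos <- rbind(t(utils::combn(lab, 2)), cbind(lab, lab))
    for (theta in c(0, 0.05, 0.19, 0.45)) for (f in c(0, 0.0892, 0.3)) {
        tot <- sum(apply(genos, 1, genotypeFrequency, freqs = fr,
                         theta = theta, f = f))
        expect_equal(tot, 1, tolerance = 1e-12)
    }
})

test_that("theta moves the two modes in the documented directions", {
    fr <- c(`120` = 0.1, `124` = 0.6, `128` = 0.3)
    thetas <- seq(0, 0.45, by = 0.05)
    # conditional match probabilities: non-decreasing in theta for
    # homozygotes and for heterozygotes whose alleles are not both common
    # (p_i p_j <= (p_i + p_j) / 5)
    for (g in list(c(120, 120), c(124, 124), c(128, 128), c(120, 124),
                   c(120, 128))) {
        cond <- vapply(thetas, function(t)
            genotypeFrequency(g, fr, theta = t, mode = "conditional-match"),
            numeric(1))
        expect_true(all(diff(cond) >= -1e-12))
    }
    # ... while a heterozygote of two common alleles (0.6, 0.3) starts on
    # the non-monotone side of the boundary and dips
    common <- vapply(thetas, function(t)
        genotypeFrequency(c(124, 128), fr, theta = t,
                          mode = "conditional-match"), numeric(1))
    expect_lt(min(common), common[1] + 1e-12)
    het <- vapply(thetas, function(t)
        genotypeFrequency(c(120, 124), fr, theta = t), numeric(1))
    expect_true(all(diff(het) < 0))               # unconditional het decreases
})

test_that("profile frequency is the locus product, order-invariant, no imputation", {
    db <- makeFreqDb(list(LA = c(`120` = 0.3, `124` = 0.7),
                          LB = c(`150` = 0.6, `154` = 0.4)))
    prof <- rbind(LA = c(120, 124), LB = c(150, 150))
    expect_equal(profileFrequency(prof, db, "G"),
                 (2 * 0.3 * 0.7) * (0.6^2))
    # one locus reduces to genotypeFrequency
    expect_equal(profileFrequency(prof["LA", , drop = FALSE], db, "G"),
                 genotypeFrequency(c(120, 124), alleleFreqs(db, "G", "LA")))
    # locus order does not matter
    expect_equal(profileFrequency(prof[c("LB", "LA"), ], db, "G"),
                 profileFrequency(prof, db, "G"))
    # theta/f propagate per locus
    expect_equal(profileFrequency(prof, db, "G", theta = 0.19, f = 0.09),
                 genotypeFrequency(c(120, 124), alleleFreqs(db, "G", "LA"),
                                   0.19, 0.09) *
                 genotypeFrequency(c(150, 150), alleleFreqs(db, "G", "LB"),
                                   0.19, 0.09))
    bad <- rbind(LA = c(120, 124), LB = c(NA, NA))
    expect_error(profileFrequency(bad, db, "G"), "missing")
})

test_that("extreme profiles pick the right pairs and respect symmetry", {
    # every locus two equifrequent alleles: most common = rarest = 0.5^L
    db <- makeFreqDb(list(LA = c(`120` = 0.5, `124` = 0.5),
                          LB = c(`150` = 0.5, `152` = 0.5),
                          LC = c(`160` = 0.5, `162` = 0.5)))
    ex <- extremeProfiles(db, "G")
    expect_equal(ex$most_common, 0.5^3)
    expect_equal(ex$rarest, 0.5^3)

    # rarest profile uses floored frequencies
    db2 <- applyFloor(makeFreqDb(list(LA = c(`120` = 0.999, `124` = 0.001))),
                      0.0066)
    ex2 <- extremeProfiles(db2, "G")
    expect_equal(ex2$rarest, 2 * 0.999 * 0.0066)
    expect_equal(ex2$rarest_pairs$LA, c(120L, 124L))

    expect_error(extremeProfiles(makeFreqDb(list(LA = c(`120` = 1))), "G"),
                 "fewer than 2")
})

test_that("frequency ties break towards the smaller fragment size", {
    expect_equal(tieBreakExtremes(c(`120` = 0.4, `124` = 0.4,
                                    `130` = 0.2))$most_common, c(120L, 124L))
    expect_equal(tieBreakExtremes(c(`120` = 0.5, `124` = 0.3,
                                    `130` = 0.2))$most_common, c(120L, 124L))
    eq <- tieBreakExtremes(c(`130` = 0.25, `120` = 0.25, `124` = 0.25,
                             `140` = 0.25))
    expect_equal(eq$most_common, c(120L, 124L))
    expect_equal(eq$rarest, c(120L, 124L))
})

test_that("random match probabilities format as one-in-N statements", {
    expect_equal(randomMatchProbability(0.5)$text, "1 in 2")
    expect_equal(randomMatchProbability(0.5)$one_in, 2)
    expect_error(randomMatchProbability(0), "> 0")
})
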