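test_that("closed forms: equifrequent diallelic and monomorphic loci", {
    d <- freqDiversity(c(0.5, 0.5))
    expect_equal(unname(d["He"]), 0.5)
    expect_equal(unname(d["PIC"]), 0.375)

    gt <- makeGT(list(L1 = cbind(rep(120, 12), rep(120, 12))),
                 populations = rep("P", 12))
    s <- locusSummary(gt, "L1", "P")
    expect_equal(s$Ho, 0); expect_equal(s$He, 0); expect_equal(s$PIC, 0)
    expect_equal(s$MP, 1); expect_equal(s$PD, 0)
})

test_that("MP and PD match brute-force genotype enumeration", {
    set.seed(12)
    m <- cbind(sample(c(120L, 124L, 128L), 10, TRUE),
               sample(c(120L, 124L, 128L), 10, TRUE))
    gt <- makeGT(list(L1 = m), populations = rep("P", 10))
    s <- locusSummary(gt, "L1", "P")
    # brute force: count every distinct unordered genotype
    key <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    mp <- sum((table(key) / 10)^2)
    expect_equal(s$MP, mp)
    expect_equal(s$PD, 1 - mp)
    # unbiased He with hand-computed allele frequencies
    p <- as.numeric(table(c(m[, 1], m[, 2]))) / 20
    expect_equal(s$He, (20 / 19) * (1 - sum(p^2)))
})

test_that("PD + MP = 1, PIC <= He, and He ignores allele labels", {
    gt <- simulateHierarchicalSSR(nRegions = 1, popsPerRegion = 3,
                                  nPerPop = 25, nLoci = 6,
                                  allelesPerLocus = 7, fInbreed = 0.1,
                                  seed = 13)
    for (l in lociNames(gt)) {
        s <- locusSummary(gt, l, "combined", "combined")
        expect_equal(s$MP + s$PD, 1)
        expect_lte(s$PIC, s$He)
        expect_gte(s$PIC, 0)
    }
    # relabel alleles (order-reversing affine map) -> identical He/PIC/Ho
    gt2 <- gt
    gt2@alleles <- (1000L - gt@alleles)[, , 2:1, drop = FALSE]
    dimnames(gt2@alleles) <- dimnames(gt@alleles)
    s1 <- locusSummary(gt, "L01", "combined", "combined")
    s2 <- locusSummary(gt2, "L01", "combined", "combined")
    expect_equal(s2[c("Ho", "He", "PIC", "MP")], s1[c("Ho", "He", "PIC", "MP")])
})

test_that("the HWE Monte-Carlo test matches two-allele exact enumeration", {
    # strongly heterozygote-deficient: all homozygotes, two alleles at 0.5
    gt <- makeGT(list(L1 = cbind(rep(c(120L, 124L), each = 10),
                                 rep(c(120L, 124L), each = 10))),
                 populations = rep("P", 20))
    r <- hweExactTest(gt, "L1", "P", nPerm = 5000, seed = 1)
    expect_lt(r$p, 0.01)
    expect_lt(abs(r$p - hweExact2(10, 0, 10)), 0.005)

    # a moderate case: exact two-allele enumeration vs Monte Carlo
    gt2 <- makeGT(list(L1 = cbind(c(rep(120L, 9), rep(124L, 6), rep(120L, 5)),
                                  c(rep(120L, 9), rep(124L, 6), rep(124L, 5)))),
                  populations = rep("P", 20))
    r2 <- hweExactTest(gt2, "L1", "P", nPerm = 20000, seed = 2)
    expect_lt(abs(r2$p - hweExact2(9, 5, 6)), 0.02)

    # deterministic under a fixed seed; monomorphic flagged with p = 1
    r3 <- hweExactTest(gt2, "L1", "P", nPerm = 2000, seed = 7)
    r4 <- hweExactTest(gt2, "L1", "P", nPerm = 2000, seed = 7)
    expect_identical(r3$p, r4$p)
    mono <- makeGT(list(L1 = cbind(rep(120L, 8), rep(120L, 8))),
                   populations = rep("P", 8))
    rm <- hweExactTest(mono, "L1", "P")
    expect_equal(rm$p, 1); expect_true(rm$monomorphic)
})

test_that("the LD permutation test sees perfect association and enumerates pairs", {
    set.seed(30)
    a <- cbind(sample(c(120L, 124L), 50, TRUE), sample(c(120L, 124L), 50, TRUE))
    gt <- makeGT(list(L1 = a, L2 = a + 30L), populations = rep("P", 50))
    r <- ldExactTest(gt, "L1", "L2", "P", nPerm = 2000, seed = 1)
    expect_lte(r$p, 0.001)

    gt10 <- simulateHierarchicalSSR(nRegions = 1, popsPerRegion = 1,
                                    nPerPop = 12, nLoci = 10,
                                    allelesPerLocus = 4, seed = 2)
    pairs <- ldAllPairs(gt10, "combined", "combined", nPerm = 20, seed = 1)
    expect_equal(nrow(pairs), choose(10, 2))
    expect_equal(nrow(unique(pairs[, c("locusA", "locusB")])), 45L)
})

test_that("independently simulated loci reject at about the nominal rate", {
    # type-I error of the LD test under the null, 60 replicate locus pairs
    n <- 40
    reject <- vapply(seq_len(60), function(i) {
        set.seed(1000 + i)
        m1 <- cbind(sample(c(120L, 124L, 128L), n, TRUE),
                    sample(c(120L, 124L, 128L), n, TRUE))
        m2 <- cbind(sample(c(150L, 154L), n, TRUE),
                    sample(c(150L, 154L), n, TRUE))
        gt <- makeGT(list(L1 = m1, L2 = m2), populations = rep("P", n))
        ldExactTest(gt, "L1", "L2", "P", nPerm = 400, seed = i)$p < 0.05
    }, logical(1))
    # binomial 99% envelope around 0.05 for 60 trials
    expect_lte(sum(reject), qbinom(0.995, 60, 0.05))
})

test_that("Bonferroni thresholds and boundary flags are exact", {
    b <- bonferroni(rep(0.5, 10), alpha = 0.05)
    expect_equal(b$threshold, 0.0050)
    b2 <- bonferroni(c(0.0049, 0.0051, NA), alpha = 0.05)
    # threshold 0.05/3; check boundary behaviour at k = 10 explicitly
    b10 <- bonferroni(c(0.0049, 0.0051, rep(1, 8)), alpha = 0.05)
    expect_true(b10$significant[1])
    expect_false(b10$significant[2])
    expect_equal(bonferroni(0.2, alpha = 0.05)$threshold, 0.05)
})
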