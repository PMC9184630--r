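toyAln <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("marker alignments concatenate with recorded boundaries", {
    sim <- simulateCpDNA(seed = 7)   # default marker lengths 573/487/500/593
    cc <- concatenateAlignments(sim$alignments)
    expect_equal(unique(Biostrings::width(cc)), 2153L)
    b <- attr(cc, "boundaries")
    expect_equal(b$end - b$start + 1L, c(573L, 487L, 500L, 593L))

    one <- concatenateAlignments(sim$alignments[1])
    expect_equal(as.character(one), as.character(sim$alignments[[1]]))

    broken <- sim$alignments
    broken[[2]] <- broken[[2]][-1]
    expect_error(concatenateAlignments(broken), "not shared")
})

test_that("variable sites are found by hand-checkable rules", {
    # 2 SNP columns + one 3-bp gap run shared by 2 sequences = 3 sites
    aln <- toyAln(c(a = "ACGTACGTAA",
                    b = "ACCTACGTAA",
                    c = "ACGTA---AA",
                    d = "TCGTA---AA"))
    s <- findVariableSites(aln)
    expect_equal(sum(s$kind == "substitution"), 2L)
    expect_equal(sum(s$kind == "deletion"), 1L)
    del <- s[s$kind == "deletion", ]
    expect_equal(c(del$position, del$end), c(6L, 8L))
    expect_setequal(s$position[s$kind == "substitution"], c(1L, 3L))

    # identical sequences: nothing variable
    expect_equal(nrow(findVariableSites(toyAln(c(a = "ACGT", b = "ACGT")))), 0L)

    # overlapping but unequal gap runs split into separate events where the
    # carrier set changes: {c} at column 3, {b, c} over columns 4-6
    aln2 <- toyAln(c(a = "AAACCCAAA",
                     b = "AAA---AAA",
                     c = "AA----AAA"))
    s2 <- findVariableSites(aln2)
    expect_equal(sum(s2$kind == "deletion"), 2L)
    expect_equal(s2$position[s2$kind == "deletion"], c(3L, 4L))
    expect_equal(s2$end[s2$kind == "deletion"], c(3L, 6L))

    # N columns are missing data, not variation
    alnN <- toyAln(c(a = "ANGT", b = "AAGT"))
    expect_equal(nrow(findVariableSites(alnN)), 0L)
})

test_that("simulated substitution and deletion counts are recovered", {
    sim <- simulateCpDNA(substitutionSites = 21, deletionEvents = 7, seed = 3)
    s <- findVariableSites(concatenateAlignments(sim$alignments))
    expect_equal(sum(s$kind == "substitution"), 21L)
    expect_equal(sum(s$kind == "deletion"), 7L)
    expect_equal(nrow(s), 28L)
})

test_that("haplotype calling recovers the simulator truth exactly", {
    sim <- simulateCpDNA(seed = 11, nHaplotypesPerRegion = 3,
                         rareHaplotypeRate = 0.15)
    cc <- concatenateAlignments(sim$alignments)
    ht <- callHaplotypes(cc, findVariableSites(cc), sim$meta)
    a <- haplotypeAssignments(ht)[names(sim$truth)]
    expect_false(anyNA(a))
    # identical partitions (adjusted Rand index 1): every called haplotype
    # maps to exactly one truth label and vice versa
    tab <- table(a, sim$truth)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    # counts bookkeeping
    expect_equal(sum(haplotypeCounts(ht)), sum(!is.na(a)))
    expect_equal(rowSums(regionTotals(ht)), rowSums(haplotypeCounts(ht)))
    # H1 is the most frequent haplotype
    tot <- rowSums(haplotypeCounts(ht))
    expect_equal(names(which.max(tot)), "H1")
    expect_true(all(diff(tot) <= 0))
})

test_that("concatenation order changes coordinates, not haplotype membership", {
    sim <- simulateCpDNA(seed = 19, markerLengths = c(m1 = 300, m2 = 400),
                         substitutionSites = 12, deletionEvents = 4)
    fwd <- concatenateAlignments(sim$alignments)
    rev <- concatenateAlignments(sim$alignments[c(2, 1)])
    hf <- callHaplotypes(fwd, findVariableSites(fwd), sim$meta)
    hr <- callHaplotypes(rev, findVariableSites(rev), sim$meta)
    af <- haplotypeAssignments(hf); ar <- haplotypeAssignments(hr)
    tab <- table(af[names(ar)], ar)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("samples with N are assigned only when unambiguous", {
    aln <- toyAln(c(a = "ACGTACGT", b = "ACGTACGT",
                    c = "TCGTACGA", d = "TCGTACGA",
                    q1 = "NCGTACGT",   # matches neither uniquely (site 1 N,
                                       # but site 8 T pins it to hap a/b)
                    q2 = "NCGTACGN"))  # N at both variable sites: ambiguous
    meta <- data.frame(sample_id = c("a", "b", "c", "d", "q1", "q2"),
                       population = c("P1", "P1", "P2", "P2", "P1", "P1"),
                       region = c("RA", "RA", "RB", "RB", "RA", "RA"))
    sites <- findVariableSites(aln)
    ht <- callHaplotypes(aln, sites, meta)
    a <- haplotypeAssignments(ht)
    expect_equal(unname(a["q1"]), unname(a["a"]))
    expect_true(is.na(a["q2"]))
})

test_that("region inference distinguishes diagnostic, shared and unknown", {
    sim <- simulateCpDNA(seed = 11, nHaplotypesPerRegion = 3,
                         rareHaplotypeRate = 0.15)
    cc <- concatenateAlignments(sim$alignments)
    ht <- callHaplotypes(cc, findVariableSites(cc), sim$meta)
    rt <- regionTotals(ht)
    # every simulated haplotype is region-endemic by construction
    diag1 <- rownames(rt)[rowSums(rt > 0) == 1][1]
    r <- inferRegion(diag1, ht)
    expect_equal(r$status, "diagnostic")
    expect_equal(r$region, colnames(rt)[which(rt[diag1, ] > 0)])

    expect_equal(inferRegion("H999", ht)$status, "unknown")

    # force a shared haplotype in a hand-built table
    aln <- toyAln(c(a = "ACGT", b = "ACGT", c = "AGGT"))
    meta <- data.frame(sample_id = c("a", "b", "c"),
                       population = c("P1", "P2", "P2"),
                       region = c("RA", "RB", "RB"))
    ht2 <- callHaplotypes(aln, findVariableSites(aln), meta)
    shared <- haplotypeAssignments(ht2)[["a"]]
    r2 <- inferRegion(shared, ht2)
    expect_equal(r2$status, "shared")
    expect_setequal(r2$region, c("RA", "RB"))
})
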