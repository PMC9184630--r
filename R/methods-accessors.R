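#' Accessors for GenotypeTable
#'
#' @param x a \linkS4class{GenotypeTable}
#' @name GenotypeTable-accessors
#' @aliases nSamples nLoci lociNames sampleIDs populations regions
NULL

#' @rdname GenotypeTable-accessors
#' @export
setMethod("nSamples", "GenotypeTable", function(x) dim(x@alleles)[1])

#' @rdname GenotypeTable-accessors
#' @export
setMethod("nLoci", "GenotypeTable", function(x) dim(x@alleles)[2])

#' @rdname GenotypeTable-accessors
#' @export
setMethod("lociNames", "GenotypeTable", function(x) dimnames(x@alleles)[[2]])

#' @rdname GenotypeTable-accessors
#' @export
setMethod("sampleIDs", "GenotypeTable", function(x) x@sampleData$sample_id)

#' @rdname GenotypeTable-accessors
#' @export
setMethod("populations", "GenotypeTable", function(x) x@sampleData$population)

#' @rdname GenotypeTable-accessors
#' @export
setMethod("regions", "GenotypeTable", function(x) x@sampleData$region)

#' Allele pairs for one locus
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param locus locus name or index
#' @return integer matrix \code{n x 2} of allele labels (NA = missing)
#' @export
locusGenotypes <- function(gt, locus) {
    m <- gt@alleles[, locus, , drop = FALSE]
    dim(m) <- c(dim(gt@alleles)[1], 2L)
    rownames(m) <- sampleIDs(gt)
    m
}

#' Sample metadata of a GenotypeTable
#' @param gt a \linkS4class{GenotypeTable}
#' @return data.frame with sample_id, population, region
#' @export
sampleData <- function(gt) gt@sampleData

#' Subset samples of a GenotypeTable
#'
#' @param x a \linkS4class{GenotypeTable}
#' @param i sample index (numeric, logical or sample IDs)
#' @param j locus index or names
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nSamples(x))
    if (is.character(i)) i <- match(i, sampleIDs(x))
    if (missing(j)) j <- seq_len(nLoci(x))
    GenotypeTable(x@alleles[i, j, , drop = FALSE], x@sampleData[i, , drop = FALSE])
})

setMethod("show", "GenotypeTable", function(object) {
    sd <- object@sampleData
    cat("GenotypeTable with", nSamples(object), "samples,",
        nLoci(object), "loci\n")
    cat("  populations:", length(unique(sd$population)), "")
    if (any(!is.na(sd$region)))
        cat(" regions:", paste(unique(sd$region), collapse = ", "))
    cat("\n  loci:", paste(utils::head(lociNames(object), 8), collapse = ", "),
        if (nLoci(object) > 8) "..." else "", "\n")
    miss <- mean(is.na(object@alleles[, , 1]))
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' Accessors for AlleleFreqDB
#'
#' @param x an \linkS4class{AlleleFreqDB}
#' @param group group name
#' @param locus locus name
#' @param floored return floored frequencies (forensic use) instead of raw
#' @name AlleleFreqDB-accessors
#' @aliases groupNames groupSizes alleleFreqs floorValues
NULL

#' @rdname AlleleFreqDB-accessors
#' @export
setMethod("groupNames", "AlleleFreqDB", function(x) names(x@groupSizes))

#' @rdname AlleleFreqDB-accessors
#' @export
setMethod("groupSizes", "AlleleFreqDB", function(x) x@groupSizes)

#' @rdname AlleleFreqDB-accessors
#' @export
setMethod("alleleFreqs", "AlleleFreqDB", function(x, group, locus, floored = FALSE) {
    ft <- x@freqTable
    sel <- ft$group == group & ft$locus == locus
    if (!any(sel))
        stop("no frequencies for group '", group, "', locus '", locus, "'")
    p <- if (floored) ft$freq_floored[sel] else ft$frequency[sel]
    names(p) <- ft$allele[sel]
    p
}
)

#' @rdname AlleleFreqDB-accessors
#' @export
setMethod("floorValues", "AlleleFreqDB", function(x) x@floor)

#' @rdname AlleleFreqDB-accessors
#' @export
setMethod("lociNames", "AlleleFreqDB",
    function(x) unique(x@freqTable$locus))

#' Frequency table of an AlleleFreqDB
#' @param db an \linkS4class{AlleleFreqDB}
#' @return the long-format frequency data.frame
#' @export
freqTable <- function(db) db@freqTable

setMethod("show", "AlleleFreqDB", function(object) {
    cat("AlleleFreqDB (grouping:", object@grouping, ")\n")
    for (g in groupNames(object)) {
        fl <- object@floor[g]
        cat(sprintf("  %s: N = %d%s\n", g, object@groupSizes[g],
            if (is.na(fl)) "" else sprintf(", floor = %.4f", fl)))
    }
    cat("  loci:", length(lociNames(object)),
        " alleles:", nrow(object@freqTable), "\n")
})

setMethod("show", "FStatResult", function(object) {
    cat("Weir-Cockerham F-statistics —", object@level, "\n")
    cat(sprintf("  theta (coancestry) = %.4f", object@theta))
    if (!all(is.na(object@ci["theta", ])))
        cat(sprintf("  [%.4f, %.4f]", object@ci["theta", 1], object@ci["theta", 2]))
    cat(sprintf("\n  f (inbreeding)     = %.4f", object@f))
    if (!all(is.na(object@ci["f", ])))
        cat(sprintf("  [%.4f, %.4f]", object@ci["f", 1], object@ci["f", 2]))
    cat(sprintf("\n  F (overall)        = %.4f\n", object@Fit))
    if (object@nBoot > 0)
        cat("  bootstrap replicates (over loci):", object@nBoot, "\n")
})

#' Accessors for HaplotypeTable
#'
#' @param x a \linkS4class{HaplotypeTable}
#' @name HaplotypeTable-accessors
#' @aliases haplotypeNames haplotypeCounts haplotypeAssignments variableSites
NULL

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("haplotypeNames", "HaplotypeTable",
    function(x) x@haplotypes$haplotype)

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("haplotypeAssignments", "HaplotypeTable", function(x) x@assignments)

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("variableSites", "HaplotypeTable", function(x) x@sites)

setMethod("show", "HaplotypeTable", function(object) {
    tot <- rowSums(object@counts)
    cat("HaplotypeTable:", nrow(object@haplotypes), "haplotypes over",
        nrow(object@sites), "variable sites\n")
    cat("  populations:", ncol(object@counts),
        " resolved samples:", sum(tot), "\n")
    top <- utils::head(order(-tot), 5)
    for (i in top)
        cat(sprintf("  %s: %d (%.1f%%)\n", object@haplotypes$haplotype[i],
                    tot[i], 100 * tot[i] / sum(tot)))
})
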