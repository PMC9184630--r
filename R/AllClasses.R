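#' @import methods
NULL

#' GenotypeTable: diploid multilocus SSR genotypes
#'
#' Container for codominant diploid microsatellite genotypes with population
#' and (optionally) region labels. Alleles are integer fragment sizes in base
#' pairs; a missing locus call is a pair of \code{NA}s (never a half-missing
#' pair).
#'
#' @slot alleles integer array of dimension \code{n_samples x n_loci x 2};
#'   \code{dimnames} carry sample IDs and locus names. \code{NA} encodes a
#'   missing call and must occur for both slots of a locus or neither.
#' @slot sampleData data.frame with columns \code{sample_id},
#'   \code{population}, \code{region} (region may be \code{NA} throughout;
#'   populations must nest cleanly within regions).
#'
#' @export
setClass("GenotypeTable",
    representation(alleles = "array", sampleData = "data.frame"))

setValidity("GenotypeTable", function(object) {
    a <- object@alleles
    sd <- object@sampleData
    msg <- character()
    if (length(dim(a)) != 3L || dim(a)[3] != 2L)
        msg <- c(msg, "alleles must be an n x L x 2 array")
    if (!is.integer(a))
        msg <- c(msg, "allele labels must be integers (fragment sizes)")
    if (!all(c("sample_id", "population", "region") %in% names(sd)))
        msg <- c(msg, "sampleData needs sample_id, population, region columns")
    if (nrow(sd) != dim(a)[1])
        msg <- c(msg, "sampleData rows must match first array dimension")
    if (anyDuplicated(sd$sample_id))
        msg <- c(msg, "duplicate sample_id")
    if (length(dim(a)) == 3L && dim(a)[3] == 2L) {
        half <- xor(is.na(a[, , 1, drop = FALSE]), is.na(a[, , 2, drop = FALSE]))
        if (any(half))
            msg <- c(msg, "a locus call must be both-present or both-missing")
    }
    ## region labels, when present, must partition populations
    if (any(!is.na(sd$region))) {
        if (any(is.na(sd$region)))
            msg <- c(msg, "region labels must be set for all samples or none")
        tab <- unique(sd[, c("population", "region")])
        if (anyDuplicated(tab$population))
            msg <- c(msg, "a population maps to more than one region")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param alleles integer array \code{n x L x 2} (dimnames: samples, loci).
#' @param sampleData data.frame with \code{sample_id}, \code{population} and
#'   optionally \code{region}; defaults region to \code{NA} (one implicit
#'   region).
#' @return a \linkS4class{GenotypeTable}
#' @export
GenotypeTable <- function(alleles, sampleData) {
    if (is.null(sampleData$region)) sampleData$region <- NA_character_
    sampleData$sample_id <- as.character(sampleData$sample_id)
    sampleData$population <- as.character(sampleData$population)
    sampleData$region <- as.character(sampleData$region)
    rownames(sampleData) <- NULL
    storage.mode(alleles) <- "integer"
    if (is.null(dimnames(alleles)[[1]]))
        dimnames(alleles)[[1]] <- sampleData$sample_id
    new("GenotypeTable", alleles = alleles, sampleData = sampleData)
}

#' AlleleFreqDB: per-group allele-frequency database
#'
#' Allele frequencies per locus for each group (population, region, or the
#' combined database), with per-locus sample sizes and an optional
#' minimum-allele-frequency floor. Raw frequencies (used in descriptive
#' statistics) and floored frequencies (used in forensic profile
#' calculations) are kept side by side.
#'
#' @slot grouping one of \code{"population"}, \code{"region"},
#'   \code{"combined"}.
#' @slot freqTable data.frame with columns \code{group}, \code{locus},
#'   \code{allele}, \code{count}, \code{frequency}, \code{freq_floored},
#'   \code{n_individuals} (non-missing individuals for that group x locus).
#' @slot groupSizes named integer, individuals per group.
#' @slot floor named numeric, per-group floor (NA when no floor applied).
#'
#' @export
setClass("AlleleFreqDB",
    representation(grouping = "character", freqTable = "data.frame",
                   groupSizes = "integer", floor = "numeric"))

setValidity("AlleleFreqDB", function(object) {
    ft <- object@freqTable
    msg <- character()
    need <- c("group", "locus", "allele", "count", "frequency",
              "freq_floored", "n_individuals")
    if (!all(need %in% names(ft)))
        msg <- c(msg, paste("freqTable needs columns:",
                            paste(need, collapse = ", ")))
    if (!object@grouping %in% c("population", "region", "combined"))
        msg <- c(msg, "grouping must be population, region or combined")
    if (length(msg) == 0L && nrow(ft)) {
        sums <- tapply(ft$frequency, paste(ft$group, ft$locus), sum)
        if (any(abs(sums - 1) > 1e-9))
            msg <- c(msg, "raw frequencies must sum to 1 per (group, locus)")
        if (any(ft$count %% 1 != 0) || any(ft$count < 0))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (length(msg)) msg else TRUE
})

#' FStatResult: Weir-Cockerham estimates with bootstrap CIs
#'
#' @slot level label for the hierarchical level analysed.
#' @slot theta coancestry (F_ST) point estimate.
#' @slot f inbreeding (F_IS) point estimate.
#' @slot Fit overall F (F_IT) point estimate.
#' @slot ci 2 x 2 matrix, rows \code{theta}/\code{f}, columns
#'   \code{2.5\%}/\code{97.5\%}; all-NA when no bootstrap was run.
#' @slot nBoot number of locus-bootstrap replicates.
#'
#' @export
setClass("FStatResult",
    representation(level = "character", theta = "numeric", f = "numeric",
                   Fit = "numeric", ci = "matrix", nBoot = "integer"))

#' HaplotypeTable: chloroplast haplotype database
#'
#' Unique haplotypes over the variable sites of a (concatenated) cpDNA
#' alignment, their per-population counts, and region diagnostics.
#'
#' @slot haplotypes data.frame with columns \code{haplotype} (H1..Hk,
#'   descending total count) and \code{state} (variant-site state string).
#' @slot counts integer matrix, haplotypes x populations.
#' @slot popRegion named character, population -> region.
#' @slot sites data.frame of variable sites (\code{position} 1-based,
#'   \code{kind} substitution/deletion, \code{states}, and for deletions
#'   \code{end} of the gap run).
#' @slot assignments named character, sample -> haplotype name (NA when a
#'   sample could not be resolved).
#'
#' @export
setClass("HaplotypeTable",
    representation(haplotypes = "data.frame", counts = "matrix",
                   popRegion = "character", sites = "data.frame",
                   assignments = "character"))

setValidity("HaplotypeTable", function(object) {
    msg <- character()
    if (nrow(object@haplotypes) != nrow(object@counts))
        msg <- c(msg, "one counts row per haplotype required")
    tot <- rowSums(object@counts)
    if (is.unsorted(rev(tot)))
        msg <- c(msg, "haplotypes must be ordered by descending total count")
    if (length(msg)) msg else TRUE
})
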