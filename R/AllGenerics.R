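#' @rdname GenotypeTable-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname AlleleFreqDB-accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname AlleleFreqDB-accessors
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname AlleleFreqDB-accessors
#' @export
setGeneric("alleleFreqs",
    function(x, group, locus, floored = FALSE) standardGeneric("alleleFreqs"))

#' @rdname AlleleFreqDB-accessors
#' @export
setGeneric("floorValues", function(x) standardGeneric("floorValues"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("haplotypeNames", function(x) standardGeneric("haplotypeNames"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("haplotypeAssignments",
    function(x) standardGeneric("haplotypeAssignments"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("variableSites", function(x) standardGeneric("variableSites"))
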