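#' Reference population metadata for the Shorea leprosula databases
#'
#' The published sampling design of the Peninsular Malaysia S. leprosula
#' reference databases: 44 natural populations with their regional cluster
#' membership (Region A: 12 populations; Region B: 32), coordinates,
#' altitude and per-population SSR sample sizes (totals 381, 1029 and 1410
#' individuals). Used as the default population-to-region map and for
#' computing the regional minimum-allele-frequency floors.
#'
#' @return data.frame: population, name, region, latitude, longitude,
#'   altitude_m, n_samples
#' @export
referencePopulations <- function() {
    path <- system.file("extdata", "sleprosula_populations.csv",
                        package = "timberID", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Population-to-region map of the reference design
#' @return named character vector population -> region
#' @export
referenceRegionMap <- function() {
    rp <- referencePopulations()
    stats::setNames(rp$region, rp$population)
}
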