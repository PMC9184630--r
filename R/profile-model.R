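#' Genotype frequency under the subpopulation-cum-inbreeding model
#'
#' Two standard corrections of the product rule are implemented.
#'
#' \emph{unconditional-frequency} (default): the expected frequency of the
#' genotype in a subpopulation with coancestry \code{theta} and inbreeding
#' \code{f}: homozygote AiAi \code{f p + (1-f) p (theta + (1-theta) p)};
#' heterozygote AiAj \code{(1-f) 2 p_i p_j (1-theta)}. Sums to 1 over the
#' genotype space for any (theta, f).
#'
#' \emph{conditional-match}: the classic conditional match probabilities
#' (NRC-II recommendation 4.10 / Balding-Nichols), i.e. the probability a
#' random member of the subpopulation carries the genotype given it has
#' already been seen once. Homozygote match probabilities are monotonically
#' non-decreasing in \code{theta}; heterozygote ones are as well unless both
#' alleles are very common (the derivative at theta = 0 is
#' 2 p_i + 2 p_j - 10 p_i p_j, negative only when p_i p_j exceeds
#' (p_i + p_j) / 5). \code{f} is not part of this formula and is ignored.
#'
#' @param genotype length-2 vector of allele labels (unordered pair)
#' @param freqs named numeric of allele frequencies for the locus (floored
#'   frequencies for forensic use)
#' @param theta coancestry in [0, 1)
#' @param f inbreeding coefficient in [0, 1)
#' @param mode \code{"unconditional-frequency"} or \code{"conditional-match"}
#' @return the genotype probability
#' @export
genotypeFrequency <- function(genotype, freqs, theta = 0, f = 0,
                              mode = c("unconditional-frequency",
                                       "conditional-match")) {
    mode <- match.arg(mode)
    stopifnot(length(genotype) == 2L, theta >= 0, theta < 1, f >= 0, f < 1)
    g <- as.character(genotype)
    if (!all(g %in% names(freqs)))
        stop("allele(s) ", paste(setdiff(g, names(freqs)), collapse = ", "),
             " absent from the frequency table; apply a minimum-allele-",
             "frequency floor (applyFloor) before forensic calculations")
    pi <- unname(freqs[g[1]]); pj <- unname(freqs[g[2]])
    hom <- g[1] == g[2]
    if (mode == "unconditional-frequency") {
        if (hom) f * pi + (1 - f) * pi * (theta + (1 - theta) * pi)
        else (1 - f) * 2 * pi * pj * (1 - theta)
    } else {
        denom <- (1 + theta) * (1 + 2 * theta)
        if (hom) {
            (2 * theta + (1 - theta) * pi) * (3 * theta + (1 - theta) * pi) /
                denom
        } else {
            2 * (theta + (1 - theta) * pi) * (theta + (1 - theta) * pj) / denom
        }
    }
}

#' Multilocus profile frequency
#'
#' Product over loci of \code{\link{genotypeFrequency}} computed from a
#' group's (floored) allele frequencies. The profile must be complete: no
#' missing locus is imputed.
#'
#' @param profile integer matrix loci x 2 with rownames = locus names, or a
#'   named list of allele pairs
#' @param db an \linkS4class{AlleleFreqDB}
#' @param group group name within the db
#' @param theta,f,mode passed to \code{\link{genotypeFrequency}}
#' @param floored use floored frequencies (default TRUE; forensic convention)
#' @return the profile probability
#' @export
profileFrequency <- function(profile, db, group, theta = 0, f = 0,
                             mode = c("unconditional-frequency",
                                      "conditional-match"),
                             floored = TRUE) {
    mode <- match.arg(mode)
    profile <- .as_profile(profile)
    if (any(is.na(profile)))
        stop("profile has missing loci; profile frequency needs a complete ",
             "profile")
    p <- 1
    for (l in rownames(profile)) {
        fr <- alleleFreqs(db, group, l, floored = floored)
        p <- p * genotypeFrequency(profile[l, ], fr, theta, f, mode)
    }
    p
}

.as_profile <- function(profile) {
    if (is.list(profile))
        profile <- do.call(rbind, profile)
    stopifnot(is.matrix(profile), ncol(profile) == 2L,
              !is.null(rownames(profile)))
    profile
}

#' Extract one sample's multilocus profile
#' @param gt a \linkS4class{GenotypeTable}
#' @param sample sample ID or index
#' @return integer matrix loci x 2
#' @export
ssrProfile <- function(gt, sample) {
    if (is.character(sample)) sample <- match(sample, sampleIDs(gt))
    m <- gt@alleles[sample, , , drop = TRUE]
    dim(m) <- c(nLoci(gt), 2L)
    rownames(m) <- lociNames(gt)
    m
}

#' Most common and rarest profile frequencies of a database
#'
#' The most common (rarest) profile is the fully heterozygous profile
#' carrying the two most (least) frequent alleles at every locus, evaluated
#' on floored frequencies. Frequency ties are broken towards the smaller
#' allele label, deterministically.
#'
#' @param db an \linkS4class{AlleleFreqDB} (floor applied)
#' @param group group name
#' @param theta,f,mode passed to \code{\link{genotypeFrequency}}
#' @return list: \code{most_common} and \code{rarest} probabilities, plus the
#'   selected allele pairs per locus
#' @export
extremeProfiles <- function(db, group, theta = 0, f = 0,
                            mode = c("unconditional-frequency",
                                     "conditional-match")) {
    mode <- match.arg(mode)
    loci <- lociNames(db)
    pairsC <- pairsR <- list()
    pc <- pr <- 1
    for (l in loci) {
        fr <- alleleFreqs(db, group, l, floored = TRUE)
        if (length(fr) < 2L)
            stop("locus '", l, "' has fewer than 2 alleles in group '",
                 group, "'")
        sel <- tieBreakExtremes(fr)
        pairsC[[l]] <- sel$most_common
        pairsR[[l]] <- sel$rarest
        pc <- pc * genotypeFrequency(sel$most_common, fr, theta, f, mode)
        pr <- pr * genotypeFrequency(sel$rarest, fr, theta, f, mode)
    }
    list(most_common = pc, rarest = pr,
         most_common_pairs = pairsC, rarest_pairs = pairsR)
}

#' Deterministic selection of extreme allele pairs
#'
#' Returns the two most common and the two rarest alleles at a locus;
#' frequency ties are resolved towards the smaller integer allele label.
#'
#' @param freqs named numeric of allele frequencies
#' @return list with integer pairs \code{most_common} and \code{rarest}
#' @export
tieBreakExtremes <- function(freqs) {
    stopifnot(length(freqs) >= 2L)
    lab <- as.integer(names(freqs))
    oC <- order(-freqs, lab)
    oR <- order(freqs, lab)
    list(most_common = sort(lab[oC[1:2]]), rarest = sort(lab[oR[1:2]]))
}

#' Random match probability as a "1 in N" statement
#'
#' The reciprocal of a profile frequency, formatted with the usual
#' short-scale unit words (thousand, million, billion, trillion,
#' quadrillion, quintillion) at 3 significant figures.
#'
#' @param profileFreq profile frequency, > 0
#' @return list: \code{one_in} (the reciprocal) and \code{text}
#' @export
randomMatchProbability <- function(profileFreq) {
    stopifnot(is.numeric(profileFreq), length(profileFreq) == 1L)
    if (profileFreq <= 0) stop("profile frequency must be > 0")
    n <- 1 / profileFreq
    units <- c(1, 1e3, 1e6, 1e9, 1e12, 1e15, 1e18)
    words <- c("", " thousand", " million", " billion", " trillion",
               " quadrillion", " quintillion")
    k <- findInterval(n, units)
    val <- signif(n / units[k], 3)
    txt <- if (k == 1L) paste0("1 in ", format(val, big.mark = ","))
           else paste0("1 in ", val, words[k])
    list(one_in = n, text = txt)
}
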