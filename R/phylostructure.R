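#' Nei's DA genetic distance between populations
#'
#' DA(X, Y) = 1 - (1/L) sum over loci of sum over alleles of
#' sqrt(x_a * y_a), computed on raw allele frequencies. 0 for identical
#' frequency vectors, 1 when the two populations share no allele at any
#' locus.
#'
#' @param db a population-grouping \linkS4class{AlleleFreqDB}
#' @param loci loci to use (default all shared)
#' @return symmetric distance matrix with population labels
#' @export
neiDa <- function(db, loci = NULL) {
    pops <- groupNames(db)
    if (length(pops) < 2L) stop("need at least 2 populations")
    if (is.null(loci)) loci <- lociNames(db)
    ## frequency lookup: list[pop][locus] -> named numeric
    fr <- lapply(pops, function(g) {
        lapply(stats::setNames(loci, loci), function(l)
            tryCatch(alleleFreqs(db, g, l), error = function(e) NULL))
    })
    names(fr) <- pops
    d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
        tot <- 0; nl <- 0L
        for (l in loci) {
            x <- fr[[i]][[l]]; y <- fr[[j]][[l]]
            if (is.null(x) || is.null(y)) {
                warning("locus '", l, "' dropped for pair ", pops[i], "/",
                        pops[j])
                next
            }
            shared <- intersect(names(x), names(y))
            tot <- tot + sum(sqrt(x[shared] * y[shared]))
            nl <- nl + 1L
        }
        d[i, j] <- d[j, i] <- 1 - tot / nl
    }
    d
}

#' UPGMA dendrogram
#'
#' Average-linkage (UPGMA) clustering of a distance matrix, returned as an
#' ultrametric \code{ape::phylo} tree. Labels are sorted before clustering
#' so that merge-order ties resolve lexicographically and the output is
#' deterministic.
#'
#' @param d symmetric distance matrix with labels
#' @return an \code{ape} phylo object with branch lengths
#' @export
upgmaTree <- function(d) {
    stopifnot(is.matrix(d), nrow(d) >= 2L, isSymmetric(unname(d)))
    ord <- order(rownames(d))
    d <- d[ord, ord]
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ape::as.phylo(hc)
}

#' Bootstrap support for the UPGMA population tree
#'
#' Resamples loci with replacement (the locus is the bootstrap unit),
#' rebuilds the allele-frequency database, the Nei DA matrix and the UPGMA
#' tree for each replicate, and reports for every internal node of the
#' original tree the percentage of replicates containing the same
#' bipartition.
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param nBoot bootstrap replicates
#' @param seed integer seed
#' @return list: \code{tree} (phylo, original data), \code{support}
#'   (percentage per internal node, in \code{tree$node.label}), \code{nBoot}
#' @export
bootstrapTree <- function(gt, nBoot = 1000, seed = 1) {
    loci <- lociNames(gt)
    if (length(loci) < 2L) stop("need at least 2 loci to bootstrap")
    db <- buildAlleleDb(gt, "population")
    tree <- upgmaTree(neiDa(db))
    restore <- .with_seed(seed)
    on.exit(restore())
    boots <- vector("list", nBoot)
    for (b in seq_len(nBoot)) {
        bl <- sample(loci, replace = TRUE)
        boots[[b]] <- upgmaTree(.nei_da_loci(db, bl))
    }
    cnt <- ape::prop.clades(tree, boots, rooted = TRUE)
    cnt[is.na(cnt)] <- 0
    support <- 100 * cnt / nBoot
    tree$node.label <- round(support, 1)
    list(tree = tree, support = support, nBoot = nBoot)
}

## DA over an explicit multiset of loci (repeats allowed, for bootstraps)
.nei_da_loci <- function(db, lociMultiset) {
    pops <- groupNames(db)
    d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    fr <- lapply(pops, function(g)
        lapply(stats::setNames(unique(lociMultiset), unique(lociMultiset)),
               function(l) alleleFreqs(db, g, l)))
    names(fr) <- pops
    for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
        tot <- 0
        for (l in lociMultiset) {
            x <- fr[[i]][[l]]; y <- fr[[j]][[l]]
            shared <- intersect(names(x), names(y))
            tot <- tot + sum(sqrt(x[shared] * y[shared]))
        }
        d[i, j] <- d[j, i] <- 1 - tot / length(lociMultiset)
    }
    d
}
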