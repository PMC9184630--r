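#' Read a diploid SSR genotype table
#'
#' Reads genotype CSVs in either a long dialect (one row per sample x locus)
#' or a GenAlEx-like wide dialect (two adjacent allele columns per locus).
#' Allele labels are integer fragment sizes in bp. Missing calls may be
#' encoded as 0 or empty cells; a half-missing pair is rejected.
#'
#' @param path CSV file path.
#' @param dialect \code{"genalex"} (wide, default) or \code{"long"}.
#' @param regionMap optional named character vector population -> region;
#'   overrides/provides the region column. Populations absent from the map
#'   are an error.
#' @return a \linkS4class{GenotypeTable}
#' @export
readGenotypeTable <- function(path, dialect = c("genalex", "long"),
                              regionMap = NULL) {
    dialect <- match.arg(dialect)
    stopifnot(file.exists(path))
    raw <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (dialect == "long") {
        need <- c("sample_id", "population", "locus", "allele1", "allele2")
        if (!all(need %in% names(raw)))
            stop("long dialect needs columns: ", paste(need, collapse = ", "))
        loci <- unique(raw$locus)
        ids <- unique(raw$sample_id)
        a <- array(NA_integer_, c(length(ids), length(loci), 2L),
                   dimnames = list(ids, loci, NULL))
        i <- match(raw$sample_id, ids)
        j <- match(raw$locus, loci)
        a[cbind(i, j, 1L)] <- .parse_allele(raw$allele1)
        a[cbind(i, j, 2L)] <- .parse_allele(raw$allele2)
        meta <- unique(raw[, intersect(c("sample_id", "population", "region"),
                                       names(raw))])
        if (anyDuplicated(meta$sample_id))
            stop("duplicate sample_id with conflicting metadata")
        meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    } else {
        metaCols <- intersect(c("sample_id", "population", "region"),
                              names(raw))
        if (!all(c("sample_id", "population") %in% metaCols))
            stop("wide dialect needs sample_id and population columns")
        if (anyDuplicated(raw$sample_id))
            stop("duplicate sample_id: ",
                 paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
                       collapse = ", "))
        alleleCols <- setdiff(names(raw), metaCols)
        if (length(alleleCols) %% 2L != 0L)
            stop("odd number of allele columns (", length(alleleCols),
                 "): each locus needs two")
        loci <- sub("(_2|\\.2|_[ab])$", "",
                    alleleCols[seq(1, length(alleleCols), by = 2)])
        a <- array(NA_integer_,
                   c(nrow(raw), length(loci), 2L),
                   dimnames = list(raw$sample_id, loci, NULL))
        for (k in seq_along(loci)) {
            a[, k, 1] <- .parse_allele(raw[[alleleCols[2 * k - 1]]])
            a[, k, 2] <- .parse_allele(raw[[alleleCols[2 * k]]])
        }
        meta <- raw[, metaCols, drop = FALSE]
    }
    ## reject half-missing pairs at parse time with a clear message
    half <- xor(is.na(a[, , 1, drop = FALSE]), is.na(a[, , 2, drop = FALSE]))
    if (any(half))
        stop("half-missing genotype call(s): a locus call must have both ",
             "alleles present or both missing")
    if (!is.null(regionMap)) {
        unknown <- setdiff(unique(meta$population), names(regionMap))
        if (length(unknown))
            stop("population(s) without region mapping: ",
                 paste(unknown, collapse = ", "))
        meta$region <- unname(regionMap[meta$population])
    }
    GenotypeTable(a, meta)
}

.parse_allele <- function(x) {
    x <- trimws(as.character(x))
    x[x == "" | x == "0" | is.na(x)] <- NA
    suppressWarnings(as.integer(x))
}

#' Write a GenotypeTable as CSV
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param path output CSV path
#' @param dialect \code{"genalex"} (wide) or \code{"long"}
#' @export
writeGenotypeTable <- function(gt, path, dialect = c("genalex", "long")) {
    dialect <- match.arg(dialect)
    sd <- sampleData(gt)
    loci <- lociNames(gt)
    if (dialect == "genalex") {
        out <- sd
        for (k in seq_along(loci)) {
            m <- locusGenotypes(gt, k)
            m[is.na(m)] <- 0L
            out[[loci[k]]] <- m[, 1]
            out[[paste0(loci[k], "_2")]] <- m[, 2]
        }
    } else {
        out <- do.call(rbind, lapply(seq_along(loci), function(k) {
            m <- locusGenotypes(gt, k)
            m[is.na(m)] <- 0L
            data.frame(sd, locus = loci[k], allele1 = m[, 1], allele2 = m[, 2])
        }))
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write an allele-frequency database as CSV
#'
#' One row per (group, locus, allele) with counts, raw and floored
#' frequencies, the per-locus non-missing sample size, the group sample size
#' and the group floor. Frequencies per (group, locus) sum to 1 (raw scale).
#'
#' @param db an \linkS4class{AlleleFreqDB}
#' @param path output path
#' @export
writeAlleleFreqTable <- function(db, path) {
    ft <- freqTable(db)
    if (nrow(ft) == 0L) stop("empty allele-frequency database; nothing written")
    ft$n_group <- unname(groupSizes(db)[ft$group])
    ft$floor <- unname(floorValues(db)[ft$group])
    ft$grouping <- db@grouping
    utils::write.csv(ft, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read an allele-frequency database from CSV
#'
#' @param path CSV as written by \code{\link{writeAlleleFreqTable}} (minimal
#'   required columns: group, locus, allele, count, frequency,
#'   n_individuals).
#' @return an \linkS4class{AlleleFreqDB}
#' @export
readAlleleFreqTable <- function(path) {
    ft <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("group", "locus", "allele", "count", "frequency",
              "n_individuals")
    if (!all(need %in% names(ft)))
        stop("allele-frequency CSV needs columns: ",
             paste(need, collapse = ", "))
    if (is.null(ft$freq_floored)) ft$freq_floored <- ft$frequency
    grouping <- if (!is.null(ft$grouping)) ft$grouping[1] else "combined"
    if (!is.null(ft$n_group)) {
        gs <- tapply(ft$n_group, ft$group, function(x) as.integer(x[1]))
    } else {
        gs <- tapply(ft$n_individuals, ft$group, function(x) as.integer(max(x)))
    }
    gs <- stats::setNames(as.integer(gs), names(gs))
    fl <- if (!is.null(ft$floor)) {
        stats::setNames(as.numeric(tapply(ft$floor, ft$group, `[`, 1)),
                        names(tapply(ft$floor, ft$group, `[`, 1)))
    } else stats::setNames(rep(NA_real_, length(gs)), names(gs))
    fl <- fl[names(gs)]
    keep <- c("group", "locus", "allele", "count", "frequency",
              "n_individuals", "freq_floored")
    new("AlleleFreqDB", grouping = grouping,
        freqTable = ft[, keep], groupSizes = gs, floor = fl)
}

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned FASTA (gap character \code{-}); all records must have
#' identical lengths. Lowercase bases are normalised to uppercase; the
#' alphabet is restricted to A, C, G, T, N and the gap.
#'
#' @param path FASTA file path
#' @return a \code{Biostrings::DNAStringSet} of equal-width sequences
#' @export
readAlignedFasta <- function(path) {
    stopifnot(file.exists(path))
    x <- Biostrings::readBStringSet(path)
    if (anyDuplicated(names(x)))
        stop("duplicate record names in ", path)
    w <- Biostrings::width(x)
    if (length(unique(w)) > 1L) {
        bad <- names(x)[w != w[1]]
        stop("ragged alignment: record(s) ", paste(bad, collapse = ", "),
             " differ in length from '", names(x)[1], "' (", w[1], " bp)")
    }
    seqs <- toupper(as.character(x))
    if (any(grepl("[^ACGTN-]", seqs)))
        stop("alignment contains characters outside {A,C,G,T,N,-}")
    Biostrings::DNAStringSet(seqs)
}

#' Write an alignment as FASTA
#' @param aln a \code{DNAStringSet}
#' @param path output path
#' @export
writeAlignedFasta <- function(aln, path) {
    Biostrings::writeXStringSet(aln, path)
    invisible(path)
}

## alignment -> character matrix (samples x columns)
.aln_matrix <- function(aln) {
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
    m
}
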