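#' Concatenate marker alignments
#'
#' Column-wise concatenation of per-marker alignments sharing an identical
#' sample set, in the order given. Marker boundaries are recorded in the
#' \code{"boundaries"} attribute (1-based start/end per marker).
#'
#' @param alns named list of \code{DNAStringSet} alignments
#' @return a single \code{DNAStringSet} over the concatenated columns
#' @export
concatenateAlignments <- function(alns) {
    stopifnot(length(alns) >= 1L)
    ids <- names(alns[[1]])
    for (m in seq_along(alns)) {
        miss <- union(setdiff(ids, names(alns[[m]])),
                      setdiff(names(alns[[m]]), ids))
        if (length(miss))
            stop("sample(s) not shared by all markers: ",
                 paste(miss, collapse = ", "))
    }
    seqs <- as.character(alns[[1]])[ids]
    lens <- Biostrings::width(alns[[1]])[1]
    if (length(alns) > 1L) {
        for (m in 2:length(alns)) {
            seqs <- paste0(seqs, as.character(alns[[m]])[ids])
            lens <- c(lens, Biostrings::width(alns[[m]])[1])
        }
    }
    out <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    ends <- cumsum(lens)
    attr(out, "boundaries") <- data.frame(
        marker = if (is.null(names(alns))) sprintf("marker%d", seq_along(lens))
                 else names(alns),
        start = c(1L, utils::head(ends, -1) + 1L), end = ends)
    out
}

#' Find variable sites in an alignment
#'
#' A substitution site is a column with at least two distinct non-gap,
#' non-N states. A deletion event is a maximal run of consecutive columns
#' whose set of gap-carrying samples is identical (one event regardless of
#' run length; overlapping but unequal gap runs are separate events).
#' N is treated as missing and excluded from state comparison.
#'
#' @param aln a \code{DNAStringSet} alignment (>= 2 sequences)
#' @return data.frame: \code{position} (1-based start), \code{end},
#'   \code{kind} ("substitution"/"deletion"), \code{states}
#'   (comma-separated observed states; for deletions the carrier count)
#' @export
findVariableSites <- function(aln) {
    stopifnot(length(aln) >= 2L)
    m <- .aln_matrix(aln)
    L <- ncol(m)
    rows <- list()
    ## substitutions
    for (j in seq_len(L)) {
        st <- unique(m[, j])
        st <- setdiff(st, c("N", "-"))
        if (length(st) >= 2L)
            rows[[length(rows) + 1L]] <- data.frame(
                position = j, end = j, kind = "substitution",
                states = paste(sort(st), collapse = ","))
    }
    ## deletion events: maximal runs of identical non-empty gap-carrier sets
    carrier <- apply(m == "-", 2, function(x) paste(which(x), collapse = ","))
    runStart <- NA_integer_
    flush <- function(s, e) data.frame(
        position = s, end = e, kind = "deletion",
        states = paste0("gap:", carrier[s]))
    for (j in seq_len(L)) {
        if (carrier[j] != "") {
            if (is.na(runStart)) runStart <- j
            else if (carrier[j] != carrier[j - 1L]) {
                rows[[length(rows) + 1L]] <- flush(runStart, j - 1L)
                runStart <- j
            }
        } else if (!is.na(runStart)) {
            rows[[length(rows) + 1L]] <- flush(runStart, j - 1L)
            runStart <- NA_integer_
        }
    }
    if (!is.na(runStart))
        rows[[length(rows) + 1L]] <- flush(runStart, L)
    if (length(rows) == 0L)
        return(data.frame(position = integer(), end = integer(),
                          kind = character(), states = character()))
    out <- do.call(rbind, rows)
    out <- out[order(out$position, out$kind), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Collapse samples into haplotypes over the variable sites
#'
#' The haplotype of a sample is the tuple of its states at the variable
#' sites (the base at a substitution site; gap presence over a deletion
#' event). Identical tuples collapse into one haplotype; haplotypes are
#' named H1..Hk by descending total count (ties by first observation).
#' Samples with N at a variable site are assigned only when their
#' non-missing states match exactly one observed haplotype, otherwise they
#' are left unresolved (NA).
#'
#' @param aln a \code{DNAStringSet} alignment
#' @param sites variable sites from \code{\link{findVariableSites}}
#' @param meta data.frame with \code{sample_id}, \code{population},
#'   \code{region} for every sequence in \code{aln}
#' @return a \linkS4class{HaplotypeTable}
#' @export
callHaplotypes <- function(aln, sites, meta) {
    stopifnot(all(names(aln) %in% meta$sample_id))
    m <- .aln_matrix(aln)
    nS <- nrow(m)
    ## state matrix: samples x variable sites ("?" = missing)
    sm <- matrix("", nS, nrow(sites), dimnames = list(rownames(m), NULL))
    for (k in seq_len(nrow(sites))) {
        if (sites$kind[k] == "substitution") {
            st <- m[, sites$position[k]]
            st[st == "N"] <- "?"
            sm[, k] <- st
        } else {
            run <- m[, sites$position[k]:sites$end[k], drop = FALSE]
            sm[, k] <- ifelse(apply(run == "-", 1, all), "-",
                              ifelse(apply(run == "N", 1, any), "?", "*"))
        }
    }
    key <- apply(sm, 1, paste, collapse = "")
    complete <- !grepl("?", key, fixed = TRUE)
    ## haplotypes from complete samples, in order of first observation
    uh <- unique(key[complete])
    hapOf <- rep(NA_character_, nS)
    names(hapOf) <- rownames(m)
    hapOf[complete] <- key[complete]
    ## resolve N-bearing samples against observed haplotypes
    for (i in which(!complete)) {
        pat <- strsplit(key[i], "")[[1]]
        ok <- vapply(uh, function(h) {
            hs <- strsplit(h, "")[[1]]
            all(pat == hs | pat == "?")
        }, logical(1))
        if (sum(ok) == 1L) hapOf[i] <- uh[ok]
    }
    counts0 <- table(factor(hapOf, levels = uh))
    ord <- order(-as.numeric(counts0), match(uh, uh))
    uh <- uh[ord]
    hapNames <- stats::setNames(sprintf("H%d", seq_along(uh)), uh)
    assignments <- stats::setNames(unname(hapNames[hapOf]), names(hapOf))
    pops <- meta$population[match(rownames(m), meta$sample_id)]
    popLevels <- unique(meta$population)
    cnt <- table(factor(assignments, levels = hapNames),
                 factor(pops, levels = popLevels))
    counts <- matrix(as.integer(cnt), nrow = length(uh),
                     dimnames = list(unname(hapNames), popLevels))
    popRegion <- stats::setNames(
        meta$region[match(popLevels, meta$population)], popLevels)
    new("HaplotypeTable",
        haplotypes = data.frame(haplotype = unname(hapNames), state = uh,
                                stringsAsFactors = FALSE),
        counts = counts, popRegion = popRegion, sites = sites,
        assignments = assignments)
}

#' Region totals of a HaplotypeTable
#' @param table a \linkS4class{HaplotypeTable}
#' @return integer matrix haplotypes x regions
#' @export
regionTotals <- function(table) {
    reg <- table@popRegion[colnames(table@counts)]
    t(rowsum(t(table@counts), group = reg))
}

#' Infer the region of origin of a query haplotype
#'
#' @param queryHaplotype a haplotype name (e.g. "H3") or a variant-state
#'   string as stored in the table
#' @param table a \linkS4class{HaplotypeTable} built with region metadata
#' @return list: \code{status} ("diagnostic", "shared" or "unknown") and
#'   \code{region} (single region, vector of regions, or NA)
#' @export
inferRegion <- function(queryHaplotype, table) {
    hp <- table@haplotypes
    idx <- match(queryHaplotype, hp$haplotype)
    if (is.na(idx)) idx <- match(queryHaplotype, hp$state)
    if (is.na(idx))
        return(list(status = "unknown", region = NA_character_))
    rt <- regionTotals(table)
    present <- colnames(rt)[rt[idx, ] > 0]
    if (length(present) == 1L)
        list(status = "diagnostic", region = present)
    else if (length(present) > 1L)
        list(status = "shared", region = present)
    else list(status = "unknown", region = NA_character_)
}
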