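## Reporter-ion ingestion: per-spectrum normalization, per-protein median
## aggregation, and replicate merging under the both-replicates rule.

.REPORTER_COLS <- sprintf("reporter_%02d", 1:10)
.CHANNEL_COLS <- sprintf("channel_%02d", 1:10)
.REPLICATES <- c("rep1", "rep2")

#' Normalize one reporter-ion spectrum
#'
#' Converts raw reporter intensities to relative abundances by dividing by
#' the spectrum total (ratio-to-sum normalization), the representation under
#' which co-fractionating proteins share profiles regardless of absolute
#' abundance.
#'
#' @param reporters Numeric vector of 10 nonnegative reporter intensities.
#' @return Numeric vector of 10 values summing to 1.
#' @export
#' @examples
#' normalizeSpectrum(c(1, 2, 3, 4, 0, 0, 0, 0, 0, 0))
normalizeSpectrum <- function(reporters) {
    if (length(reporters) != 10L)
        stop("a spectrum must carry exactly 10 reporter values")
    if (any(!is.finite(reporters)) || any(reporters < 0))
        stop("reporter values must be finite and nonnegative")
    s <- sum(reporters)
    if (s <= 0)
        stop("all-zero spectrum cannot be normalized")
    reporters / s
}

## Reason a PSM is not quantifiable, or NA if it is.
.psmRejectReason <- function(x) {
    if (any(!is.finite(x))) return("non-finite reporter value")
    if (any(x < 0)) return("negative reporter value")
    if (sum(x) <= 0) return("zero total reporter intensity")
    NA_character_
}

#' Aggregate PSMs to one protein profile
#'
#' Each PSM spectrum is normalized to relative abundances, the channel-wise
#' median is taken across PSMs, and (by default) the median vector is
#' renormalized to sum to 1 — channel medians of sum-to-one vectors need not
#' themselves sum to one, and the classifier assumes compositional profiles.
#'
#' @param reporters Numeric matrix, one row per PSM, 10 columns of raw
#'   reporter intensities (all rows quantifiable).
#' @param renormalize Renormalize the median vector to sum to 1 (default
#'   TRUE).
#' @return Numeric vector of 10 relative abundances.
#' @export
#' @examples
#' m <- rbind(c(5, 5, 0, 0, 0, 0, 0, 0, 0, 0),
#'            c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
#'            c(0, 0, 9, 0, 0, 0, 0, 0, 0, 0))
#' aggregateProtein(m)
aggregateProtein <- function(reporters, renormalize = TRUE) {
    if (!is.matrix(reporters)) reporters <- matrix(reporters, nrow = 1)
    if (ncol(reporters) != 10L)
        stop("PSM matrix must have 10 reporter columns")
    if (nrow(reporters) == 0L)
        stop("at least one accepted PSM is required")
    norm <- reporters / rowSums(reporters)
    med <- apply(norm, 2, median)
    if (renormalize) med <- med / sum(med)
    unname(med)
}

#' Read a PSM quantitation table
#'
#' Delimited text (comma for .csv, tab for .tsv/.txt) with header columns
#' \code{protein_group_id}, \code{replicate} and
#' \code{reporter_01..reporter_10}.
#'
#' @param path File path.
#' @return data.frame with the required columns.
#' @export
readPsmTable <- function(path) {
    df <- .readDelim(path)
    need <- c("protein_group_id", "replicate", .REPORTER_COLS)
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("PSM table is missing column(s): ", paste(miss, collapse = ", "))
    df
}

#' Build per-replicate protein profiles from a PSM table
#'
#' Applies the quantifiable-PSM filter (finite, nonnegative, positive total
#' intensity; rejections are returned, not raised), then aggregates the
#' accepted PSMs of each protein and replicate with
#' \code{\link{aggregateProtein}}. Exactly the two replicate labels "rep1"
#' and "rep2" are accepted.
#'
#' @param psms data.frame as returned by \code{\link{readPsmTable}}.
#' @param renormalize Passed to \code{\link{aggregateProtein}}.
#' @return List with per-replicate profile matrices \code{rep1} and
#'   \code{rep2} (proteins x 10 fractions, rows summing to 1), matching
#'   per-replicate PSM counts \code{nPsms}, and a \code{rejected} data.frame
#'   (protein, replicate, reason).
#' @export
buildProfiles <- function(psms, renormalize = TRUE) {
    need <- c("protein_group_id", "replicate", .REPORTER_COLS)
    miss <- setdiff(need, names(psms))
    if (length(miss))
        stop("PSM table is missing column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(psms$replicate), .REPLICATES)
    if (length(bad))
        stop("unsupported replicate label(s): ", paste(bad, collapse = ", "),
             " (this pipeline expects exactly 'rep1' and 'rep2')")

    m <- as.matrix(psms[, .REPORTER_COLS])
    reason <- apply(m, 1, .psmRejectReason)
    keep <- is.na(reason)
    rejected <- data.frame(protein = psms$protein_group_id[!keep],
                           replicate = psms$replicate[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)

    out <- list(rejected = rejected, nPsms = list())
    for (r in .REPLICATES) {
        sel <- keep & psms$replicate == r
        groups <- split(which(sel), psms$protein_group_id[sel])
        prof <- t(vapply(groups,
                         function(i) aggregateProtein(m[i, , drop = FALSE],
                                                      renormalize = renormalize),
                         numeric(10)))
        colnames(prof) <- .CHANNEL_COLS
        out[[r]] <- prof
        out$nPsms[[r]] <- vapply(groups, length, integer(1))
    }
    out
}

#' Merge replicate profiles under the both-replicates rule
#'
#' Only proteins quantified in both biological replicates are retained; the
#' combined 20-channel profile is the concatenation rep1 || rep2. Proteins
#' present in a single replicate are recorded in the dropped-proteins log
#' (\code{metadata(x)$dropped}), not silently discarded.
#'
#' @param rep1,rep2 Per-replicate profile matrices (proteins x 10, protein
#'   ids as rownames, rows summing to 1), e.g. from
#'   \code{\link{buildProfiles}}.
#' @param nPsmsRep1,nPsmsRep2 Optional named PSM counts per protein.
#' @return A \linkS4class{FractionProfileSet} over the intersection of
#'   protein ids.
#' @export
mergeReplicates <- function(rep1, rep2, nPsmsRep1 = NULL, nPsmsRep2 = NULL) {
    if (is.null(rownames(rep1)) || is.null(rownames(rep2)))
        stop("profile matrices must have protein ids as rownames")
    shared <- sort(intersect(rownames(rep1), rownames(rep2)))
    dropped <- sort(c(setdiff(rownames(rep1), rownames(rep2)),
                      setdiff(rownames(rep2), rownames(rep1))))
    if (length(shared) == 0L)
        stop("no protein was quantified in both replicates; ",
             "cannot build a merged dataset")
    fps <- FractionProfileSet(
        rep1[shared, , drop = FALSE], rep2[shared, , drop = FALSE],
        nPsmsRep1 = if (is.null(nPsmsRep1)) NULL else unname(nPsmsRep1[shared]),
        nPsmsRep2 = if (is.null(nPsmsRep2)) NULL else unname(nPsmsRep2[shared]))
    S4Vectors::metadata(fps)$dropped <- dropped
    fps
}

#' PSM table to merged profiles in one step
#'
#' Convenience wrapper: \code{\link{buildProfiles}} followed by
#' \code{\link{mergeReplicates}}.
#'
#' @param psms data.frame as returned by \code{\link{readPsmTable}}.
#' @param renormalize Passed to \code{\link{aggregateProtein}}.
#' @return A \linkS4class{FractionProfileSet}; rejected PSMs are recorded in
#'   \code{metadata(x)$rejectedPsms}.
#' @export
profilesFromPsms <- function(psms, renormalize = TRUE) {
    bp <- buildProfiles(psms, renormalize = renormalize)
    fps <- mergeReplicates(bp$rep1, bp$rep2, bp$nPsms$rep1, bp$nPsms$rep2)
    S4Vectors::metadata(fps)$rejectedPsms <- bp$rejected
    fps
}

#' Write / read a protein-level profile table
#'
#' Long-format delimited text with columns \code{protein_id},
#' \code{replicate} and \code{channel_01..channel_10}, the protein-level
#' entry point alternative to PSM tables.
#'
#' @param x A \linkS4class{FractionProfileSet}.
#' @param path Output file (.csv or .tsv).
#' @return \code{writeProfileTable}: the path, invisibly.
#' @export
writeProfileTable <- function(x, path) {
    rows <- lapply(.REPLICATES, function(r) {
        m <- profileMatrix(x, r)
        colnames(m) <- .CHANNEL_COLS
        data.frame(protein_id = rownames(m), replicate = r, m,
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    .writeDelim(do.call(rbind, rows), path)
    invisible(path)
}

#' @rdname writeProfileTable
#' @param values "normalized" if the table already holds relative abundances
#'   (used as-is), "raw" to apply ratio-to-sum normalization per row.
#' @return \code{readProfileTable}: list of per-replicate profile matrices
#'   \code{rep1} and \code{rep2}.
#' @export
readProfileTable <- function(path, values = c("normalized", "raw")) {
    values <- match.arg(values)
    df <- .readDelim(path)
    need <- c("protein_id", "replicate", .CHANNEL_COLS)
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("profile table is missing column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(df$replicate), .REPLICATES)
    if (length(bad))
        stop("unsupported replicate label(s): ", paste(bad, collapse = ", "))
    out <- list()
    for (r in .REPLICATES) {
        sub <- df[df$replicate == r, , drop = FALSE]
        if (anyDuplicated(sub$protein_id))
            stop("duplicated protein_id within replicate ", r)
        m <- as.matrix(sub[, .CHANNEL_COLS])
        rownames(m) <- sub$protein_id
        if (values == "raw") m <- m / rowSums(m)
        out[[r]] <- m
    }
    out
}
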