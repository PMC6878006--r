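## Curated marker handling: loading, validation, intersection with the
## quantified proteome.

#' Read a curated marker table
#'
#' Delimited text with columns \code{protein_id} and \code{class}; an
#' optional \code{subannotation} column (e.g. "cytosol", "periplasm" for
#' soluble markers) is carried along but ignored by the classifier. Rows
#' duplicated with a consistent class are collapsed; conflicting duplicates
#' and labels outside the class vocabulary are errors.
#'
#' @param path File path (.csv or .tsv).
#' @param classes Allowed class vocabulary (default
#'   \code{\link{lopitClasses}}).
#' @return A \linkS4class{MarkerSet}.
#' @export
readMarkers <- function(path, classes = lopitClasses()) {
    df <- .readDelim(path)
    miss <- setdiff(c("protein_id", "class"), names(df))
    if (length(miss))
        stop("marker table is missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(df) == 0L)
        stop("marker table is empty")
    df$protein_id <- trimws(as.character(df$protein_id))
    df$class <- trimws(as.character(df$class))
    df$class[is.na(df$class)] <- ""
    if (any(!nzchar(df$class)))
        stop("empty class label in marker table")
    bad <- setdiff(unique(df$class), classes)
    if (length(bad))
        stop("unknown marker class label(s): ", paste(bad, collapse = ", "),
             " (allowed: ", paste(classes, collapse = ", "), ")")
    byId <- split(df$class, df$protein_id)
    conflict <- names(byId)[vapply(byId, function(x) length(unique(x)) > 1L,
                                   logical(1))]
    if (length(conflict))
        stop("conflicting class labels for protein(s): ",
             paste(conflict, collapse = ", "))
    labels <- vapply(byId, `[`, character(1), 1L)
    markerSet(names(labels), labels, classes = classes)
}

#' Intersect markers with the quantified proteome
#'
#' Restricts a marker set to the proteins that actually carry a merged
#' fractionation profile and reports markers missing from the data. Every
#' class must retain at least \code{minPerClass} represented markers —
#' otherwise training and per-class threshold calibration are impossible.
#'
#' @param markers A \linkS4class{MarkerSet}.
#' @param profiles A \linkS4class{FractionProfileSet}.
#' @param minPerClass Minimum represented markers per class (default 2).
#' @return List with \code{training} (a \linkS4class{MarkerSet} restricted
#'   to quantified proteins), \code{missing} (marker ids without profiles)
#'   and \code{classCounts} (represented markers per class).
#' @export
intersectWithProfiles <- function(markers, profiles, minPerClass = 2L) {
    present <- proteinIds(markers) %in% proteinIds(profiles)
    missing <- proteinIds(markers)[!present]
    kept <- markerClasses(markers)[present]
    counts <- table(factor(kept, levels = classLabels(markers)))
    low <- names(counts)[counts < minPerClass]
    if (length(low))
        stop("class(es) with fewer than ", minPerClass,
             " markers represented in the data: ",
             paste(low, collapse = ", "))
    list(training = markerSet(names(kept), unname(kept),
                              classes = classLabels(markers)),
         missing = missing,
         classCounts = as.integer(counts) |> stats::setNames(names(counts)))
}

#' Attach marker labels to a profile set
#'
#' Fills the \code{markerClass} column of \code{rowData} for proteins in
#' the marker set (NA elsewhere).
#'
#' @param profiles A \linkS4class{FractionProfileSet}.
#' @param markers A \linkS4class{MarkerSet}.
#' @return The updated \linkS4class{FractionProfileSet}.
#' @export
addMarkers <- function(profiles, markers) {
    mk <- rep(NA_character_, nrow(profiles))
    names(mk) <- rownames(profiles)
    hit <- intersect(proteinIds(markers), rownames(profiles))
    mk[hit] <- markerClasses(markers)[hit]
    SummarizedExperiment::rowData(profiles)$markerClass <- unname(mk)
    profiles
}
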