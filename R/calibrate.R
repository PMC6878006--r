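## Per-class score threshold calibration to a target FDR, and final
## assignment including the "unclassified" category.

.EPS_ABOVE_ONE <- 1e-9

## Empirical FDR of class `cl` at cutoff `t`: among annotated proteins
## predicted `cl` with score >= t, the fraction whose annotation differs.
## The FDR of an empty selection is 0 by convention.
.fdrAt <- function(score, correct, t) {
    sel <- score >= t
    if (!any(sel)) return(0)
    mean(!correct[sel])
}

#' Calibrate per-class score thresholds to a target FDR
#'
#' For each compartment, the threshold is the smallest candidate cutoff
#' such that, among annotated proteins predicted to that compartment and
#' scoring at or above the cutoff, the fraction whose annotation disagrees
#' does not exceed \code{fdrTarget}. Candidate cutoffs are the observed
#' scores of the class's annotated predictions plus 1.0 (the empirical FDR
#' is a step function that only changes at observed scores). If no cutoff
#' attains the target, the threshold is set just above 1 — the class
#' assigns nothing — with a warning; likewise for a class with no annotated
#' predictions.
#'
#' The annotation should be a labeled set distinct from the training
#' markers (in synthetic runs, a second labeled sample); reusing the
#' training markers underestimates the FDR because the classifier fits
#' them.
#'
#' @param scores data.frame from \code{\link{scoreAll}}.
#' @param annotation Named character vector: protein id -> known
#'   compartment.
#' @param fdrTarget Target false discovery rate in (0, 1); default 0.075.
#' @param classes Class vocabulary to calibrate (default: the classes
#'   appearing in the score table's per-class columns).
#' @return A \linkS4class{ThresholdSet} (method "fdr").
#' @export
#' @examples
#' sc <- data.frame(protein_id = c("a", "b", "c"),
#'                  predicted_class = "TM", score = c(0.9, 0.8, 0.7))
#' ann <- c(a = "TM", b = "TM", c = "PM")
#' thresholds(calibrateThresholds(sc, ann, 0.075, classes = "TM"))
calibrateThresholds <- function(scores, annotation, fdrTarget = 0.075,
                                classes = NULL) {
    if (!is.numeric(fdrTarget) || fdrTarget <= 0 || fdrTarget >= 1)
        stop("'fdrTarget' must lie strictly between 0 and 1")
    if (is.null(names(annotation)))
        stop("'annotation' must be a named vector (protein id -> class)")
    if (is.null(classes)) {
        cols <- grep("^score_", names(scores), value = TRUE)
        classes <- if (length(cols)) sub("^score_", "", cols)
                   else sort(unique(scores$predicted_class))
    }
    ann <- scores[scores$protein_id %in% names(annotation), , drop = FALSE]
    annClass <- annotation[ann$protein_id]

    th <- vapply(classes, function(cl) {
        sel <- ann$predicted_class == cl
        if (!any(sel)) {
            warning("class '", cl, "' has no annotated predictions; ",
                    "threshold set above 1 (assigns nothing)")
            return(1 + .EPS_ABOVE_ONE)
        }
        if (sum(sel) < 2L)
            warning("class '", cl, "' has fewer than 2 annotated predictions; ",
                    "its threshold is poorly determined")
        score <- ann$score[sel]
        correct <- annClass[sel] == cl
        cand <- sort(unique(c(score, 1.0)))
        ok <- vapply(cand, function(t) .fdrAt(score, correct, t) <= fdrTarget,
                     logical(1))
        if (!any(ok)) {
            warning("class '", cl, "' cannot attain FDR <= ", fdrTarget,
                    " at any cutoff; threshold set above 1 (assigns nothing)")
            return(1 + .EPS_ABOVE_ONE)
        }
        cand[which(ok)[1]]
    }, numeric(1))

    new("ThresholdSet", thresholds = stats::setNames(th, classes),
        fdrTarget = fdrTarget, method = "fdr")
}

#' Final compartment assignment
#'
#' A protein keeps its predicted compartment if its score reaches that
#' compartment's threshold, and is reported as "unclassified" otherwise.
#' Curated marker proteins always carry their curated label, whatever their
#' score — assigned per-class counts conventionally include the markers
#' themselves.
#'
#' @param scores data.frame from \code{\link{scoreAll}}.
#' @param thresholds A \linkS4class{ThresholdSet} — calibrated
#'   (\code{\link{calibrateThresholds}}) or fixed
#'   (\code{\link{fixedThresholds}}).
#' @param markers Optional \linkS4class{MarkerSet} for the marker override.
#' @return data.frame with columns \code{protein_id}, \code{final_label},
#'   \code{predicted_class}, \code{score}, \code{threshold},
#'   \code{is_marker}.
#' @export
assignProteins <- function(scores, thresholds, markers = NULL) {
    stopifnot(is(thresholds, "ThresholdSet"))
    th <- thresholds(thresholds)
    miss <- setdiff(unique(scores$predicted_class), names(th))
    if (length(miss))
        stop("no threshold for predicted class(es): ",
             paste(miss, collapse = ", "))
    applied <- unname(th[scores$predicted_class])
    final <- ifelse(scores$score >= applied, scores$predicted_class,
                    "unclassified")
    isMarker <- rep(FALSE, nrow(scores))
    if (!is.null(markers)) {
        i <- match(scores$protein_id, proteinIds(markers))
        isMarker <- !is.na(i)
        final[isMarker] <- unname(markerClasses(markers)[i[isMarker]])
    }
    data.frame(protein_id = scores$protein_id, final_label = final,
               predicted_class = scores$predicted_class,
               score = scores$score, threshold = applied,
               is_marker = isMarker, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Summarize an assignment table
#'
#' Per-compartment counts (markers included) plus the unclassified count;
#' the counts partition the table, so they sum to its size.
#'
#' @param assignments data.frame from \code{\link{assignProteins}}.
#' @param classes Class vocabulary to report (default
#'   \code{\link{lopitClasses}}).
#' @return List with \code{counts} (named integer over the classes and
#'   "unclassified") and \code{total}.
#' @export
summarizeAssignments <- function(assignments, classes = lopitClasses()) {
    extra <- setdiff(unique(assignments$final_label),
                     c(classes, "unclassified"))
    levs <- c(classes, extra, "unclassified")
    counts <- table(factor(assignments$final_label, levels = levs))
    list(counts = stats::setNames(as.integer(counts), levs),
         total = nrow(assignments))
}

#' Write an assignment table to CSV
#'
#' @param assignments data.frame from \code{\link{assignProteins}}.
#' @param path Output .csv/.tsv path.
#' @return The path, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
    .writeDelim(assignments, path)
    invisible(path)
}
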