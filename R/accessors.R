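## Accessor generics and methods for the core classes.

#' Profile matrix of a FractionProfileSet
#'
#' @param x A \linkS4class{FractionProfileSet}.
#' @param replicate "combined" (default, 20 channels), "rep1" or "rep2"
#'   (10 channels).
#' @return Numeric matrix, proteins in rows.
#' @export
setGeneric("profileMatrix", function(x, replicate = "combined")
    standardGeneric("profileMatrix"))

#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "FractionProfileSet", function(x, replicate = "combined") {
    m <- SummarizedExperiment::assay(x, "profile")
    switch(match.arg(replicate, c("combined", "rep1", "rep2")),
           combined = m,
           rep1 = m[, 1:10, drop = FALSE],
           rep2 = m[, 11:20, drop = FALSE])
})

#' Protein identifiers
#'
#' @param x A \linkS4class{FractionProfileSet} or \linkS4class{MarkerSet}.
#' @return Character vector of protein ids.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "FractionProfileSet", function(x) rownames(x))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "MarkerSet", function(x) names(x@entries))

#' Marker class labels
#'
#' For a \code{MarkerSet}, the named vector of protein id to class label.
#' For a \code{FractionProfileSet}, the per-protein marker class from
#' \code{rowData} (NA for non-markers).
#'
#' @param x A \linkS4class{MarkerSet} or \linkS4class{FractionProfileSet}.
#' @return Named character vector.
#' @export
setGeneric("markerClasses", function(x) standardGeneric("markerClasses"))

#' @rdname markerClasses
#' @export
setMethod("markerClasses", "MarkerSet", function(x) x@entries)

#' @rdname markerClasses
#' @export
setMethod("markerClasses", "FractionProfileSet", function(x) {
    out <- SummarizedExperiment::rowData(x)$markerClass
    names(out) <- rownames(x)
    out
})

#' Class vocabulary of a MarkerSet
#'
#' @param x A \linkS4class{MarkerSet}.
#' @return Character vector of allowed class labels, in order.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "MarkerSet", function(x) x@classes)

#' Per-class thresholds of a ThresholdSet
#'
#' @param x A \linkS4class{ThresholdSet}.
#' @return Named numeric vector of per-class score cutoffs.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname thresholds
#' @export
setMethod("thresholds", "ThresholdSet", function(x) x@thresholds)
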