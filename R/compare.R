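## Dataset-level comparisons: protein-list overlap and cross-dataset
## assignment concordance.

#' Overlap between two protein lists
#'
#' Exact set arithmetic after id normalization (trimmed whitespace,
#' case-folded), as used to compare protein coverage between studies that
#' share a genome's locus-tag namespace.
#'
#' @param listA,listB Character vectors of protein ids.
#' @return List with counts \code{n_only_A}, \code{n_only_B},
#'   \code{n_both} and the corresponding membership vectors \code{only_A},
#'   \code{only_B}, \code{both}.
#' @export
#' @examples
#' overlapReport(c("slr0488", "sll1276"), c("SLL1276", "slr1149"))
overlapReport <- function(listA, listB) {
    a <- unique(.normalizeIds(listA))
    b <- unique(.normalizeIds(listB))
    both <- sort(intersect(a, b))
    onlyA <- sort(setdiff(a, b))
    onlyB <- sort(setdiff(b, a))
    list(n_only_A = length(onlyA), n_only_B = length(onlyB),
         n_both = length(both),
         only_A = onlyA, only_B = onlyB, both = both)
}

#' Assignment concordance between two studies
#'
#' Contingency table of compartment labels over the proteins shared by two
#' assignment tables, with row and column marginals. An optional label
#' mapping translates the second study's vocabulary into the first's.
#'
#' @param assignmentsA,assignmentsB data.frames with columns
#'   \code{protein_id} and \code{final_label}.
#' @param labelMapB Optional named character vector mapping B's labels to
#'   the shared vocabulary; a B label absent from the mapping is an error.
#' @return List with \code{table} (labels of A in rows, B in columns),
#'   \code{rowMarginals}, \code{colMarginals} and \code{n_shared}.
#' @export
concordanceReport <- function(assignmentsA, assignmentsB, labelMapB = NULL) {
    idA <- .normalizeIds(assignmentsA$protein_id)
    idB <- .normalizeIds(assignmentsB$protein_id)
    labB <- as.character(assignmentsB$final_label)
    if (!is.null(labelMapB)) {
        bad <- setdiff(unique(labB), names(labelMapB))
        if (length(bad))
            stop("unmappable label(s) in second table: ",
                 paste(bad, collapse = ", "))
        labB <- unname(labelMapB[labB])
    }
    shared <- intersect(idA, idB)
    if (length(shared) == 0L) {
        warning("no shared proteins between the two assignment tables")
        empty <- table(character(0), character(0))
        return(list(table = empty, rowMarginals = integer(0),
                    colMarginals = integer(0), n_shared = 0L))
    }
    a <- as.character(assignmentsA$final_label)[match(shared, idA)]
    b <- labB[match(shared, idB)]
    levs <- sort(unique(c(a, b)))
    tab <- table(A = factor(a, levels = levs), B = factor(b, levels = levs))
    list(table = tab, rowMarginals = rowSums(tab), colMarginals = colSums(tab),
         n_shared = length(shared))
}
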