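## PCA organelle map: 2-D projection of the 20-channel combined profiles.

#' Project profiles onto the first two principal components
#'
#' Mean-centered (by default unscaled — the profiles are already
#' compositional on a common scale) PCA of the combined 20-channel
#' profiles, keeping the top two components. Proteins with similar
#' distribution profiles along the gradient cluster together on the
#' resulting map. A deterministic sign convention is applied: the
#' largest-magnitude loading of each component is made positive, so
#' coordinates are reproducible across runs and platforms.
#'
#' @param profiles A \linkS4class{FractionProfileSet} or a numeric matrix
#'   (proteins x channels, protein ids as rownames).
#' @param scale. Also scale channels to unit variance (default FALSE).
#' @return data.frame with columns \code{protein_id}, \code{pc1},
#'   \code{pc2}; attributes \code{explainedVariance} (two fractions) and
#'   \code{loadings} (channels x 2).
#' @export
setGeneric("pcaProject", function(profiles, scale. = FALSE)
    standardGeneric("pcaProject"))

#' @rdname pcaProject
#' @export
setMethod("pcaProject", "FractionProfileSet", function(profiles, scale. = FALSE) {
    pcaProject(profileMatrix(profiles), scale. = scale.)
})

#' @rdname pcaProject
#' @export
setMethod("pcaProject", "matrix", function(profiles, scale. = FALSE) {
    if (nrow(profiles) < 3L)
        stop("PCA projection needs at least 3 proteins")
    v <- apply(profiles, 2, stats::var)
    if (all(v < .Machine$double.eps))
        stop("profiles are constant; PCA is undefined")
    pc <- prcomp(profiles, center = TRUE, scale. = scale., rank. = 2)
    for (j in 1:2) {
        load <- pc$rotation[, j]
        if (load[which.max(abs(load))] < 0) {
            pc$rotation[, j] <- -load
            pc$x[, j] <- -pc$x[, j]
        }
    }
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    out <- data.frame(protein_id = rownames(profiles),
                      pc1 = unname(pc$x[, 1]), pc2 = unname(pc$x[, 2]),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "explainedVariance") <- ev[1:2]
    attr(out, "loadings") <- pc$rotation[, 1:2, drop = FALSE]
    out
})

#' Render the organelle map
#'
#' Scatter plot of the PCA coordinates. Assigned proteins are colored by
#' final compartment, unclassified proteins are gray, and marker proteins
#' are drawn with a distinct outlined shape. Output format follows the file
#' extension (.png or .svg).
#'
#' @param coords data.frame from \code{\link{pcaProject}}.
#' @param assignments Optional assignment data.frame from
#'   \code{\link{assignProteins}} (columns \code{protein_id},
#'   \code{final_label}).
#' @param markers Optional \linkS4class{MarkerSet}; marker proteins are
#'   highlighted.
#' @param path Output image path (.png or .svg).
#' @param width,height Device size in inches.
#' @return The path, invisibly.
#' @export
renderMap <- function(coords, assignments = NULL, markers = NULL, path,
                      width = 7, height = 5.5) {
    if (nrow(coords) == 0L)
        stop("no coordinates to plot")
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("png", "svg"))
        stop("unsupported image extension: '", ext, "' (use .png or .svg)")

    df <- coords
    df$label <- "unclassified"
    if (!is.null(assignments)) {
        i <- match(df$protein_id, assignments$protein_id)
        df$label <- ifelse(is.na(i), "unclassified", assignments$final_label[i])
    }
    df$marker <- if (is.null(markers)) FALSE else
        df$protein_id %in% proteinIds(markers)
    levs <- c(setdiff(sort(unique(df$label)), "unclassified"), "unclassified")
    df$label <- factor(df$label, levels = levs)
    pal <- c(TM = "#2ca02c", PM = "#d62728", soluble = "#1f77b4",
             small_ribosomal = "#ff7f0e", large_ribosomal = "#9467bd")
    cols <- ifelse(levs == "unclassified", "grey70",
                   ifelse(levs %in% names(pal), pal[levs],
                          grDevices::hcl.colors(length(levs), "Dark 3")))
    ev <- attr(coords, "explainedVariance")
    axlab <- if (is.null(ev)) c("PC1", "PC2") else
        sprintf("PC%d (%.1f%%)", 1:2, 100 * ev)

    p <- ggplot2::ggplot(df, ggplot2::aes(x = pc1, y = pc2, color = label)) +
        ggplot2::geom_point(data = df[!df$marker, ], size = 1.4, alpha = 0.7) +
        ggplot2::geom_point(data = df[df$marker, ], size = 1.8, shape = 17) +
        ggplot2::scale_color_manual(values = stats::setNames(cols, levs),
                                    name = "compartment", drop = FALSE) +
        ggplot2::labs(x = axlab[1], y = axlab[2]) +
        ggplot2::theme_bw()
    dev <- if (ext == "png") grDevices::png else grDevices::svg
    if (ext == "png")
        dev(path, width = width, height = height, units = "in", res = 150)
    else
        dev(path, width = width, height = height)
    print(p)
    grDevices::dev.off()
    invisible(path)
}

#' Write PCA coordinates to CSV
#'
#' @param coords data.frame from \code{\link{pcaProject}}.
#' @param path Output .csv/.tsv path.
#' @return The path, invisibly.
#' @export
writeCoordinates <- function(coords, path) {
    .writeDelim(coords[, c("protein_id", "pc1", "pc2")], path)
    invisible(path)
}
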