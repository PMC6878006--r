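## Synthetic co-fractionation data generator.
##
## Emulates the 10-fraction x 2-replicate isobaric-tag design: compartment
## templates define expected relative-abundance profiles along the gradient,
## protein profiles are Dirichlet draws around their template (compositional
## noise), and PSM reporter vectors are Dirichlet draws around the protein's
## replicate profile scaled by a log-normal total intensity.

## Flat-Dirichlet concentrations: "noise" proteins resembling no compartment,
## and outlier PSMs.
.NOISE_ALPHA <- 0.8
.OUTLIER_ALPHA <- 0.5

#' Default compartment templates
#'
#' Five templates named after the canonical compartments, with smooth
#' unimodal profiles peaking at distinct gradient fractions: the soluble
#' fraction at the light end, small and large ribosomal subunits at
#' intermediate densities, and the plasma and thylakoid membranes towards
#' the dense end (the chlorophyll-rich thylakoid membrane sediments
#' deepest). Shapes are discretized Gaussians over the 10 fractions.
#'
#' @param concentration Within-class Dirichlet concentration shared by all
#'   templates (default 60; larger = tighter clusters).
#' @return List of 5 \linkS4class{CompartmentTemplate} objects.
#' @export
#' @examples
#' tpl <- defaultTemplates()
#' sapply(tpl, function(t) which.max(t@meanProfile))
defaultTemplates <- function(concentration = 60) {
    centers <- c(TM = 9, PM = 7, soluble = 1.5,
                 small_ribosomal = 3.5, large_ribosomal = 5)
    widths <- c(TM = 1, PM = 1, soluble = 1.2,
                small_ribosomal = 1, large_ribosomal = 1)
    lapply(lopitClasses(), function(cl) {
        p <- exp(-((1:10 - centers[cl])^2) / (2 * widths[cl]^2))
        compartmentTemplate(cl, p / sum(p), concentration)
    })
}

#' Simulate a gradient co-fractionation dataset
#'
#' Generates a PSM-level quantitation table over 10 reporter channels and
#' two biological replicates, with known per-protein ground truth. For each
#' protein and replicate, the replicate profile is a Dirichlet draw with
#' parameter \code{concentration * meanProfile} of its compartment template
#' (two replicates are independent draws around the same template); each PSM
#' is a Dirichlet draw with parameter
#' \code{psmNoiseConcentration * profile}, scaled by a log-normal total
#' reporter intensity. A configurable fraction of PSMs are outliers drawn
#' from a flat Dirichlet, noise proteins are drawn from a flat symmetric
#' Dirichlet (they co-fractionate with no compartment), and proteins flagged
#' replicate-1-only are absent from replicate 2.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return List with elements \code{psms} (data.frame with columns
#'   \code{protein_group_id}, \code{replicate},
#'   \code{reporter_01..reporter_10}), \code{markers} (a
#'   \linkS4class{MarkerSet}), and \code{truth} (data.frame with
#'   \code{protein_id}, \code{true_label} — a compartment or "noise" — and
#'   \code{is_marker}).
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(nMarkersPerClass = 3,
#'                                         nUnknownsPerClass = 5,
#'                                         nNoiseProteins = 2, seed = 7))
#' head(sim$truth)
simulateDataset <- function(config) {
    validObject(config)
    .withSeed(config@seed, .simulateDataset(config))
}

.simulateDataset <- function(config) {
    classes <- vapply(config@templates, slot, character(1), "name")
    perClass <- config@nMarkersPerClass + config@nUnknownsPerClass
    nTotal <- length(classes) * perClass + config@nNoiseProteins

    ids <- sprintf("syn%04d", seq_len(nTotal))
    trueLabel <- c(rep(classes, each = perClass),
                   rep("noise", config@nNoiseProteins))
    isMarker <- c(rep(rep(c(TRUE, FALSE),
                          c(config@nMarkersPerClass, config@nUnknownsPerClass)),
                      length(classes)),
                  rep(FALSE, config@nNoiseProteins))
    rep1Only <- runif(nTotal) < config@fracRep1Only

    alphaFor <- function(lbl) {
        if (lbl == "noise") return(rep(.NOISE_ALPHA, 10))
        tpl <- config@templates[[match(lbl, classes)]]
        tpl@concentration * tpl@meanProfile
    }

    nPsm <- config@psmPerProtein
    rows <- vector("list", nTotal * 2L)
    k <- 0L
    for (i in seq_len(nTotal)) {
        reps <- if (rep1Only[i]) "rep1" else c("rep1", "rep2")
        alpha <- alphaFor(trueLabel[i])
        for (r in reps) {
            profile <- drop(.rdirichlet(1, alpha))
            rel <- .rdirichlet(nPsm, config@psmNoiseConcentration * profile)
            out <- runif(nPsm) < config@psmOutlierRate
            if (any(out))
                rel[out, ] <- .rdirichlet(sum(out), rep(.OUTLIER_ALPHA, 10))
            total <- rlnorm(nPsm, meanlog = log(1e6), sdlog = 0.5)
            k <- k + 1L
            rows[[k]] <- data.frame(protein_group_id = ids[i], replicate = r,
                                    rel * total, stringsAsFactors = FALSE)
        }
    }
    psms <- do.call(rbind, rows[seq_len(k)])
    names(psms)[3:12] <- sprintf("reporter_%02d", 1:10)
    rownames(psms) <- NULL

    markers <- markerSet(ids[isMarker], trueLabel[isMarker], classes = classes)
    truth <- data.frame(protein_id = ids, true_label = trueLabel,
                        is_marker = isMarker, stringsAsFactors = FALSE)
    list(psms = psms, markers = markers, truth = truth)
}

#' Write a simulated dataset to delimited files
#'
#' Writes \code{psms.csv}, \code{markers.csv} and \code{truth.csv} in the
#' formats read back by \code{\link{readPsmTable}} and
#' \code{\link{readMarkers}}.
#'
#' @param sim Result of \code{\link{simulateDataset}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, c("psms.csv", "markers.csv", "truth.csv"))
    .writeDelim(sim$psms, paths[1])
    .writeDelim(data.frame(protein_id = proteinIds(sim$markers),
                           class = unname(markerClasses(sim$markers))),
                paths[2])
    .writeDelim(sim$truth, paths[3])
    invisible(paths)
}
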