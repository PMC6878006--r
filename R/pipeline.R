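## Declarative end-to-end pipeline driver:
## ingest -> markers -> map -> classify -> calibrate -> assign -> summarize.

.configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                force = TRUE), f)
    unname(tools::md5sum(f))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full localization pipeline
#'
#' Executes ingest, marker attachment, PCA map, classification, threshold
#' calibration, assignment and summary from a single declarative
#' configuration (a list, or a path to a YAML file). The configuration
#' names either real inputs (\code{inputs$psm_table} or
#' \code{inputs$profile_table}, plus \code{markers}) or a
#' \code{simulation} block whose parameters override the defaults of
#' \code{\link{simulationConfig}}. Calibration runs in \code{fdr} mode
#' (per-class thresholds from held-out annotation; in simulated runs a
#' second labeled sample is drawn from the ground truth) or \code{fixed}
#' mode (user cutoffs, defaulting to 0.75 per membrane/ribosomal class and
#' 0.65 for soluble).
#'
#' All outputs (profiles, coordinates, map image, scores, assignments,
#' summary and manifest JSON) are written under \code{output_dir} when one
#' is configured.
#'
#' @param config List or path to a YAML configuration. Recognized keys:
#'   \code{simulation}, \code{inputs}, \code{markers},
#'   \code{normalization$renormalize}, \code{classifier}
#'   (\code{costGrid}, \code{gammaGrid}, \code{cvOuterRounds},
#'   \code{cvInnerFolds}), \code{calibration} (\code{mode},
#'   \code{fdr_target}, \code{fixed_cutoffs}, \code{annotation_file},
#'   \code{n_validation_per_class}), \code{seed}, \code{output_dir}.
#' @return Invisibly, a list with \code{profiles}, \code{markers},
#'   \code{coords}, \code{model}, \code{scores}, \code{thresholds},
#'   \code{assignments}, \code{summary}, and (simulated runs) \code{truth}
#'   and \code{validation}.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    seed <- as.integer(config$seed %||% 1L)
    outDir <- config$output_dir
    renorm <- config$normalization$renormalize %||% TRUE

    truth <- NULL
    if (!is.null(config$simulation)) {
        sim <- .stage("simulate", {
            args <- config$simulation
            args$seed <- seed
            do.call(simulationConfig, args) |> simulateDataset()
        })
        psms <- sim$psms
        markers <- sim$markers
        truth <- sim$truth
    } else if (!is.null(config$inputs)) {
        if (is.null(config$markers))
            stop("config error: 'markers' file is required for real inputs")
        psms <- NULL
        if (!is.null(config$inputs$psm_table))
            psms <- .stage("ingest", readPsmTable(config$inputs$psm_table))
        markers <- .stage("markers", readMarkers(config$markers))
    } else {
        stop("config error: provide either an 'inputs' or a 'simulation' block")
    }

    profiles <- .stage("profiles", {
        if (!is.null(psms)) profilesFromPsms(psms, renormalize = renorm)
        else {
            pt <- readProfileTable(config$inputs$profile_table,
                                   values = config$inputs$values %||% "normalized")
            mergeReplicates(pt$rep1, pt$rep2)
        }
    })
    profiles <- addMarkers(profiles, markers)

    coords <- .stage("map", pcaProject(profiles,
                                       scale. = config$pca_scale %||% FALSE))

    spec <- .stage("classifier spec", {
        cc <- config$classifier %||% list()
        classifierSpec(
            costGrid = cc$costGrid %||% 2^(-4:4),
            gammaGrid = cc$gammaGrid %||% 2^(-4:4),
            cvOuterRounds = cc$cvOuterRounds %||% 100L,
            cvInnerFolds = cc$cvInnerFolds %||% 5L,
            seed = seed)
    })
    model <- .stage("train", tuneAndTrain(profiles, markers, spec))
    scores <- .stage("score", scoreAll(model, profiles))

    cal <- config$calibration %||% list()
    mode <- cal$mode %||% "fdr"
    validation <- NULL
    thr <- .stage("calibrate", {
        if (mode == "fixed") {
            cuts <- cal$fixed_cutoffs
            if (is.null(cuts)) fixedThresholds()
            else fixedThresholds(unlist(cuts))
        } else if (mode == "fdr") {
            target <- cal$fdr_target %||% 0.075
            ann <- if (!is.null(cal$annotation_file)) {
                a <- readMarkers(cal$annotation_file,
                                 classes = classLabels(markers))
                markerClasses(a)
            } else if (!is.null(truth)) {
                validation <- .sampleValidation(
                    truth, profiles, markers,
                    nPerClass = cal$n_validation_per_class %||% 20L,
                    seed = seed)
                validation
            } else {
                stop("fdr mode needs an 'annotation_file' (or a simulated ",
                     "run, where a held-out labeled sample is drawn from ",
                     "the ground truth)")
            }
            calibrateThresholds(scores, ann, fdrTarget = target,
                                classes = classLabels(markers))
        } else stop("unknown calibration mode '", mode, "'")
    })

    assignments <- .stage("assign", assignProteins(scores, thr, markers))
    summary <- summarizeAssignments(assignments,
                                    classes = classLabels(markers))

    res <- list(profiles = profiles, markers = markers, coords = coords,
                model = model, scores = scores, thresholds = thr,
                assignments = assignments, summary = summary,
                truth = truth, validation = validation)

    if (!is.null(outDir)) .stage("write outputs", {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeProfileTable(profiles, file.path(outDir, "profiles.csv"))
        writeCoordinates(coords, file.path(outDir, "coordinates.csv"))
        renderMap(coords, assignments, markers,
                  file.path(outDir, "map.png"))
        writeScores(scores, file.path(outDir, "scores.csv"))
        writeAssignments(assignments, file.path(outDir, "assignments.csv"))
        cfgHash <- .configHash(config)
        jsonlite::write_json(
            list(counts = as.list(summary$counts), total = summary$total,
                 thresholds = as.list(thresholds(thr)),
                 threshold_method = thr@method,
                 fdr_target = thr@fdrTarget,
                 cost = model@cost, gamma = model@gamma,
                 cv_macro_f1 = model@cvMacroF1,
                 seed = seed, config_hash = cfgHash),
            file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA,
            na = "null")
        jsonlite::write_json(
            list(package = "cofrac",
                 version = as.character(utils::packageVersion("cofrac")),
                 r_version = R.version.string,
                 seed = seed, config_hash = cfgHash,
                 training_hash = model@trainingHash),
            file.path(outDir, "manifest.json"), auto_unbox = TRUE)
    })
    invisible(res)
}

## Held-out labeled sample for FDR calibration in simulated runs: up to
## `nPerClass` non-marker, non-noise proteins per class, drawn from truth.
.sampleValidation <- function(truth, profiles, markers, nPerClass, seed) {
    pool <- truth[!truth$is_marker & truth$true_label != "noise" &
                  truth$protein_id %in% proteinIds(profiles), , drop = FALSE]
    .withSeed(seed + 1L, {
        picks <- lapply(split(pool, pool$true_label), function(d) {
            d[sample(nrow(d), min(nPerClass, nrow(d))), , drop = FALSE]
        })
        sel <- do.call(rbind, picks)
        stats::setNames(sel$true_label, sel$protein_id)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
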