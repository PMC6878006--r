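#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Canonical compartment labels
#'
#' The five subcellular niches used for marker-based localization in a
#' cyanobacterial cell: thylakoid membrane (TM), plasma membrane (PM), the
#' soluble fraction (cytosolic, thylakoid-lumen and periplasmic proteins
#' pooled under one label), and the small and large ribosomal subunits.
#'
#' @return Character vector of the five class labels, in canonical order.
#' @export
#' @examples
#' lopitClasses()
lopitClasses <- function() {
    c("TM", "PM", "soluble", "small_ribosomal", "large_ribosomal")
}

## ---------------------------------------------------------------------------
## CompartmentTemplate
## ---------------------------------------------------------------------------

#' Compartment profile template
#'
#' Expected relative-abundance profile of one subcellular compartment across
#' the 10 gradient fractions, with a Dirichlet concentration controlling the
#' within-class dispersion (larger = tighter co-fractionating cluster).
#'
#' @slot name Compartment label.
#' @slot meanProfile Numeric vector of 10 nonnegative values summing to 1.
#' @slot concentration Positive scalar; Dirichlet concentration of protein
#'   profiles around \code{meanProfile}.
#' @export
setClass("CompartmentTemplate",
    representation(name = "character", meanProfile = "numeric",
                   concentration = "numeric"))

setValidity("CompartmentTemplate", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    p <- object@meanProfile
    if (length(p) != 10L)
        msg <- c(msg, "'meanProfile' must have length 10")
    else {
        if (any(!is.finite(p)) || any(p < 0))
            msg <- c(msg, "'meanProfile' must be finite and nonnegative")
        else if (abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, "'meanProfile' must sum to 1 (tolerance 1e-9)")
    }
    if (length(object@concentration) != 1L || !is.finite(object@concentration) ||
        object@concentration <= 0)
        msg <- c(msg, "'concentration' must be a positive scalar")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CompartmentTemplate Constructor; \code{meanProfile} is
#'   renormalized to sum to 1.
#' @param name,meanProfile,concentration See slots.
#' @export
compartmentTemplate <- function(name, meanProfile, concentration = 60) {
    if (length(meanProfile) == 10L && all(is.finite(meanProfile)) &&
        all(meanProfile >= 0) && sum(meanProfile) > 0)
        meanProfile <- meanProfile / sum(meanProfile)
    new("CompartmentTemplate", name = as.character(name),
        meanProfile = as.numeric(meanProfile),
        concentration = as.numeric(concentration))
}

setMethod("show", "CompartmentTemplate", function(object) {
    cat("CompartmentTemplate '", object@name, "' (concentration ",
        format(object@concentration), ")\n", sep = "")
    cat("  peak fraction:", which.max(object@meanProfile), "\n")
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Synthetic co-fractionation experiment configuration
#'
#' Parameters of the synthetic 10-fraction, two-replicate gradient
#' experiment: compartment templates, numbers of marker / unknown / noise
#' proteins, whole-replicate dropout, and PSM-level replication noise.
#'
#' @slot templates List of \linkS4class{CompartmentTemplate} (at least 2,
#'   unique names).
#' @slot nMarkersPerClass Markers generated per compartment (>= 2).
#' @slot nUnknownsPerClass Unlabeled proteins generated per compartment.
#' @slot nNoiseProteins Proteins drawn from a flat symmetric Dirichlet,
#'   resembling no compartment (ground truth "noise").
#' @slot fracRep1Only Probability in [0, 1) that a protein is present in
#'   replicate 1 only (whole-replicate dropout).
#' @slot psmPerProtein Peptide-spectrum matches per protein per replicate.
#' @slot psmNoiseConcentration Dirichlet concentration of PSM reporter
#'   vectors around the protein's replicate profile.
#' @slot psmOutlierRate Probability that a PSM is an outlier drawn from a
#'   flat symmetric Dirichlet instead of the protein profile.
#' @slot seed Integer RNG seed; a fixed seed makes the simulation
#'   byte-for-byte reproducible.
#' @export
setClass("SimulationConfig",
    representation(templates = "list", nMarkersPerClass = "integer",
                   nUnknownsPerClass = "integer", nNoiseProteins = "integer",
                   fracRep1Only = "numeric", psmPerProtein = "integer",
                   psmNoiseConcentration = "numeric", psmOutlierRate = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (length(object@templates) < 2L)
        msg <- c(msg, "at least 2 compartment templates are required")
    if (!all(vapply(object@templates, is, logical(1), "CompartmentTemplate")))
        msg <- c(msg, "'templates' must all be CompartmentTemplate objects")
    else {
        nms <- vapply(object@templates, slot, character(1), "name")
        if (anyDuplicated(nms))
            msg <- c(msg, "template names must be unique")
    }
    if (object@nMarkersPerClass < 2L)
        msg <- c(msg, "'nMarkersPerClass' must be >= 2 (classifier needs >= 2 training points per class)")
    if (object@nUnknownsPerClass < 0L || object@nNoiseProteins < 0L)
        msg <- c(msg, "protein counts must be nonnegative")
    if (object@fracRep1Only < 0 || object@fracRep1Only >= 1)
        msg <- c(msg, "'fracRep1Only' must be in [0, 1)")
    if (object@psmPerProtein < 1L)
        msg <- c(msg, "'psmPerProtein' must be >= 1")
    if (object@psmNoiseConcentration <= 0)
        msg <- c(msg, "'psmNoiseConcentration' must be positive")
    if (object@psmOutlierRate < 0 || object@psmOutlierRate >= 1)
        msg <- c(msg, "'psmOutlierRate' must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SimulationConfig Constructor with the package's default study
#'   design: 5 compartments, 20 markers and 100 unknowns per class, 10 noise
#'   proteins, 4 PSMs per protein and replicate.
#' @param templates,nMarkersPerClass,nUnknownsPerClass,nNoiseProteins See slots.
#' @param fracRep1Only,psmPerProtein,psmNoiseConcentration,psmOutlierRate,seed
#'   See slots.
#' @export
simulationConfig <- function(templates = defaultTemplates(),
                             nMarkersPerClass = 20L,
                             nUnknownsPerClass = 100L,
                             nNoiseProteins = 10L,
                             fracRep1Only = 0.05,
                             psmPerProtein = 4L,
                             psmNoiseConcentration = 120,
                             psmOutlierRate = 0.02,
                             seed = 1L) {
    new("SimulationConfig", templates = templates,
        nMarkersPerClass = as.integer(nMarkersPerClass),
        nUnknownsPerClass = as.integer(nUnknownsPerClass),
        nNoiseProteins = as.integer(nNoiseProteins),
        fracRep1Only = as.numeric(fracRep1Only),
        psmPerProtein = as.integer(psmPerProtein),
        psmNoiseConcentration = as.numeric(psmNoiseConcentration),
        psmOutlierRate = as.numeric(psmOutlierRate),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    nms <- vapply(object@templates, slot, character(1), "name")
    cat("SimulationConfig:", length(nms), "compartments (",
        paste(nms, collapse = ", "), ")\n")
    cat("  per class:", object@nMarkersPerClass, "markers +",
        object@nUnknownsPerClass, "unknowns;",
        object@nNoiseProteins, "noise proteins\n")
    cat("  PSMs/protein/replicate:", object@psmPerProtein,
        "| rep1-only fraction:", object@fracRep1Only,
        "| seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## FractionProfileSet
## ---------------------------------------------------------------------------

#' Merged fractionation profiles
#'
#' A \linkS4class{SummarizedExperiment} holding, for each protein identified
#' in both biological replicates, the concatenated 20-channel relative
#' abundance profile (10 gradient fractions per replicate, each replicate
#' block summing to 1). \code{colData} records replicate and fraction for
#' every channel; \code{rowData} carries PSM counts and, once markers are
#' attached, the curated marker class.
#'
#' @export
setClass("FractionProfileSet", contains = "SummarizedExperiment")

setValidity("FractionProfileSet", function(object) {
    msg <- NULL
    m <- SummarizedExperiment::assay(object)
    if (ncol(m) != 20L)
        msg <- c(msg, "profiles must have 20 channels (2 replicates x 10 fractions)")
    else {
        if (any(!is.finite(m)) || any(m < 0))
            msg <- c(msg, "profile values must be finite and nonnegative")
        if (nrow(m) > 0) {
            s1 <- rowSums(m[, 1:10, drop = FALSE])
            s2 <- rowSums(m[, 11:20, drop = FALSE])
            if (any(abs(s1 - 1) > 1e-9) || any(abs(s2 - 1) > 1e-9))
                msg <- c(msg, "each replicate block must sum to 1 (tolerance 1e-9)")
        }
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "profiles must have unique protein-id rownames")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn FractionProfileSet Constructor from two per-replicate profile
#'   matrices (proteins x 10 fractions, identical rownames; rows sum to 1).
#' @param rep1,rep2 Numeric matrices, proteins x 10 fractions, with protein
#'   ids as rownames.
#' @param nPsmsRep1,nPsmsRep2 Optional integer vectors of accepted-PSM counts
#'   per protein.
#' @export
FractionProfileSet <- function(rep1, rep2, nPsmsRep1 = NULL, nPsmsRep2 = NULL) {
    stopifnot(is.matrix(rep1), is.matrix(rep2),
              ncol(rep1) == 10L, ncol(rep2) == 10L,
              !is.null(rownames(rep1)), !is.null(rownames(rep2)))
    if (!identical(rownames(rep1), rownames(rep2)))
        stop("rep1 and rep2 must cover the same proteins in the same order; ",
             "use mergeReplicates() for raw per-replicate inputs")
    combined <- cbind(rep1, rep2)
    colnames(combined) <- paste0(rep(c("rep1", "rep2"), each = 10), "_F",
                                 sprintf("%02d", rep(1:10, 2)))
    cd <- S4Vectors::DataFrame(
        replicate = factor(rep(c("rep1", "rep2"), each = 10)),
        fraction = rep(1:10, 2),
        row.names = colnames(combined))
    n <- nrow(combined)
    fill <- function(v) if (is.null(v)) rep(NA_integer_, n) else as.integer(v)
    rd <- S4Vectors::DataFrame(
        nPsmsRep1 = fill(nPsmsRep1), nPsmsRep2 = fill(nPsmsRep2),
        markerClass = rep(NA_character_, n),
        row.names = rownames(combined))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(profile = combined), colData = cd, rowData = rd)
    new("FractionProfileSet", se)
}

setMethod("show", "FractionProfileSet", function(object) {
    cat("FractionProfileSet:", nrow(object),
        "proteins x 20 channels (2 replicates x 10 fractions)\n")
    mk <- SummarizedExperiment::rowData(object)$markerClass
    n <- sum(!is.na(mk))
    if (n > 0) {
        tab <- table(mk[!is.na(mk)])
        cat("  markers:", n, "(",
            paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
    } else cat("  markers: none attached\n")
})

## ---------------------------------------------------------------------------
## MarkerSet
## ---------------------------------------------------------------------------

#' Curated marker proteins
#'
#' Maps marker protein ids to one of the compartment labels used as
#' supervised training classes.
#'
#' @slot entries Named character vector: names are protein ids, values are
#'   class labels.
#' @slot classes Ordered character vector of allowed class labels.
#' @export
setClass("MarkerSet",
    representation(entries = "character", classes = "character"))

setValidity("MarkerSet", function(object) {
    msg <- NULL
    if (length(object@classes) < 2L)
        msg <- c(msg, "at least 2 classes are required")
    if (anyDuplicated(object@classes))
        msg <- c(msg, "class labels must be unique")
    if (is.null(names(object@entries)) || any(!nzchar(names(object@entries))))
        msg <- c(msg, "'entries' must be named by protein id")
    if (anyDuplicated(names(object@entries)))
        msg <- c(msg, "each marker protein must appear exactly once")
    bad <- setdiff(unique(object@entries), object@classes)
    if (length(bad))
        msg <- c(msg, paste0("unknown class label(s): ",
                             paste(bad, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' @describeIn MarkerSet Constructor from parallel vectors of protein ids and
#'   class labels.
#' @param proteinIds Character vector of marker protein ids.
#' @param labels Character vector of class labels, same length.
#' @param classes Allowed class vocabulary (default the five canonical
#'   compartments of \code{\link{lopitClasses}}).
#' @export
markerSet <- function(proteinIds, labels, classes = lopitClasses()) {
    stopifnot(length(proteinIds) == length(labels))
    entries <- as.character(labels)
    names(entries) <- as.character(proteinIds)
    new("MarkerSet", entries = entries, classes = as.character(classes))
}

setMethod("show", "MarkerSet", function(object) {
    cat("MarkerSet:", length(object@entries), "markers,",
        length(object@classes), "classes\n")
    tab <- table(factor(object@entries, levels = object@classes))
    cat(" ", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
})

#' @describeIn MarkerSet Number of markers.
#' @param x A \code{MarkerSet}.
#' @export
setMethod("length", "MarkerSet", function(x) length(x@entries))

## ---------------------------------------------------------------------------
## ClassifierSpec
## ---------------------------------------------------------------------------

#' SVM classifier specification
#'
#' Hyperparameter search space and cross-validation design for the
#' class-weighted RBF-kernel SVM. Class weights default to inverse class
#' frequency (computed from the training set at fit time).
#'
#' @slot costGrid,gammaGrid Positive reals searched over their Cartesian
#'   product.
#' @slot classWeights Named positive weights; empty means compute inverse
#'   frequency weights from the training labels.
#' @slot cvOuterRounds Rounds of stratified 80/20 partitioning used to
#'   estimate generalization macro-F1 and select hyperparameters.
#' @slot cvInnerFolds Folds of the inner stratified cross-validation that
#'   picks (cost, gamma) within each outer round.
#' @slot seed RNG seed making tuning and Platt scaling reproducible.
#' @export
setClass("ClassifierSpec",
    representation(costGrid = "numeric", gammaGrid = "numeric",
                   classWeights = "numeric", cvOuterRounds = "integer",
                   cvInnerFolds = "integer", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
    msg <- NULL
    if (length(object@costGrid) == 0L || any(object@costGrid <= 0))
        msg <- c(msg, "'costGrid' must be nonempty and positive")
    if (length(object@gammaGrid) == 0L || any(object@gammaGrid <= 0))
        msg <- c(msg, "'gammaGrid' must be nonempty and positive")
    if (length(object@classWeights) && any(object@classWeights <= 0))
        msg <- c(msg, "'classWeights' must be strictly positive")
    if (object@cvOuterRounds < 1L || object@cvInnerFolds < 2L)
        msg <- c(msg, "'cvOuterRounds' must be >= 1 and 'cvInnerFolds' >= 2")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ClassifierSpec Constructor. Default grids span \code{2^-4}
#'   to \code{2^4} (9 log-spaced values each).
#' @param costGrid,gammaGrid,classWeights,cvOuterRounds,cvInnerFolds,seed See
#'   slots.
#' @export
classifierSpec <- function(costGrid = 2^(-4:4), gammaGrid = 2^(-4:4),
                           classWeights = numeric(0),
                           cvOuterRounds = 100L, cvInnerFolds = 5L,
                           seed = 1L) {
    new("ClassifierSpec", costGrid = as.numeric(costGrid),
        gammaGrid = as.numeric(gammaGrid),
        classWeights = classWeights,
        cvOuterRounds = as.integer(cvOuterRounds),
        cvInnerFolds = as.integer(cvInnerFolds), seed = as.integer(seed))
}

setMethod("show", "ClassifierSpec", function(object) {
    cat("ClassifierSpec: RBF kernel;",
        length(object@costGrid), "x", length(object@gammaGrid),
        "(cost x gamma) grid;",
        object@cvOuterRounds, "outer rounds,",
        object@cvInnerFolds, "inner folds; seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## TrainedClassifier
## ---------------------------------------------------------------------------

#' Trained localization classifier
#'
#' The refit class-weighted RBF SVM together with the chosen
#' hyperparameters, cross-validation performance estimate and provenance.
#'
#' @slot model The fitted \code{e1071::svm} object.
#' @slot platt Per-class-pair Platt sigmoid parameters (A, B) fitted on the
#'   training decision values, used to turn one-vs-one decision values into
#'   coupled class-membership probabilities.
#' @slot classes Class labels in canonical order.
#' @slot cost,gamma Chosen hyperparameters.
#' @slot classWeights Weights used at fit time (mean 1).
#' @slot cvMacroF1 Mean held-out macro-F1 across outer rounds.
#' @slot perRound Per-outer-round data.frame: chosen cost, gamma, macro-F1.
#' @slot seed RNG seed used for tuning.
#' @slot trainingHash Hash of the training matrix and labels, for
#'   provenance.
#' @export
setClass("TrainedClassifier",
    representation(model = "ANY", platt = "list",
                   classes = "character", cost = "numeric",
                   gamma = "numeric", classWeights = "numeric",
                   cvMacroF1 = "numeric", perRound = "data.frame",
                   seed = "integer", trainingHash = "character"))

setMethod("show", "TrainedClassifier", function(object) {
    cat("TrainedClassifier: RBF SVM,", length(object@classes), "classes\n")
    cat("  cost =", object@cost, "| gamma =", object@gamma,
        "| CV macro-F1 =", round(object@cvMacroF1, 3), "\n")
})

## ---------------------------------------------------------------------------
## ThresholdSet
## ---------------------------------------------------------------------------

#' Per-class score thresholds
#'
#' Minimum winning-class score required to assign a protein to each
#' compartment; proteins scoring below their predicted class's threshold are
#' reported as unclassified. Thresholds are either calibrated to a target
#' false discovery rate against held-out annotation
#' (\code{\link{calibrateThresholds}}) or fixed by the user.
#'
#' @slot thresholds Named numeric, one per class. A value slightly above 1
#'   means the class assigns nothing.
#' @slot fdrTarget Target FDR used in calibration (NA for fixed cutoffs).
#' @slot method "fdr" or "fixed".
#' @export
setClass("ThresholdSet",
    representation(thresholds = "numeric", fdrTarget = "numeric",
                   method = "character"))

setValidity("ThresholdSet", function(object) {
    msg <- NULL
    th <- object@thresholds
    if (is.null(names(th)) || any(!nzchar(names(th))))
        msg <- c(msg, "'thresholds' must be named by class")
    if (any(!is.finite(th)) || any(th < 0) || any(th > 1 + 1e-6))
        msg <- c(msg, "thresholds must lie in [0, 1] (or 1 + epsilon for 'assign nothing')")
    if (!object@method %in% c("fdr", "fixed"))
        msg <- c(msg, "'method' must be 'fdr' or 'fixed'")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ThresholdSet Constructor for fixed per-class cutoffs. The
#'   defaults are the cutoffs used for the published cyanobacterial map:
#'   0.75 for TM, PM and both ribosomal subunits, 0.65 for soluble.
#' @param thresholds Named numeric vector of per-class cutoffs.
#' @export
fixedThresholds <- function(thresholds = c(TM = 0.75, PM = 0.75,
                                           soluble = 0.65,
                                           small_ribosomal = 0.75,
                                           large_ribosomal = 0.75)) {
    new("ThresholdSet", thresholds = thresholds, fdrTarget = NA_real_,
        method = "fixed")
}

setMethod("show", "ThresholdSet", function(object) {
    cat("ThresholdSet (", object@method, " mode", sep = "")
    if (!is.na(object@fdrTarget))
        cat(", FDR target ", object@fdrTarget, sep = "")
    cat("):\n")
    th <- object@thresholds
    cat(" ", paste(names(th), round(th, 4), sep = "=", collapse = ", "), "\n")
})
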