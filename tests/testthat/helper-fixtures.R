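# Shared fixtures and independent oracles, all built in code.

# Small but complete simulated experiment (5 classes).
tinySim <- function(seed = 7, nMarkersPerClass = 4, nUnknownsPerClass = 6,
                    nNoiseProteins = 2, ...) {
    simulateDataset(simulationConfig(
        nMarkersPerClass = nMarkersPerClass,
        nUnknownsPerClass = nUnknownsPerClass,
        nNoiseProteins = nNoiseProteins, seed = seed, ...))
}

# Zero-noise configuration: huge Dirichlet concentrations collapse every
# profile onto its template mean; no outliers, no replicate dropout.
zeroNoiseConfig <- function(seed = 7, nMarkersPerClass = 4,
                            nUnknownsPerClass = 6, nNoiseProteins = 2) {
    simulationConfig(templates = defaultTemplates(concentration = 1e9),
                     nMarkersPerClass = nMarkersPerClass,
                     nUnknownsPerClass = nUnknownsPerClass,
                     nNoiseProteins = nNoiseProteins,
                     fracRep1Only = 0, psmNoiseConcentration = 1e9,
                     psmOutlierRate = 0, seed = seed)
}

# A fast classifier spec for unit tests.
smallSpec <- function(seed = 1, ...) {
    classifierSpec(costGrid = c(1, 4), gammaGrid = c(0.5, 2),
                   cvOuterRounds = 3L, cvInnerFolds = 2L, seed = seed, ...)
}

# Independent nearest-centroid classifier (oracle for degenerate cases).
nearestCentroid <- function(trainX, trainY, x) {
    cents <- do.call(rbind, lapply(split(seq_along(trainY), trainY),
                                   function(i) colMeans(trainX[i, , drop = FALSE])))
    d <- as.matrix(dist(rbind(cents, x)))[-(seq_len(nrow(cents))),
                                          seq_len(nrow(cents)), drop = FALSE]
    rownames(cents)[apply(d, 1, which.min)]
}

# Brute-force FDR threshold oracle: exhaustive scan over all candidate
# cutoffs (observed scores plus 1.0); FDR of an empty selection is 0.
bruteForceThreshold <- function(score, correct, target) {
    cand <- sort(unique(c(score, 1.0)))
    for (t in cand) {
        sel <- score >= t
        fdr <- if (!any(sel)) 0 else mean(!correct[sel])
        if (fdr <= target) return(t)
    }
    1 + 1e-9
}

# Randomized scored-and-annotated instance for calibration tests.
randomScoreInstance <- function(n, classes = c("TM", "PM", "soluble"),
                                seed = 1) {
    set.seed(seed)
    data.frame(protein_id = sprintf("p%03d", seq_len(n)),
               predicted_class = sample(classes, n, replace = TRUE),
               score = round(runif(n), 3),
               true_class = sample(classes, n, replace = TRUE),
               stringsAsFactors = FALSE)
}

# Per-class thresholds computed with the brute-force oracle.
oracleThresholds <- function(inst, target, classes) {
    vapply(classes, function(cl) {
        sel <- inst$predicted_class == cl
        if (!any(sel)) return(1 + 1e-9)
        bruteForceThreshold(inst$score[sel],
                            inst$true_class[sel] == cl, target)
    }, numeric(1))
}

# Profiles built directly from matrices: two degenerate, well-separated
# classes with zero within-class variance.
degenerateFps <- function(nPerClass = 4) {
    a <- c(0.8, 0.2, rep(0, 8))
    b <- c(rep(0, 8), 0.3, 0.7)
    rep1 <- rbind(matrix(a, nPerClass, 10, byrow = TRUE),
                  matrix(b, nPerClass, 10, byrow = TRUE))
    rownames(rep1) <- sprintf("p%02d", seq_len(2 * nPerClass))
    FractionProfileSet(rep1, rep1)
}

degenerateMarkers <- function(nPerClass = 4) {
    markerSet(sprintf("p%02d", seq_len(2 * nPerClass)),
              rep(c("A", "B"), each = nPerClass), classes = c("A", "B"))
}
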