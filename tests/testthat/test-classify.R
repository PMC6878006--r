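test_that("class weights are inverse frequencies with mean 1", {
    expect_equal(computeClassWeights(rep(c("A", "B"), c(10, 40))),
                 c(A = 1.6, B = 0.4))
    expect_equal(computeClassWeights(rep(c("A", "B", "C"), each = 7)),
                 c(A = 1, B = 1, C = 1))
    # sizes {1, 1, 2} -> weights prop. {2, 2, 1} -> normalized {1.2, 1.2, 0.6}
    expect_equal(computeClassWeights(c("A", "B", "C", "C")),
                 c(A = 1.2, B = 1.2, C = 0.6))
    expect_error(computeClassWeights(character(0)), "at least one")
})

test_that("a one-pair grid is chosen without search", {
    fps <- degenerateFps()
    spec <- classifierSpec(costGrid = 2, gammaGrid = 0.7,
                           cvOuterRounds = 2L, cvInnerFolds = 2L, seed = 1)
    model <- tuneAndTrain(fps, degenerateMarkers(), spec)
    expect_equal(model@cost, 2)
    expect_equal(model@gamma, 0.7)
})

test_that("separable degenerate clusters give perfect cross-validation", {
    model <- tuneAndTrain(degenerateFps(), degenerateMarkers(), smallSpec())
    expect_equal(model@cvMacroF1, 1.0)
})

test_that("scores are probabilities: sum to 1 with argmax prediction", {
    sim <- tinySim(seed = 31)
    fps <- profilesFromPsms(sim$psms)
    model <- tuneAndTrain(fps, sim$markers, smallSpec())
    sc <- scoreAll(model, fps)
    expect_setequal(sc$protein_id, proteinIds(fps))
    probCols <- paste0("score_", model@classes)
    probs <- as.matrix(sc[, probCols])
    expect_true(all(abs(rowSums(probs) - 1) <= 1e-9))
    expect_true(all(sc$score >= 0 & sc$score <= 1))
    win <- model@classes[max.col(probs, ties.method = "first")]
    expect_identical(sc$predicted_class, win)
    expect_equal(sc$score, probs[cbind(seq_len(nrow(probs)),
                                       match(sc$predicted_class,
                                             model@classes))])
})

test_that("a protein identical to a marker inherits its class", {
    fps <- degenerateFps()
    mk <- markerSet(c("p01", "p02", "p05", "p06"),
                    c("A", "A", "B", "B"), classes = c("A", "B"))
    model <- tuneAndTrain(fps, mk, smallSpec())
    sc <- scoreAll(model, fps)
    # p03/p04 share p01's profile exactly; p07/p08 share p05's
    expect_equal(sc$predicted_class[match(c("p03", "p07"), sc$protein_id)],
                 c("A", "B"))
})

test_that("tuning and scoring are deterministic under a fixed seed", {
    sim <- tinySim(seed = 32)
    fps <- profilesFromPsms(sim$psms)
    spec <- smallSpec(seed = 99)
    m1 <- tuneAndTrain(fps, sim$markers, spec)
    m2 <- tuneAndTrain(fps, sim$markers, spec)
    expect_identical(c(m1@cost, m1@gamma), c(m2@cost, m2@gamma))
    expect_identical(m1@perRound, m2@perRound)
    expect_identical(scoreAll(m1, fps), scoreAll(m2, fps))
})

test_that("zero-noise SVM predictions equal the nearest-centroid oracle", {
    sim <- simulateDataset(zeroNoiseConfig(seed = 33))
    fps <- profilesFromPsms(sim$psms)
    model <- tuneAndTrain(fps, sim$markers, smallSpec())
    sc <- scoreAll(model, fps)

    mk <- markerClasses(sim$markers)
    m <- profileMatrix(fps)
    oracle <- nearestCentroid(m[names(mk), ], unname(mk), m)
    # equivalence holds where class structure exists; flat-profile noise
    # proteins sit far from every cluster and carry no meaningful label
    truth <- sim$truth[match(sc$protein_id, sim$truth$protein_id), ]
    nonNoise <- truth$true_label != "noise"
    expect_identical(sc$predicted_class[nonNoise],
                     unname(oracle)[nonNoise])

    # and every non-noise protein is predicted as its true compartment
    expect_identical(sc$predicted_class[nonNoise],
                     truth$true_label[nonNoise])
})

test_that("refit model stays self-consistent on its markers", {
    sim <- tinySim(seed = 34, nMarkersPerClass = 8)
    fps <- profilesFromPsms(sim$psms)
    model <- tuneAndTrain(fps, sim$markers, smallSpec())
    sc <- scoreAll(model, fps)
    mk <- markerClasses(sim$markers)
    mk <- mk[names(mk) %in% sc$protein_id]
    pred <- sc$predicted_class[match(names(mk), sc$protein_id)]
    expect_gte(mean(pred == unname(mk)), 0.95)
})

test_that("dimension mismatches are rejected", {
    fps <- degenerateFps()
    model <- tuneAndTrain(fps, degenerateMarkers(), smallSpec())
    bad <- matrix(0.05, 2, 12,
                  dimnames = list(c("x1", "x2"), NULL))
    expect_error(scoreAll(model, bad), "dimension")
})

test_that("single-member classes cannot be stratified", {
    fps <- degenerateFps()
    mk <- markerSet(c("p01", "p05"), c("A", "B"), classes = c("A", "B"))
    expect_error(tuneAndTrain(fps, mk, smallSpec()), "fewer than 2")
})
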