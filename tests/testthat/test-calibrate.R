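test_that("threshold calibration matches the walked-through example", {
    sc <- data.frame(protein_id = c("a", "b", "c"),
                     predicted_class = "TM", score = c(0.9, 0.8, 0.7),
                     stringsAsFactors = FALSE)
    ann <- c(a = "TM", b = "TM", c = "PM")
    # candidates {0.7, 0.8, 0.9, 1.0}: at 0.7 FDR = 1/3 > 0.075,
    # at 0.8 FDR = 0/2 -> smallest qualifying cutoff is 0.8
    th <- calibrateThresholds(sc, ann, 0.075, classes = "TM")
    expect_equal(unname(thresholds(th)), 0.8)
    expect_equal(unname(thresholds(th)),
                 bruteForceThreshold(sc$score, c(TRUE, TRUE, FALSE), 0.075))
})

test_that("all-correct annotation yields the smallest observed score", {
    sc <- data.frame(protein_id = c("a", "b", "c", "d"),
                     predicted_class = c("TM", "TM", "PM", "PM"),
                     score = c(0.9, 0.55, 0.6, 0.85),
                     stringsAsFactors = FALSE)
    ann <- c(a = "TM", b = "TM", c = "PM", d = "PM")
    th <- thresholds(calibrateThresholds(sc, ann, 0.075,
                                         classes = c("TM", "PM")))
    expect_equal(unname(th), c(0.55, 0.6))

    # near-vacuous FDR target: everything passes at the smallest score
    lax <- thresholds(calibrateThresholds(
        sc, c(a = "TM", b = "PM", c = "PM", d = "TM"), 1 - 1e-9,
        classes = c("TM", "PM")))
    expect_equal(unname(lax), c(0.55, 0.6))
})

test_that("unattainable targets disable a class with a warning", {
    sc <- data.frame(protein_id = c("a", "b"), predicted_class = "TM",
                     score = c(1.0, 1.0), stringsAsFactors = FALSE)
    expect_warning(
        th <- calibrateThresholds(sc, c(a = "PM", b = "PM"), 0.075,
                                  classes = "TM"),
        "cannot attain")
    expect_gt(unname(thresholds(th)), 1)

    expect_warning(
        th2 <- calibrateThresholds(sc, c(a = "TM", b = "TM"), 0.075,
                                   classes = c("TM", "PM")),
        "no annotated predictions")
    expect_gt(thresholds(th2)[["PM"]], 1)
})

test_that("calibration agrees with brute force on randomized instances", {
    classes <- c("TM", "PM", "soluble")
    for (s in 1:50) {
        inst <- randomScoreInstance(n = sample(5:50, 1), seed = s)
        ann <- setNames(inst$true_class, inst$protein_id)
        got <- suppressWarnings(
            thresholds(calibrateThresholds(inst, ann, 0.1,
                                           classes = classes)))
        expect_equal(unname(got), unname(oracleThresholds(inst, 0.1, classes)),
                     info = paste("instance", s))
    }
})

test_that("thresholds rise monotonically as the FDR target tightens", {
    classes <- c("TM", "PM", "soluble")
    targets <- c(0.02, 0.075, 0.2, 0.5)
    for (s in 1:20) {
        inst <- randomScoreInstance(n = 40, seed = 100 + s)
        ann <- setNames(inst$true_class, inst$protein_id)
        th <- sapply(targets, function(tg) suppressWarnings(
            thresholds(calibrateThresholds(inst, ann, tg, classes = classes))))
        # columns ordered by loosening target: thresholds must not increase
        expect_true(all(diff(t(th)) <= 1e-12))
    }
})

test_that("fixed cutoffs reproduce the published boundary semantics", {
    sc <- data.frame(protein_id = c("x1", "x2", "x3", "x4"),
                     predicted_class = c("TM", "soluble", "TM", "PM"),
                     score = c(0.74, 0.66, 0.76, 0.74),
                     stringsAsFactors = FALSE)
    asn <- assignProteins(sc, fixedThresholds())
    expect_equal(asn$final_label,
                 c("unclassified", "soluble", "TM", "unclassified"))
})

test_that("markers always keep their curated label", {
    sc <- data.frame(protein_id = c("m1", "u1"),
                     predicted_class = c("PM", "PM"),
                     score = c(0.1, 0.95), stringsAsFactors = FALSE)
    mk <- markerSet("m1", "TM")
    asn <- assignProteins(sc, fixedThresholds(), mk)
    expect_equal(asn$final_label, c("TM", "PM"))
    expect_equal(asn$is_marker, c(TRUE, FALSE))
})

test_that("a missing class threshold is an error", {
    sc <- data.frame(protein_id = "a", predicted_class = "TM", score = 0.9,
                     stringsAsFactors = FALSE)
    expect_error(assignProteins(sc, fixedThresholds(c(PM = 0.75))), "TM")
})

test_that("assignment summaries partition the table", {
    empty <- data.frame(protein_id = character(0),
                        final_label = character(0))
    s0 <- summarizeAssignments(empty)
    expect_true(all(s0$counts == 0))
    expect_equal(s0$total, 0)

    asn <- data.frame(protein_id = c("a", "b", "c"),
                      final_label = c("TM", "TM", "unclassified"))
    s <- summarizeAssignments(asn)
    expect_equal(s$counts[["TM"]], 2)
    expect_equal(s$counts[["unclassified"]], 1)
    expect_equal(sum(s$counts), s$total)

    sim <- tinySim(seed = 41)
    fps <- profilesFromPsms(sim$psms)
    model <- tuneAndTrain(fps, sim$markers, smallSpec())
    sc <- scoreAll(model, fps)
    full <- assignProteins(sc, fixedThresholds(), sim$markers)
    expect_equal(sum(summarizeAssignments(full)$counts), nrow(sc))
})
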