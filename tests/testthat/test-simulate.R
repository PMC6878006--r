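test_that("configuration preconditions are enforced", {
    expect_error(simulationConfig(templates = defaultTemplates()[1]),
                 "at least 2")
    expect_error(simulationConfig(nMarkersPerClass = 1), ">= 2")
    expect_error(simulationConfig(fracRep1Only = 1), "fracRep1Only")
    expect_error(compartmentTemplate("x", rep(0.1, 5)), "length 10")
    dup <- defaultTemplates()
    dup[[2]] <- dup[[1]]
    expect_error(simulationConfig(templates = dup), "unique")
})

test_that("default templates are valid, distinct compartment shapes", {
    tpl <- defaultTemplates()
    expect_length(tpl, 5)
    expect_setequal(vapply(tpl, function(t) t@name, character(1)),
                    lopitClasses())
    for (t in tpl) {
        expect_equal(sum(t@meanProfile), 1, tolerance = 1e-12)
        expect_true(all(t@meanProfile >= 0))
    }
    peaks <- vapply(tpl, function(t) which.max(t@meanProfile), integer(1))
    expect_gt(length(unique(peaks)), 1)
    profiles <- t(vapply(tpl, function(t) t@meanProfile, numeric(10)))
    d <- dist(profiles)
    expect_true(all(d > 0))
})

test_that("simulated datasets are reproducible and structurally sound", {
    s1 <- tinySim(seed = 7)
    s2 <- tinySim(seed = 7)
    expect_identical(s1$psms, s2$psms)
    expect_identical(s1$truth, s2$truth)

    # every generated protein appears exactly once in the truth table
    expect_false(anyDuplicated(s1$truth$protein_id) > 0)
    expect_setequal(unique(s1$psms$protein_group_id), s1$truth$protein_id)

    # reporter values are nonnegative and finite
    m <- as.matrix(s1$psms[, sprintf("reporter_%02d", 1:10)])
    expect_true(all(is.finite(m)) && all(m >= 0))

    # markers are flagged consistently and sized per class
    expect_equal(sum(s1$truth$is_marker), 5 * 4)
    mk <- markerClasses(s1$markers)
    expect_equal(unname(table(mk)[lopitClasses()]), rep(4L, 5),
                 ignore_attr = TRUE)
    expect_true(all(s1$truth$true_label[s1$truth$is_marker] ==
                    mk[s1$truth$protein_id[s1$truth$is_marker]]))

    # noise proteins carry the "noise" label and no marker flag
    noise <- s1$truth[s1$truth$true_label == "noise", ]
    expect_equal(nrow(noise), 2)
    expect_false(any(noise$is_marker))
})

test_that("replicate-1-only proteins are absent from replicate 2", {
    sim <- tinySim(seed = 11, nUnknownsPerClass = 30, fracRep1Only = 0.3)
    byRep <- split(sim$psms$protein_group_id, sim$psms$replicate)
    onlyR1 <- setdiff(byRep$rep1, byRep$rep2)
    expect_gt(length(onlyR1), 0)
    expect_true(all(sim$truth$protein_id %in% byRep$rep1))
})

test_that("zero-noise limit collapses profiles onto template means", {
    cfg <- zeroNoiseConfig(seed = 3)
    sim <- simulateDataset(cfg)
    fps <- profilesFromPsms(sim$psms)
    tplMeans <- vapply(cfg@templates, function(t) t@meanProfile,
                       numeric(10))
    colnames(tplMeans) <- vapply(cfg@templates, function(t) t@name,
                                 character(1))
    nonNoise <- sim$truth[sim$truth$true_label != "noise", ]
    for (r in c("rep1", "rep2")) {
        m <- profileMatrix(fps, r)[nonNoise$protein_id, ]
        expect_lt(max(abs(m - t(tplMeans)[nonNoise$true_label, ])), 1e-3)
    }
})

test_that("larger concentrations tighten within-class clusters", {
    avgWithin <- function(conc) {
        sim <- simulateDataset(simulationConfig(
            templates = defaultTemplates(concentration = conc),
            nMarkersPerClass = 2, nUnknownsPerClass = 18,
            nNoiseProteins = 0, fracRep1Only = 0,
            psmNoiseConcentration = 1e6, psmOutlierRate = 0, seed = 42))
        fps <- profilesFromPsms(sim$psms)
        m <- profileMatrix(fps)
        mean(vapply(split(sim$truth$protein_id, sim$truth$true_label),
                    function(ids) mean(dist(m[ids, ])), numeric(1)))
    }
    d <- vapply(c(5, 60, 500), avgWithin, numeric(1))
    expect_true(all(diff(d) < 0))
})
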