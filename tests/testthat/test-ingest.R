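test_that("spectrum normalization is ratio-to-sum", {
    expect_equal(normalizeSpectrum(rep(500, 10)), rep(0.1, 10))
    expect_equal(normalizeSpectrum(c(1, rep(0, 9))), c(1, rep(0, 9)))
    expect_equal(normalizeSpectrum(c(1, 2, 3, 4, rep(0, 6))),
                 c(0.1, 0.2, 0.3, 0.4, rep(0, 6)))
    expect_error(normalizeSpectrum(rep(0, 10)), "all-zero")
    expect_error(normalizeSpectrum(c(-1, rep(1, 9))), "nonnegative")
    expect_error(normalizeSpectrum(rep(1, 9)), "10 reporter")
})

test_that("protein aggregation is the renormalized channel-wise median", {
    # median of one PSM is that PSM's normalized vector
    one <- c(2, 2, 4, rep(0, 7))
    expect_equal(aggregateProtein(one), c(0.25, 0.25, 0.5, rep(0, 7)))

    # channel median before renormalization follows the median definition
    m <- rbind(c(0.1, 0.9, rep(0, 8)),
               c(0.2, 0.8, rep(0, 8)),
               c(0.9, 0.1, rep(0, 8)))
    raw <- aggregateProtein(m * 1000, renormalize = FALSE)
    expect_equal(raw[1], 0.2)

    # hand-computed: medians (0.5, 0.5, 0, ...) already sum to 1
    m2 <- rbind(c(0.5, 0.5, rep(0, 8)),
                c(0.5, 0.5, rep(0, 8)),
                c(0, 0, 1, rep(0, 7)))
    expect_equal(aggregateProtein(m2), c(0.5, 0.5, 0, rep(0, 7)))

    expect_error(aggregateProtein(matrix(1, 0, 10)), "at least one")
})

test_that("quantifiable-PSM filter rejects with reasons, not errors", {
    sim <- tinySim(seed = 5)
    psms <- sim$psms
    psms[1, "reporter_03"] <- NA
    psms[2, sprintf("reporter_%02d", 1:10)] <- 0
    psms[3, "reporter_01"] <- -5
    bp <- buildProfiles(psms)
    expect_equal(nrow(bp$rejected), 3)
    expect_setequal(unique(bp$rejected$reason),
                    c("non-finite reporter value", "negative reporter value",
                      "zero total reporter intensity"))
})

test_that("more than two replicate labels are rejected", {
    sim <- tinySim(seed = 5)
    psms <- sim$psms
    psms$replicate[1] <- "rep3"
    expect_error(buildProfiles(psms), "rep3")
})

test_that("aggregation is invariant to PSM order", {
    sim <- tinySim(seed = 9)
    bp1 <- buildProfiles(sim$psms)
    set.seed(1)
    bp2 <- buildProfiles(sim$psms[sample(nrow(sim$psms)), ])
    expect_equal(bp1$rep1, bp2$rep1, tolerance = 1e-15)
    expect_equal(bp1$rep2, bp2$rep2, tolerance = 1e-15)
})

test_that("replicate merge keeps exactly the both-replicate intersection", {
    prof <- function(ids) {
        m <- matrix(0.1, length(ids), 10)
        rownames(m) <- ids
        m
    }
    fps <- mergeReplicates(prof(c("A", "B")), prof(c("B", "C")))
    expect_equal(proteinIds(fps), "B")
    expect_setequal(S4Vectors::metadata(fps)$dropped, c("A", "C"))

    ids <- sprintf("p%d", 1:5)
    expect_equal(nrow(mergeReplicates(prof(ids), prof(ids))), 5)

    expect_error(mergeReplicates(prof("A"), prof("B")), "both replicates")
})

test_that("profile blocks are compositional and round-trip exactly", {
    sim <- tinySim(seed = 13, fracRep1Only = 0.2)
    fps <- profilesFromPsms(sim$psms)
    m <- profileMatrix(fps)
    expect_equal(ncol(m), 20)
    expect_true(all(abs(rowSums(m[, 1:10]) - 1) <= 1e-9))
    expect_true(all(abs(rowSums(m[, 11:20]) - 1) <= 1e-9))
    expect_equal(m, cbind(profileMatrix(fps, "rep1"),
                          profileMatrix(fps, "rep2")),
                 ignore_attr = TRUE)

    path <- withr::local_tempfile(fileext = ".csv")
    writeProfileTable(fps, path)
    back <- readProfileTable(path)
    expect_lt(max(abs(back$rep1[rownames(m), ] - profileMatrix(fps, "rep1"))),
              1e-12)
    expect_lt(max(abs(back$rep2[rownames(m), ] - profileMatrix(fps, "rep2"))),
              1e-12)
})

test_that("raw protein-level tables are normalized on read", {
    df <- data.frame(protein_id = rep(c("a", "b"), 2),
                     replicate = rep(c("rep1", "rep2"), each = 2),
                     matrix(rep(c(2, 4), each = 4 * 5), 4, 10))
    names(df)[3:12] <- sprintf("channel_%02d", 1:10)
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, path, row.names = FALSE)
    pt <- readProfileTable(path, values = "raw")
    expect_equal(unname(rowSums(pt$rep1)), c(1, 1))
})
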