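test_that("one-condition simulator honors the design and hits the target SNR", {
    d <- simulationDesign("one_condition", nGenes = 600, nSamples = 8,
                          nGroundTruth = 60, nKnowledge = 15, snrDb = 10)
    sim <- simulateOneCondition(d, seed = 3)
    expect_equal(dim(sim$x), c(600, 8))
    expect_length(truthGenes(sim$truth), 60)
    expect_length(knowledgeGenes(sim$truth), 15)
    expect_true(all(knowledgeGenes(sim$truth) %in% truthGenes(sim$truth)))
    expect_lt(abs(realizedSnr(sim$truth) - 10), 0.2)

    # ground truth = largest |loading| on process 1
    A <- sim$truth@aTrue
    ord <- order(-abs(A[, 1]), rownames(sim$x))
    expect_setequal(truthGenes(sim$truth), rownames(sim$x)[ord[1:60]])

    # noiseless limit: X = A T exactly
    dInf <- d; dInf@snrDb <- Inf
    simInf <- simulateOneCondition(dInf, seed = 3)
    expect_equal(unname(simInf$x),
                 simInf$truth@aTrue %*% simInf$truth@tTrue[[1]])

    # determinism
    sim2 <- simulateOneCondition(d, seed = 3)
    expect_identical(sim2$x, sim$x)
})

test_that("two-condition simulator removes exactly the ground-truth loadings", {
    d <- simulationDesign("two_condition", nGenes = 800, nSamples = 6,
                          nGroundTruth = 40, nKnowledge = 20, snrDb = 8)
    sim <- simulateTwoCondition(d, seed = 5)
    tr <- sim$truth
    expect_length(truthGenes(tr), 40)
    expect_length(knowledgeGenes(tr), 20)
    expect_length(intersect(truthGenes(tr), knowledgeGenes(tr)), 0)

    A1 <- tr@aTrue; A2 <- tr@aTrue2
    diffRows <- which(rowSums(A1 != A2) > 0)
    expect_setequal(rownames(sim$x1)[diffRows], truthGenes(tr))
    # differences confined to column 1; columns 2..L identical realizations
    expect_identical(A1[, -1], A2[, -1])
    expect_true(all(A2[diffRows, 1] == 0))
    expect_true(all(A1[diffRows, 1] != 0))
    # knowledge genes drawn from the remaining process-1 support
    kIdx <- match(knowledgeGenes(tr), rownames(sim$x1))
    expect_true(all(A1[kIdx, 1] != 0))

    expect_lt(max(abs(realizedSnr(tr) - 8)), 0.2)
    expect_equal(sim$labels, rep(c("cond1", "cond2"), each = 6))

    # too-small process support errors
    dBad <- simulationDesign("two_condition", nGenes = 100, nSamples = 4,
                             nGroundTruth = 40, nKnowledge = 20)
    expect_error(simulateTwoCondition(dBad, seed = 1), "support")
})

test_that("detection accuracy counts ground-truth genes in the top-|truth| positions", {
    expect_equal(detectionAccuracy(c("a", "b", "c", "d"), c("a", "b")), 1)
    expect_equal(detectionAccuracy(c("a", "b", "c", "d"), c("a", "c")), 0.5)
    expect_error(detectionAccuracy(c("a", "b"), c("a", "zzz")), "absent")
    # invariant to reordering below the cutoff
    expect_equal(detectionAccuracy(c("a", "c", "d", "b"), c("a", "c")),
                 detectionAccuracy(c("a", "c", "b", "d"), c("a", "c")))
})

test_that("random rankings score at the hypergeometric expectation", {
    set.seed(202)
    ids <- sprintf("g%04d", 1:5000)
    truth <- ids[1:200]
    acc <- vapply(1:300, function(i) {
        detectionAccuracy(sample(ids), truth)
    }, numeric(1))
    se <- sd(acc) / sqrt(length(acc))
    expect_lt(abs(mean(acc) - 200 / 5000), 3 * se + 1e-12)
})

test_that("snrSweep emits one row per method/SNR/rep and is seed-deterministic", {
    d <- simulationDesign("one_condition", nGenes = 200, nSamples = 6,
                          nGroundTruth = 20, nKnowledge = 6)
    tab <- snrSweep(d, c("vr", "pca"), snrGrid = c(10, 0, -10), reps = 3,
                    seed = 31)
    expect_equal(nrow(tab), 18)
    expect_setequal(unique(tab$method), c("vr", "pca"))
    tab2 <- snrSweep(d, c("vr", "pca"), snrGrid = c(10, 0, -10), reps = 3,
                     seed = 31)
    expect_identical(tab, tab2)
    means <- attr(tab, "means")
    expect_equal(nrow(means), 6)
    expect_true(all(means$mean >= 0 & means$mean <= 1))
})

test_that("at deeply noise-dominated SNR every method converges to random guessing", {
    d <- simulationDesign("one_condition", nGenes = 500, nSamples = 8,
                          nGroundTruth = 50, nKnowledge = 15)
    tab <- snrSweep(d, c("coca", "vr"), snrGrid = c(-25), reps = 8, seed = 61,
                    nBoot = 5, control = spsaControl(maxIter = 80, restarts = 2))
    means <- attr(tab, "means")
    guess <- 50 / 500
    for (m in c("coca", "vr")) {
        row <- means[means$method == m, ]
        expect_lt(abs(row$mean - guess), 3 * row$se)
    }
})
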