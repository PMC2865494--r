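test_that("bootstrap masks resample the background with replacement, never the knowledge", {
    ids <- paste0("g", 1:10)
    kn <- c("g1", "g2", "g3")
    pool <- paste0("g", 5:10)
    m <- makeBootstrapMask(ids, kn, pool, seed = 1)
    expect_equal(sum(positiveWeights(m)), 3)           # full knowledge set
    expect_equal(sum(negativeWeights(m)), 3)           # |draws| = |knowledge|
    expect_true(all(names(which(negativeWeights(m) > 0)) %in% pool))

    # single-gene pool: all draws collapse onto it with multiplicity
    m1 <- makeBootstrapMask(ids, kn, "g9", size = 3, seed = 2)
    expect_equal(unname(negativeWeights(m1)["g9"]), 3)

    # determinism
    expect_identical(makeBootstrapMask(ids, kn, pool, seed = 7),
                     makeBootstrapMask(ids, kn, pool, seed = 7))

    expect_error(makeBootstrapMask(ids, kn, character(0)), "empty")
    expect_error(makeBootstrapMask(ids, kn, c("g1", "g9")), "disjoint")
})

test_that("weighted negative mask equals explicit row duplication in the objective", {
    set.seed(5)
    x <- randomExpr(8, 4)
    w <- rnorm(4)
    pos <- c("g001", "g002")
    # weight gene g005 three times vs duplicating its row three times
    neg <- setNames(numeric(8), rownames(x))
    neg[c("g005", "g007")] <- c(3, 1)
    m <- knowledgeMask(rownames(x), as.numeric(rownames(x) %in% pos),
                       unname(neg))
    jw <- cocaObjective(x, m, w)
    oracle <- bruteObjective(x, 1:2, c(5, 5, 5, 7), w)
    expect_equal(jw, oracle, tolerance = 1e-9)
})

test_that("ambiguity correction aligns knowledge participation and is idempotent", {
    x <- matrix(c(-1, -2, -3, -4, 1, 1, 1, 1), 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), NULL))
    w <- c(1, 0, 0, 0)
    # knowledge g1 has participation -1 -> flip
    expect_equal(correctAmbiguity(w, x, "g1"), -w)
    # knowledge g2 has participation +1 -> unchanged
    expect_equal(correctAmbiguity(w, x, "g2"), w)
    # idempotence
    w1 <- correctAmbiguity(w, x, "g1")
    expect_equal(correctAmbiguity(w1, x, "g1"), w1)
    # exactly-zero mean keeps sign with a warning
    x0 <- matrix(c(1, -1, 0, 0, 2, 2, 2, 2), 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), NULL))
    expect_warning(out <- correctAmbiguity(c(1, 1, 0, 0), x0, "g1"), "zero")
    expect_equal(out, c(1, 1, 0, 0))
})

test_that("single-replicate bagging returns the replicate itself; bagged mean is exact", {
    set.seed(31)
    x <- randomExpr(40, 6)
    kn <- rownames(x)[1:5]
    ctrl <- spsaControl(maxIter = 60, restarts = 2)
    r1 <- runCOCA(x, kn, plan = bootstrapPlan(nBoot = 1), control = ctrl, seed = 4)
    expect_equal(unname(baggedParticipation(r1)),
                 unname(replicateParticipation(r1)[1, ]))

    r5 <- runCOCA(x, kn, plan = bootstrapPlan(nBoot = 5), control = ctrl, seed = 4)
    expect_equal(baggedParticipation(r5),
                 colMeans(replicateParticipation(r5)))
    # knowledge-gene mean participation is non-negative in every replicate
    km <- rowMeans(replicateParticipation(r5)[, kn, drop = FALSE])
    expect_true(all(km >= 0))
    # ranking is a permutation sorted by |bagged| with id tie-break
    expect_setequal(geneRanking(r5), rownames(x))
    expect_false(is.unsorted(rev(abs(baggedParticipation(r5)[geneRanking(r5)]))))
})

test_that("bagged COCA recovers the full signal set on the noiseless rank-1 fixture", {
    fx <- rank1Fixture(nPos = 20, nNull = 80, M = 8, seed = 13)
    res <- runCOCA(fx$x, sample(fx$signal, 5),
                   plan = bootstrapPlan(nBoot = 20),
                   control = spsaControl(maxIter = 150, restarts = 2),
                   seed = 17)
    top <- geneRanking(res)[1:20]
    expect_setequal(top, fx$signal)
})

test_that("bagging results are reproducible and independent of gene order", {
    set.seed(55)
    x <- randomExpr(60, 6)
    kn <- rownames(x)[c(3, 10, 20)]
    ctrl <- spsaControl(maxIter = 60, restarts = 2)
    plan <- bootstrapPlan(nBoot = 4)
    r1 <- runCOCA(x, kn, plan = plan, control = ctrl, seed = 9)
    r2 <- runCOCA(x, kn, plan = plan, control = ctrl, seed = 9)
    expect_identical(baggedParticipation(r1), baggedParticipation(r2))

    perm <- sample(nrow(x))
    r3 <- runCOCA(x[perm, ], kn, plan = plan, control = ctrl, seed = 9)
    expect_equal(baggedParticipation(r3)[rownames(x)],
                 baggedParticipation(r1))
    expect_identical(geneRanking(r3), geneRanking(r1))
})

test_that("unmatched knowledge ids are reported; too few matches error", {
    set.seed(2)
    x <- randomExpr(20, 5)
    expect_message(
        res <- runCOCA(x, c("g001", "g002", "g003", "nope1"),
                       plan = bootstrapPlan(nBoot = 1),
                       control = spsaControl(maxIter = 30, restarts = 1),
                       seed = 1),
        "nope1")
    expect_s4_class(res, "ParticipationResult")
    expect_error(runCOCA(x, c("g001", "zzz1", "zzz2"),
                         plan = bootstrapPlan(nBoot = 1)),
                 "fewer than 2")
})

test_that("across-run variability of bagged participation shrinks as B grows", {
    sim <- simulateOneCondition(
        simulationDesign("one_condition", nGenes = 250, nGroundTruth = 30,
                         nKnowledge = 10, snrDb = 5), seed = 44)
    ctrl <- spsaControl(maxIter = 80, restarts = 2)
    sdForB <- function(B) {
        runs <- vapply(1:8, function(r) {
            baggedParticipation(runCOCA(sim$x, knowledgeGenes(sim$truth),
                plan = bootstrapPlan(nBoot = B), control = ctrl,
                seed = 1000 + r))
        }, numeric(nrow(sim$x)))
        mean(apply(runs, 1, sd))
    }
    s5 <- sdForB(5); s20 <- sdForB(20)
    expect_lt(s20, s5)
})
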