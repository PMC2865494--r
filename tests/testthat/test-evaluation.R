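test_that("ROC curve matches hand enumeration, with ties grouped", {
    # ranks P, N, P, N by descending score
    sc <- c(p1 = 4, n1 = 3, p2 = 2, n2 = 1)
    roc <- rocCurve(sc, c("p1", "p2"))
    expect_equal(roc$fpr, c(0, 0, 0.5, 0.5, 1))
    expect_equal(roc$tpr, c(0, 0.5, 0.5, 1, 1))

    # all positives first -> passes through (0, 1)
    sc2 <- c(p1 = 5, p2 = 4, n1 = 1, n2 = 0.5)
    roc2 <- rocCurve(sc2, c("p1", "p2"))
    expect_true(any(roc2$fpr == 0 & roc2$tpr == 1))

    # all scores equal -> single diagonal step
    sc3 <- c(p = 1, n1 = 1, n2 = 1)
    roc3 <- rocCurve(sc3, "p")
    expect_equal(roc3$fpr, c(0, 1))
    expect_equal(roc3$tpr, c(0, 1))

    expect_error(rocCurve(sc, names(sc)), "at least one")
    expect_error(rocCurve(sc, character(0)), "at least one")
})

test_that("ROC curves are monotone nondecreasing in both coordinates", {
    set.seed(91)
    for (i in 1:10) {
        sc <- setNames(sample(1:6, 40, replace = TRUE), paste0("g", 1:40))
        pos <- sample(names(sc), 12)
        roc <- rocCurve(sc, pos)
        expect_false(is.unsorted(roc$fpr))
        expect_false(is.unsorted(roc$tpr))
    }
})

test_that("trapezoidal AUC equals brute-force Mann-Whitney, including ties", {
    expect_equal(rankingAUC(c(p1 = 4, n1 = 3, p2 = 2, n2 = 1), c("p1", "p2")),
                 0.75)
    # perfect separation and all-tied edge cases
    expect_equal(rankingAUC(c(p = 2, q = 2, n = 1), c("p", "q")), 1)
    expect_equal(rankingAUC(c(p = 1, n1 = 1, n2 = 1), "p"), 0.5)

    set.seed(303)
    for (i in 1:50) {
        n <- sample(10:200, 1)
        sc <- setNames(sample(1:8, n, replace = TRUE) +
                           ifelse(runif(n) < 0.5, 0, 0.5),
                       paste0("g", seq_len(n)))
        pos <- sample(names(sc), sample(2:(n - 2), 1))
        expect_equal(rankingAUC(sc, pos),
                     bruteAUC(sc, names(sc) %in% pos),
                     tolerance = 1e-12)
    }
})

test_that("AUC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(17)
    sc <- setNames(rnorm(100), paste0("g", 1:100))
    pos <- paste0("g", 1:30)
    ref <- as.numeric(pROC::auc(pROC::roc(
        response = names(sc) %in% pos, predictor = sc, quiet = TRUE,
        direction = "<")))
    expect_equal(rankingAUC(sc, pos), ref, tolerance = 1e-10)
})

test_that("evaluateRanking can exclude guidance genes from scoring", {
    sc <- c(k1 = 9, k2 = 8, a = 3, b = 2, c = 1)
    ev <- evaluateRanking(sc, positives = c("k1", "k2", "a"),
                          exclude = c("k1", "k2"))
    expect_equal(ev$auc, 1)  # only 'a' remains positive and tops b, c
})

test_that("expression matrices round-trip through TSV and match their GCT twin", {
    x <- randomExpr(12, 5, seed = 8)
    tsv <- tempfile(fileext = ".txt")
    writeExpression(x, tsv)
    expect_equal(readExpression(tsv), x)

    # equivalent GCT 1.2 with a Description column
    gct <- tempfile(fileext = ".gct")
    lines <- c("#1.2", paste(nrow(x), ncol(x), sep = "\t"),
               paste(c("Name", "Description", colnames(x)), collapse = "\t"),
               vapply(seq_len(nrow(x)), function(i) {
                   paste(c(rownames(x)[i], "na", sprintf("%.17g", x[i, ])),
                         collapse = "\t")
               }, character(1)))
    writeLines(lines, gct)
    expect_equal(readExpression(gct), x)

    # duplicate ids rejected
    bad <- tempfile(fileext = ".txt")
    x2 <- x; rownames(x2)[2] <- rownames(x2)[1]
    writeLines(c(paste(c("id", colnames(x2)), collapse = "\t"),
                 vapply(seq_len(nrow(x2)), function(i) {
                     paste(c(rownames(x2)[i], x2[i, ]), collapse = "\t")
                 }, character(1))), bad)
    expect_error(readExpression(bad), "duplicate")
})

test_that("gene sets parse from plain lists and GMT records", {
    plain <- tempfile(fileext = ".txt")
    writeLines(c("g1", "g2", "", "# comment", "g3"), plain)
    expect_equal(readGeneSet(plain), c("g1", "g2", "g3"))

    gmt <- tempfile(fileext = ".gmt")
    writeLines(c("set1\tdesc\tg1\tg2", "set2\tdesc\tg3\tg4\tg5"), gmt)
    sets <- readGeneSet(gmt)
    expect_named(sets, c("set1", "set2"))
    expect_equal(sets$set1, c("g1", "g2"))
    expect_equal(readGeneSet(gmt, set = "set2"), c("g3", "g4", "g5"))
})

test_that("ranking tables round-trip at full precision", {
    set.seed(23)
    x <- randomExpr(15, 4)
    r <- varianceRank(x)
    path <- tempfile(fileext = ".tsv")
    writeRanking(r, path)
    back <- readRanking(path)
    expect_equal(back$gene, r$gene)
    expect_identical(back$score, r$score)     # exact, not approximate
    expect_identical(back$abs_score, r$abs_score)
})

test_that("run manifests record seed and version as JSON", {
    path <- tempfile(fileext = ".json")
    writeManifest(path, list(seed = 42L, n_boot = 100L))
    man <- jsonlite::read_json(path)
    expect_equal(man$seed, 42L)
    expect_equal(man$package, "cocaRank")
})
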