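# Reference ranking methods used as comparators in the benchmarks.

# Validate a two-condition label vector; returns list of index vectors.
.checkLabels <- function(labels, M) {
    labels <- as.character(labels)
    if (length(labels) != M) {
        stop("labels must have one entry per sample")
    }
    lev <- unique(labels)
    if (length(lev) != 2L) {
        stop("exactly two conditions required, got ", length(lev))
    }
    idx <- list(which(labels == lev[1L]), which(labels == lev[2L]))
    if (any(lengths(idx) < 2L)) {
        stop("each condition needs at least 2 samples")
    }
    names(idx) <- lev
    idx
}

#' Variance ranking
#'
#' Unsupervised baseline: genes ordered by their unbiased sample variance
#' (denominator M - 1), descending, ties by gene id.
#'
#' @param x genes x samples expression matrix.
#' @return Ranking data.frame (`rank`, `gene`, `score`, `abs_score`, `method`).
#' @examples
#' x <- matrix(c(0, 2, 0, 1), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), NULL))
#' varianceRank(x)  # variances 2 and 0.5
#' @export
varianceRank <- function(x) {
    x <- .asExpressionMatrix(x)
    .rankTable(.rowVars(x), rownames(x), "vr")
}

#' Fold-change ranking
#'
#' Two-condition baseline: genes ordered by the absolute difference of
#' condition means (a log-ratio when the matrix holds log-scale values).
#'
#' @param x genes x samples expression matrix.
#' @param labels two-level condition labels, one per sample.
#' @return Ranking data.frame; `score` is the signed mean difference
#'   (condition 2 minus condition 1).
#' @export
foldChangeRank <- function(x, labels) {
    x <- .asExpressionMatrix(x)
    idx <- .checkLabels(labels, ncol(x))
    d <- rowMeans(x[, idx[[2L]], drop = FALSE]) -
        rowMeans(x[, idx[[1L]], drop = FALSE])
    .rankTable(d, rownames(x), "fc")
}

#' SAM-style moderated t ranking
#'
#' Two-condition baseline: the relative difference
#' `d_j = (mean2 - mean1) / (s_j + s0)` with `s_j` the pooled standard error
#' of the mean difference and the regularizer `s0` the median of the `s_j`
#' over genes (a simplification of the original percentile search). Genes
#' are ranked by `|d_j|` descending.
#'
#' @inheritParams foldChangeRank
#' @param s0 regularizer added to every `s_j`; default NULL computes the
#'   median over genes. `s0 = 0` recovers the ordinary two-sample t ordering.
#' @return Ranking data.frame; `score` is the signed statistic.
#' @export
samRank <- function(x, labels, s0 = NULL) {
    x <- .asExpressionMatrix(x)
    idx <- .checkLabels(labels, ncol(x))
    n1 <- length(idx[[1L]]); n2 <- length(idx[[2L]])
    x1 <- x[, idx[[1L]], drop = FALSE]
    x2 <- x[, idx[[2L]], drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    sj <- sqrt(sp2 * (1 / n1 + 1 / n2))
    if (is.null(s0)) {
        s0 <- stats::median(sj)
    }
    if (all(sj + s0 == 0)) {
        stop("all genes have zero variance and s0 = 0; statistic undefined")
    }
    d <- (m2 - m1) / (sj + s0)
    d[sj + s0 == 0] <- 0
    .rankTable(d, rownames(x), "sam")
}

#' PCA-guided correlation ranking
#'
#' Supervised baseline: the first principal component (first right-singular
#' direction of the row-centered knowledge-gene submatrix) provides a sample
#' profile; all genes are ranked by the absolute Pearson correlation of their
#' expression profile with it. The component sign is fixed so its inner
#' product with the mean knowledge profile is non-negative (the ranking is
#' sign-invariant anyway).
#'
#' @param x genes x samples expression matrix.
#' @param knowledge character vector of knowledge gene ids (>= 2 must match).
#' @return Ranking data.frame; `score` is the signed correlation. Genes with
#'   zero profile variance get score 0 (ranked last).
#' @export
pcaGuidedRank <- function(x, knowledge) {
    x <- .asExpressionMatrix(x)
    knowledge <- intersect(as.character(knowledge), rownames(x))
    if (length(knowledge) < 2L) {
        stop("at least 2 knowledge genes must match the expression matrix")
    }
    K <- x[knowledge, , drop = FALSE]
    Kc <- K - rowMeans(K)
    if (all(Kc == 0)) {
        stop("knowledge submatrix has rank 0 after centering")
    }
    comp <- svd(Kc, nu = 0L, nv = 1L)$v[, 1L]
    if (sum(comp * colMeans(Kc)) < 0) {
        comp <- -comp
    }
    xc <- x - rowMeans(x)
    cc <- comp - mean(comp)
    num <- drop(xc %*% cc)
    den <- sqrt(rowSums(xc^2) * sum(cc^2))
    r <- ifelse(den > 0, num / den, 0)
    .rankTable(r, rownames(x), "pca")
}
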