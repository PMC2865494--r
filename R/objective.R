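#' Participation of every gene along a direction
#'
#' Linear filtering of the expression matrix: the participation vector is
#' `A = X w`, one value per gene, measuring how strongly the gene's profile
#' projects onto the coordinative direction `w`.
#'
#' @param x genes x samples expression matrix (matrix, data.frame or
#'   SummarizedExperiment with gene rownames).
#' @param w numeric vector of length `ncol(x)`, or a
#'   [CoordinativeDirection-class].
#' @return Named numeric vector of length `nrow(x)`.
#' @examples
#' x <- matrix(1:4, 2, byrow = TRUE, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' participation(x, c(1, 1) / sqrt(2))
#' @export
participation <- function(x, w) {
    x <- .asExpressionMatrix(x)
    if (methods::is(w, "CoordinativeDirection")) {
        w <- direction(w)
    }
    w <- as.numeric(w)
    if (length(w) != ncol(x)) {
        stop("direction length ", length(w),
             " does not match sample count ", ncol(x))
    }
    drop(x %*% w)
}

# Denominator guard: a vanishing background sum would make the ratio blow up
# for degenerate w. Scaled to the weighted mean background amplitude, floored
# so exactly-zero background rows stay finite.
.epsGuard <- function(meanNeg) {
    max(1e-12 * meanNeg, 1e-300)
}

# Fast objective closure over fixed positive/negative row blocks.
# Xp, Xn: submatrices; wp, wn: per-row weights (bootstrap multiplicities).
.makeObjective <- function(Xp, wp, Xn, wn, p = 1) {
    swn <- sum(wn)
    if (p == 1) {
        function(w) {
            num <- sum(wp * abs(Xp %*% w))
            den <- sum(wn * abs(Xn %*% w))
            num / (den + .epsGuard(den / swn))
        }
    } else {
        function(w) {
            num <- sqrt(sum(wp * (Xp %*% w)^2))
            an <- abs(Xn %*% w)
            den <- sqrt(sum(wn * an^2))
            num / (den + .epsGuard(sum(wn * an) / swn))
        }
    }
}

#' Masked coordination ratio objective
#'
#' The COCA cost: the p-norm of knowledge-gene participations divided by the
#' p-norm of background-gene participations (plus a tiny guard), for a
#' candidate direction `w`. Maximizing it over unit `w` finds the direction
#' along which knowledge genes are maximally coordinated relative to
#' background genes. The ratio is invariant to rescaling `w`.
#'
#' @param x genes x samples expression matrix.
#' @param mask a [KnowledgeMask-class] over the genes of `x` (matched by id).
#' @param w numeric direction of length `ncol(x)`; must be nonzero.
#' @param p norm order, 1 (default; robust to outliers) or 2.
#' @return A single non-negative number.
#' @examples
#' x <- matrix(c(1, 0, 0, 1, 1, 1, 2, 0), 4, 2, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:4), c("s1", "s2")))
#' m <- knowledgeMask(rownames(x), c("g1", "g2"), c("g3", "g4"))
#' cocaObjective(x, m, c(1, 0))  # (1+0)/(1+2) = 1/3
#' @export
cocaObjective <- function(x, mask, w, p = 1) {
    x <- .asExpressionMatrix(x)
    stopifnot(methods::is(mask, "KnowledgeMask"))
    methods::validObject(mask)
    if (!p %in% c(1, 2)) {
        stop("p must be 1 or 2")
    }
    w <- as.numeric(w)
    if (length(w) != ncol(x)) {
        stop("direction length ", length(w),
             " does not match sample count ", ncol(x))
    }
    if (all(w == 0)) {
        stop("direction w must be nonzero")
    }
    wts <- .maskWeights(mask, rownames(x))
    ip <- which(wts$positive > 0)
    ineg <- which(wts$negative > 0)
    f <- .makeObjective(x[ip, , drop = FALSE], wts$positive[ip],
                        x[ineg, , drop = FALSE], wts$negative[ineg], p = p)
    f(w)
}

# Align mask weights to the row order of an expression matrix.
.maskWeights <- function(mask, geneIds) {
    idx <- match(geneIds, mask@geneIds)
    if (anyNA(idx)) {
        stop("mask does not cover genes: ",
             paste(utils::head(geneIds[is.na(idx)], 10L), collapse = ", "))
    }
    list(positive = mask@positive[idx], negative = mask@negative[idx])
}
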