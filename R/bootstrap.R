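#' Bootstrap knowledge mask
#'
#' Builds the per-replicate mask used by bagged COCA: the positive side is
#' the full knowledge set (never resampled); the negative side is `size`
#' background genes drawn with replacement from `pool`, duplicates collapsing
#' to membership with their draw multiplicity recorded as integer weights in
#' the objective's background sum.
#'
#' @param geneIds the gene universe (rownames of the expression matrix).
#' @param knowledge character vector of knowledge gene ids.
#' @param pool character vector of background gene ids to draw from.
#' @param size number of background draws (default: `length(knowledge)`, the
#'   balanced comparison that motivates the bootstrap).
#' @param seed optional integer seed.
#' @return A [KnowledgeMask-class] with weighted negative side.
#' @examples
#' ids <- paste0("g", 1:10)
#' makeBootstrapMask(ids, c("g1", "g2"), paste0("g", 5:10), seed = 1)
#' @export
makeBootstrapMask <- function(geneIds, knowledge, pool,
                              size = length(knowledge), seed = NULL) {
    geneIds <- as.character(geneIds)
    if (length(pool) == 0L) {
        stop("background pool is empty")
    }
    if (length(intersect(pool, knowledge))) {
        stop("background pool must be disjoint from the knowledge set")
    }
    pool <- sort(unique(as.character(pool)))  # order-independent sampling
    draws <- .withSeed(seed, function() {
        sample(pool, size, replace = TRUE)
    })
    counts <- table(draws)
    neg <- numeric(length(geneIds))
    names(neg) <- geneIds
    neg[names(counts)] <- as.numeric(counts)
    knowledgeMask(geneIds, positive = as.character(knowledge),
                  negative = unname(neg))
}

#' Resolve the sign ambiguity of a linear component
#'
#' A coordinative direction is defined only up to sign. Before replicate
#' directions can be averaged they must be oriented consistently: the
#' direction is flipped if the mean participation of the knowledge genes is
#' negative, so that after correction knowledge genes participate positively
#' on average. The rule is deterministic and idempotent. An exactly-zero
#' knowledge mean leaves the sign untouched with a warning.
#'
#' @param w numeric direction or [CoordinativeDirection-class].
#' @param x genes x samples expression matrix (same sample order as `w`).
#' @param knowledge character vector of knowledge gene ids present in `x`.
#' @return `w`, possibly negated, same type as the input.
#' @examples
#' x <- matrix(c(-1, -2, 3, 4), 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), NULL))
#' correctAmbiguity(c(1, 0), x, "g1")  # flipped: knowledge mean is -1
#' @export
correctAmbiguity <- function(w, x, knowledge) {
    x <- .asExpressionMatrix(x)
    isDir <- methods::is(w, "CoordinativeDirection")
    wv <- if (isDir) direction(w) else as.numeric(w)
    if (all(wv == 0)) {
        stop("direction w must be nonzero")
    }
    knowledge <- intersect(as.character(knowledge), rownames(x))
    if (!length(knowledge)) {
        stop("no knowledge genes found in the expression matrix")
    }
    m <- mean(x[knowledge, , drop = FALSE] %*% wv)
    if (m == 0) {
        warning("knowledge-gene mean participation is exactly zero; ",
                "keeping the current sign")
    } else if (m < 0) {
        wv <- -wv
    }
    if (isDir) {
        w@w <- wv
        w
    } else {
        wv
    }
}

#' Bagged coordinative component analysis
#'
#' The full knowledge-guided ranking pipeline. For each of B bootstrap
#' replicates, background genes are resampled with replacement from the pool
#' ([makeBootstrapMask()]), the coordinative direction is fitted on the
#' knowledge + sampled-background submatrix ([optimizeDirection()]), its sign
#' is resolved ([correctAmbiguity()]), and participation values are computed
#' for ALL genes by projecting the full matrix. Replicates are averaged
#' (bagging) and genes ranked by absolute bagged participation, ties broken
#' by gene id.
#'
#' With `conditions` given (two-level labels over samples), the direction is
#' learned on the full (concatenated) sample set but each replicate scores
#' genes by the differential participation `X1 w1 - X2 w2` between the two
#' condition blocks, which targets changes at the latent-process level rather
#' than overall process membership.
#'
#' @param x genes x samples expression matrix.
#' @param knowledge character vector of knowledge gene ids; unmatched ids are
#'   reported and dropped (error if fewer than 2 match).
#' @param plan a [BootstrapPlan-class]; see [bootstrapPlan()].
#' @param control an [SpsaControl-class] for the per-replicate optimizer.
#' @param conditions optional two-level factor/character of length `ncol(x)`.
#' @param p norm order of the objective.
#' @param center row-center gene profiles first (default TRUE).
#' @param aggregate bagging aggregator, `"mean"` (default) or `"median"`.
#' @param seed master seed; replicate b runs on a deterministic substream so
#'   results are reproducible and order-independent.
#' @return A [ParticipationResult-class].
#' @examples
#' set.seed(42)
#' x <- matrix(rnorm(400), 50, 8, dimnames = list(sprintf("g%02d", 1:50), NULL))
#' res <- runCOCA(x, c("g01", "g02", "g03"),
#'                plan = bootstrapPlan(nBoot = 3),
#'                control = spsaControl(maxIter = 50, restarts = 2), seed = 1)
#' head(rankingTable(res))
#' @export
runCOCA <- function(x, knowledge, plan = bootstrapPlan(),
                    control = spsaControl(), conditions = NULL, p = 1,
                    center = TRUE, aggregate = c("mean", "median"),
                    seed = NULL) {
    x <- .asExpressionMatrix(x)
    aggregate <- match.arg(aggregate)
    methods::validObject(plan)
    methods::validObject(control)
    genes <- rownames(x)

    knowledge <- as.character(knowledge)
    unmatched <- setdiff(knowledge, genes)
    if (length(unmatched)) {
        message("dropping ", length(unmatched), " unmatched knowledge ids: ",
                paste(utils::head(unmatched, 10L), collapse = ", "))
    }
    knowledge <- intersect(knowledge, genes)
    if (length(knowledge) < 2L) {
        stop("fewer than 2 knowledge genes matched the expression matrix; ",
             "unmatched ids: ", paste(utils::head(unmatched, 20L), collapse = ", "))
    }

    pool <- plan@pool
    if (!length(pool)) {
        pool <- setdiff(genes, knowledge)
    } else {
        pool <- setdiff(intersect(pool, genes), knowledge)
    }
    if (!length(pool)) {
        stop("background pool is empty after matching")
    }
    size <- plan@backgroundSize
    if (is.na(size)) {
        size <- length(knowledge)
    }

    condIdx <- NULL
    if (!is.null(conditions)) {
        conditions <- as.character(conditions)
        if (length(conditions) != ncol(x)) {
            stop("conditions must have one label per sample")
        }
        lev <- unique(conditions)
        if (length(lev) != 2L) {
            stop("conditions must have exactly two levels, got ",
                 length(lev))
        }
        condIdx <- list(which(conditions == lev[1L]),
                        which(conditions == lev[2L]))
    }

    if (center) {
        x <- .preprocess(x, center = TRUE)
    }

    B <- plan@nBoot
    N <- nrow(x); M <- ncol(x)
    aRep <- matrix(NA_real_, B, N, dimnames = list(NULL, genes))
    wRep <- matrix(NA_real_, B, M, dimnames = list(NULL, colnames(x)))
    for (b in seq_len(B)) {
        sb <- .deriveSeed(seed, b)
        mask <- makeBootstrapMask(genes, knowledge, pool, size = size,
                                  seed = sb)
        rows <- genes[mask@positive > 0 | mask@negative > 0]
        sub <- x[rows, , drop = FALSE]
        subMask <- knowledgeMask(rows,
            positive = mask@positive[match(rows, genes)],
            negative = mask@negative[match(rows, genes)])
        d <- optimizeDirection(sub, subMask, control = control, p = p,
                               seed = .deriveSeed(sb, 104729L),
                               center = FALSE)
        wb <- correctAmbiguity(direction(d), x, knowledge)
        wRep[b, ] <- wb
        aRep[b, ] <- if (is.null(condIdx)) {
            drop(x %*% wb)
        } else {
            drop(x[, condIdx[[1L]], drop = FALSE] %*% wb[condIdx[[1L]]]) -
                drop(x[, condIdx[[2L]], drop = FALSE] %*% wb[condIdx[[2L]]])
        }
    }

    aBag <- if (aggregate == "mean") {
        colMeans(aRep)
    } else {
        apply(aRep, 2L, stats::median)
    }
    aSd <- if (B > 1L) apply(aRep, 2L, stats::sd) else rep(NA_real_, N)
    names(aSd) <- genes
    ranking <- genes[order(-abs(aBag), genes)]

    methods::new("ParticipationResult",
        aBagged = aBag, aSd = aSd, aReplicates = aRep, wReplicates = wRep,
        ranking = ranking, knowledge = knowledge,
        conditions = if (is.null(conditions)) character(0) else conditions,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
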