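# Internal helpers: RNG plumbing and input coercion.

# Run `fun()` under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, fun) {
    if (is.null(seed) || is.na(seed)) {
        return(fun())
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    }, add = TRUE)
    set.seed(as.integer(seed))
    fun()
}

# Deterministic substream seed for replicate/restart k of a master seed.
# A Lehmer-style mix keeps the result a valid 32-bit seed; doubles are exact
# well past the magnitudes involved.
.deriveSeed <- function(master, k) {
    if (is.null(master) || is.na(master)) {
        return(NULL)
    }
    m <- abs(as.numeric(master)) %% 2147483647
    as.integer(((m * 48271 + as.numeric(k) * 16807) %% 2147483629) + 1)
}

# Coerce expression input (matrix, data.frame, or SummarizedExperiment) to a
# dense numeric matrix with unique gene rownames and sample colnames.
.asExpressionMatrix <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE)) {
            stop("the SummarizedExperiment package is required for this input type")
        }
        x <- SummarizedExperiment::assay(x, 1L)
    }
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) < 2L || ncol(x) < 2L) {
        stop("expression matrix must have at least 2 genes and 2 samples (got ",
             nrow(x), " x ", ncol(x), ")")
    }
    if (is.null(rownames(x))) {
        stop("expression matrix must carry gene identifiers as rownames")
    }
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    if (length(dup)) {
        stop("duplicate gene identifiers: ", paste(utils::head(dup, 10L), collapse = ", "))
    }
    if (is.null(colnames(x))) {
        colnames(x) <- paste0("sample_", seq_len(ncol(x)))
    }
    if (anyNA(x) || any(!is.finite(x))) {
        stop("expression matrix contains missing or non-finite values")
    }
    x
}

# Row-center (and optionally unit-variance scale) each gene profile.
.preprocess <- function(x, center = TRUE, scale. = FALSE) {
    if (center) {
        x <- x - rowMeans(x)
    }
    if (scale.) {
        s <- sqrt(.rowVars(x))
        s[s == 0] <- 1
        x <- x / s
    }
    x
}

# Unbiased per-row variance (denominator M - 1).
.rowVars <- function(x) {
    m <- rowMeans(x)
    rowSums((x - m)^2) / (ncol(x) - 1L)
}

# Standard descending-score ranking table with deterministic ties
# (|score| descending, then gene id ascending).
.rankTable <- function(score, genes, method) {
    ord <- order(-abs(score), genes)
    data.frame(
        rank = seq_along(genes),
        gene = genes[ord],
        score = unname(score[ord]),
        abs_score = abs(unname(score[ord])),
        method = method,
        stringsAsFactors = FALSE
    )
}

# Accept a ranking as character vector, ranking table, or ParticipationResult.
.asRankedGenes <- function(ranking) {
    if (methods::is(ranking, "ParticipationResult")) {
        return(geneRanking(ranking))
    }
    if (is.data.frame(ranking)) {
        if (!"gene" %in% names(ranking)) {
            stop("ranking data.frame must have a 'gene' column")
        }
        if ("rank" %in% names(ranking)) {
            return(as.character(ranking$gene[order(ranking$rank)]))
        }
        return(as.character(ranking$gene))
    }
    as.character(ranking)
}
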