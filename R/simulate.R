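# Linear latent-model simulators with controlled SNR, plus the accuracy
# metric and the SNR-sweep benchmark driver.

# Block-sparse participation matrix: process l regulates a contiguous block
# of ~N/L genes plus a configurable overlap into the next process's block
# (cyclic); nonzero loadings ~ Normal(0, 1).
.drawLoadings <- function(N, L, overlap) {
    A <- matrix(0, N, L)
    s <- N %/% L
    ov <- round(overlap * s)
    for (l in seq_len(L)) {
        from <- (l - 1L) * s + 1L
        to <- if (l == L) N else l * s
        block <- from:to
        if (ov > 0L) {
            ext <- (to + 1L):(to + ov)
            ext <- ((ext - 1L) %% N) + 1L  # wrap into the first block
            block <- c(block, ext)
        }
        A[block, l] <- stats::rnorm(length(block))
    }
    A
}

# Additive Gaussian noise scaled so the realized variance ratio hits the
# requested SNR (dB) essentially exactly; returns list(x, snrRealized).
.addNoise <- function(S, snrDb) {
    if (is.infinite(snrDb)) {
        return(list(x = S, snrRealized = Inf))
    }
    varS <- stats::var(as.vector(S))
    if (varS == 0) {
        stop("signal has zero variance; cannot set an SNR")
    }
    targetVarN <- varS / 10^(snrDb / 10)
    E <- matrix(stats::rnorm(length(S)), nrow(S), ncol(S))
    E <- E * sqrt(targetVarN) / stats::sd(as.vector(E))
    list(x = S + E,
         snrRealized = 10 * log10(varS / stats::var(as.vector(E))))
}

.geneIds <- function(N) sprintf("g%0*d", nchar(N), seq_len(N))

#' Simulate a one-condition expression dataset
#'
#' Generates `X = A T + E` with block-sparse participation `A` (N x L),
#' latent activities `T` (L x M) with standard normal entries, and i.i.d.
#' Gaussian noise at the requested SNR. Ground-truth genes are the
#' `nGroundTruth` genes with largest absolute loading on process 1;
#' knowledge genes are drawn uniformly from the ground truth, so guidance is
#' a partial view of the target set.
#'
#' @param design a [SimulationDesign-class] with `design = "one_condition"`;
#'   see [simulationDesign()].
#' @param seed integer seed.
#' @return list with elements `x` (expression matrix, gene ids as rownames)
#'   and `truth` (a [SimulationTruth-class]).
#' @examples
#' sim <- simulateOneCondition(simulationDesign("one_condition",
#'     nGenes = 200, nGroundTruth = 20, nKnowledge = 5), seed = 1)
#' dim(sim$x); length(truthGenes(sim$truth))
#' @export
simulateOneCondition <- function(design = simulationDesign("one_condition"),
                                 seed = NULL) {
    methods::validObject(design)
    if (design@design != "one_condition") {
        stop("design must be a one_condition design")
    }
    .withSeed(seed, function() {
        N <- design@nGenes; M <- design@nSamples; L <- design@nProcesses
        A <- .drawLoadings(N, L, design@overlap)
        Tm <- matrix(stats::rnorm(L * M), L, M)
        noisy <- .addNoise(A %*% Tm, design@snrDb)
        x <- noisy$x
        ids <- .geneIds(N)
        rownames(x) <- ids
        colnames(x) <- paste0("s", seq_len(M))
        ord <- order(-abs(A[, 1L]), ids)
        truth <- ids[ord[seq_len(design@nGroundTruth)]]
        knowledge <- sample(truth, design@nKnowledge)
        list(x = x, truth = methods::new("SimulationTruth",
            aTrue = A, aTrue2 = matrix(0, 0, 0), tTrue = list(Tm),
            groundTruth = truth, knowledge = knowledge,
            snrDb = design@snrDb, snrRealized = noisy$snrRealized,
            design = "one_condition",
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
    })
}

#' Simulate a two-condition expression dataset
#'
#' Both conditions share the participation matrix except that
#' `nGroundTruth` randomly chosen nonzero entries of the process-1 column
#' are set to zero in condition 2 — those genes are the ground truth the
#' methods must detect. Knowledge genes are drawn from the remaining
#' process-1 support, never overlapping the ground truth. Latent activities
#' are drawn fresh per condition; noise is added per condition at the
#' requested SNR.
#'
#' @param design a [SimulationDesign-class] with `design = "two_condition"`;
#'   `nSamples` is the per-condition sample count.
#' @param seed integer seed.
#' @return list with elements `x1`, `x2` (per-condition matrices, shared
#'   gene ids), `labels` (condition labels for `cbind(x1, x2)`), and `truth`.
#' @examples
#' sim <- simulateTwoCondition(simulationDesign("two_condition",
#'     nGenes = 500, nGroundTruth = 20, nKnowledge = 10), seed = 1)
#' length(intersect(truthGenes(sim$truth), knowledgeGenes(sim$truth)))  # 0
#' @export
simulateTwoCondition <- function(design = simulationDesign("two_condition"),
                                 seed = NULL) {
    methods::validObject(design)
    if (design@design != "two_condition") {
        stop("design must be a two_condition design")
    }
    .withSeed(seed, function() {
        N <- design@nGenes; M <- design@nSamples; L <- design@nProcesses
        A1 <- .drawLoadings(N, L, design@overlap)
        support <- which(A1[, 1L] != 0)
        need <- design@nGroundTruth + design@nKnowledge
        if (length(support) < need) {
            stop("process-1 support (", length(support),
                 " genes) is smaller than ground truth + knowledge (", need, ")")
        }
        truthIdx <- sample(support, design@nGroundTruth)
        A2 <- A1
        A2[truthIdx, 1L] <- 0
        knowledgeIdx <- sample(setdiff(support, truthIdx), design@nKnowledge)

        T1 <- matrix(stats::rnorm(L * M), L, M)
        T2 <- matrix(stats::rnorm(L * M), L, M)
        n1 <- .addNoise(A1 %*% T1, design@snrDb)
        n2 <- .addNoise(A2 %*% T2, design@snrDb)
        ids <- .geneIds(N)
        x1 <- n1$x; x2 <- n2$x
        rownames(x1) <- rownames(x2) <- ids
        colnames(x1) <- paste0("c1_s", seq_len(M))
        colnames(x2) <- paste0("c2_s", seq_len(M))
        list(x1 = x1, x2 = x2,
             labels = rep(c("cond1", "cond2"), each = M),
             truth = methods::new("SimulationTruth",
                 aTrue = A1, aTrue2 = A2, tTrue = list(T1, T2),
                 groundTruth = ids[sort(truthIdx)],
                 knowledge = ids[sort(knowledgeIdx)],
                 snrDb = design@snrDb,
                 snrRealized = c(n1$snrRealized, n2$snrRealized),
                 design = "two_condition",
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
    })
}

#' Detection accuracy of a ranking
#'
#' Fraction of ground-truth genes found among the top `length(truth)`
#' positions of the ranking — the benchmark accuracy metric.
#'
#' @param ranking a ranking: character vector of gene ids in rank order, a
#'   ranking data.frame, or a [ParticipationResult-class].
#' @param truth character vector of ground-truth gene ids.
#' @return A number in \[0, 1\].
#' @examples
#' detectionAccuracy(c("a", "b", "c", "d"), c("a", "c"))  # 0.5
#' @export
detectionAccuracy <- function(ranking, truth) {
    genes <- .asRankedGenes(ranking)
    truth <- as.character(truth)
    if (!length(truth)) {
        stop("truth set is empty")
    }
    missing <- setdiff(truth, genes)
    if (length(missing)) {
        stop("truth genes absent from the ranking: ",
             paste(utils::head(missing, 10L), collapse = ", "))
    }
    top <- genes[seq_len(length(truth))]
    length(intersect(top, truth)) / length(truth)
}

# Method registry for snrSweep. Each entry takes the simulation output and
# returns something detectionAccuracy() accepts.
.sweepMethod <- function(name, sim, design, nBoot, control, seed) {
    if (design@design == "one_condition") {
        switch(name,
            coca = runCOCA(sim$x, knowledgeGenes(sim$truth),
                plan = bootstrapPlan(nBoot = nBoot), control = control,
                seed = seed),
            vr = varianceRank(sim$x),
            pca = pcaGuidedRank(sim$x, knowledgeGenes(sim$truth)),
            stop("unknown one-condition method: ", name))
    } else {
        x <- cbind(sim$x1, sim$x2)
        switch(name,
            coca = runCOCA(x, knowledgeGenes(sim$truth),
                plan = bootstrapPlan(nBoot = nBoot), control = control,
                conditions = sim$labels, seed = seed),
            fc = foldChangeRank(x, sim$labels),
            sam = samRank(x, sim$labels),
            vr = varianceRank(x),
            stop("unknown two-condition method: ", name))
    }
}

#' Accuracy-versus-SNR benchmark sweep
#'
#' For every (SNR, replicate) cell: simulate a dataset from `design` at that
#' SNR, run each method, and record its detection accuracy. This is the
#' engine behind the comparative benchmark figures.
#'
#' @param design a [SimulationDesign-class]; its `snrDb` is overridden by
#'   the grid.
#' @param methods character vector of method names. One-condition designs
#'   support `"coca"`, `"vr"`, `"pca"`; two-condition designs `"coca"`,
#'   `"fc"`, `"sam"`, `"vr"`.
#' @param snrGrid numeric vector of SNR values in dB.
#' @param reps simulated replicates per SNR value.
#' @param seed master seed; every cell derives its own substream.
#' @param nBoot bootstrap replicates for COCA within each cell.
#' @param control [SpsaControl-class] for COCA.
#' @return Long-format data.frame with columns `method`, `snr_db`, `rep`,
#'   `accuracy`, plus a `"means"` attribute with per-(method, SNR) mean
#'   accuracy and Monte-Carlo standard errors.
#' @examples
#' \donttest{
#' d <- simulationDesign("one_condition", nGenes = 400, nGroundTruth = 40,
#'                       nKnowledge = 10)
#' tab <- snrSweep(d, c("coca", "vr"), snrGrid = c(10, -10), reps = 2,
#'                 seed = 1, nBoot = 5,
#'                 control = spsaControl(maxIter = 100, restarts = 2))
#' attr(tab, "means")
#' }
#' @export
snrSweep <- function(design, methods = c("coca", "vr"), snrGrid = c(10, 0, -10),
                     reps = 3L, seed = NULL, nBoot = 20L,
                     control = spsaControl()) {
    methods::validObject(design)
    rows <- vector("list", length(snrGrid) * reps * length(methods))
    k <- 0L
    cell <- 0L
    for (snr in snrGrid) {
        d <- design
        d@snrDb <- snr
        for (r in seq_len(reps)) {
            cell <- cell + 1L
            simSeed <- .deriveSeed(seed, cell)
            sim <- tryCatch({
                if (d@design == "one_condition") {
                    simulateOneCondition(d, seed = simSeed)
                } else {
                    simulateTwoCondition(d, seed = simSeed)
                }
            }, error = function(e) {
                stop("simulation failed at snr=", snr, " rep=", r, ": ",
                     conditionMessage(e))
            })
            for (m in methods) {
                res <- tryCatch(
                    .sweepMethod(m, sim, d, nBoot, control,
                                 .deriveSeed(simSeed, match(m, methods))),
                    error = function(e) {
                        stop("method '", m, "' failed at snr=", snr, " rep=",
                             r, ": ", conditionMessage(e))
                    })
                k <- k + 1L
                rows[[k]] <- data.frame(
                    method = m, snr_db = snr, rep = r,
                    accuracy = detectionAccuracy(res, truthGenes(sim$truth)),
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    agg <- stats::aggregate(accuracy ~ method + snr_db, data = out,
        FUN = function(a) c(mean = mean(a), se = stats::sd(a) / sqrt(length(a))))
    means <- data.frame(method = agg$method, snr_db = agg$snr_db,
        mean = agg$accuracy[, "mean"], se = agg$accuracy[, "se"],
        stringsAsFactors = FALSE)
    attr(out, "means") <- means
    out
}

#' Plot an SNR sweep
#'
#' Mean detection accuracy versus SNR per method, with the random-guess
#' expectation (`nGroundTruth / nGenes`) as a reference line.
#'
#' @param sweep output of [snrSweep()].
#' @param randomGuess expected accuracy of a random ranking (reference line);
#'   NULL to omit.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the wide matrix of mean accuracies.
#' @export
plotSnrSweep <- function(sweep, randomGuess = NULL, ...) {
    means <- attr(sweep, "means")
    if (is.null(means)) {
        stop("sweep must carry the 'means' attribute from snrSweep()")
    }
    wide <- stats::xtabs(mean ~ snr_db + method, data = means)
    snr <- as.numeric(rownames(wide))
    graphics::matplot(snr, unclass(wide), type = "b", pch = 19, lty = 1,
        xlab = "SNR (dB)", ylab = "detection accuracy",
        ylim = c(0, 1), ...)
    if (!is.null(randomGuess)) {
        graphics::abline(h = randomGuess, lty = 2, col = "grey40")
    }
    graphics::legend("topleft", legend = colnames(wide), col = seq_len(ncol(wide)),
        pch = 19, bty = "n")
    invisible(wide)
}
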