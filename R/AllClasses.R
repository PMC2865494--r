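#' @import methods
NULL

#' Knowledge mask over a gene universe
#'
#' Paired positive/negative weight vectors over the genes of an expression
#' matrix. Positive weights select the knowledge (pathway member) genes whose
#' coordination the objective rewards; negative weights select background
#' genes penalized in the denominator. Weights are ordinarily 0/1 indicators;
#' bootstrap resampling with replacement records draw multiplicity as integer
#' weights (see [makeBootstrapMask()]). A gene may carry weight in neither
#' vector, in which case it does not enter the objective but still receives a
#' participation value and a rank.
#'
#' @slot geneIds character vector naming the gene universe, unique.
#' @slot positive numeric non-negative weights, same length as `geneIds`.
#' @slot negative numeric non-negative weights, same length as `geneIds`.
#' @name KnowledgeMask-class
#' @aliases KnowledgeMask-class
#' @exportClass KnowledgeMask
setClass("KnowledgeMask",
    representation(
        geneIds = "character",
        positive = "numeric",
        negative = "numeric"
    )
)

setValidity("KnowledgeMask", function(object) {
    n <- length(object@geneIds)
    if (length(object@positive) != n || length(object@negative) != n) {
        return("positive/negative weight vectors must match geneIds in length")
    }
    if (anyDuplicated(object@geneIds)) {
        return("geneIds must be unique")
    }
    if (any(object@positive < 0) || any(object@negative < 0)) {
        return("mask weights must be non-negative")
    }
    if (any(object@positive > 0 & object@negative > 0)) {
        return("a gene cannot be both a knowledge and a background gene")
    }
    if (sum(object@positive) < 2) {
        return("total positive mask weight must be at least 2")
    }
    if (sum(object@negative) < 2) {
        return("total negative mask weight must be at least 2")
    }
    TRUE
})

#' Construct a knowledge mask
#'
#' @param geneIds character vector of gene identifiers (the universe, usually
#'   `rownames` of the expression matrix).
#' @param positive knowledge genes: either a character vector of ids or a
#'   numeric weight vector aligned with `geneIds`.
#' @param negative background genes, same conventions as `positive`.
#' @return A [KnowledgeMask-class] object.
#' @examples
#' knowledgeMask(paste0("g", 1:6), positive = c("g1", "g2"),
#'               negative = c("g4", "g5", "g6"))
#' @export
knowledgeMask <- function(geneIds, positive, negative) {
    geneIds <- as.character(geneIds)
    toWeights <- function(sel, what) {
        if (is.character(sel)) {
            missing <- setdiff(sel, geneIds)
            if (length(missing)) {
                stop("unknown ", what, " gene ids: ",
                     paste(utils::head(missing, 10L), collapse = ", "))
            }
            as.numeric(geneIds %in% sel)
        } else {
            w <- as.numeric(sel)
            if (length(w) != length(geneIds)) {
                stop(what, " weight vector length ", length(w),
                     " does not match ", length(geneIds), " gene ids")
            }
            w
        }
    }
    methods::new("KnowledgeMask",
        geneIds = geneIds,
        positive = toWeights(positive, "positive"),
        negative = toWeights(negative, "negative"))
}

#' Coordinative direction
#'
#' A unit vector in sample space maximizing the masked coordination ratio,
#' together with the attained objective value and the optimizer trace.
#'
#' @slot w named numeric vector, unit Euclidean norm, one entry per sample.
#' @slot objective numeric(1), best objective value over the trace.
#' @slot trace data.frame with columns `iteration`, `objective`.
#' @slot seed integer(1), the seed used (NA if none).
#' @slot degenerate logical(1), TRUE when the objective was identically zero
#'   and the initial direction was returned.
#' @name CoordinativeDirection-class
#' @aliases CoordinativeDirection-class
#' @exportClass CoordinativeDirection
setClass("CoordinativeDirection",
    representation(
        w = "numeric",
        objective = "numeric",
        trace = "data.frame",
        seed = "integer",
        degenerate = "logical"
    ),
    prototype(seed = NA_integer_, degenerate = FALSE)
)

setValidity("CoordinativeDirection", function(object) {
    if (abs(sqrt(sum(object@w^2)) - 1) > 1e-9) {
        return("w must have unit Euclidean norm (within 1e-9)")
    }
    if (length(object@objective) != 1L || is.na(object@objective) ||
        object@objective < 0) {
        return("objective must be a single non-negative value")
    }
    TRUE
})

#' SPSA optimizer control parameters
#'
#' Gain schedule and stopping rule for the simultaneous-perturbation
#' stochastic approximation ascent. Gains follow standard SPSA practice:
#' `a_n = a0 / (n + 1 + A)^alpha`, `c_n = c0 / (n + 1)^gamma` with
#' `A = 0.1 * maxIter`.
#'
#' @slot maxIter maximum iterations per restart.
#' @slot a0,c0 step-size and perturbation-magnitude scales.
#' @slot alpha,gamma gain-decay exponents, `0 < gamma < alpha <= 1`.
#' @slot tol relative objective improvement below which an iteration counts
#'   as stalled.
#' @slot patience consecutive stalled iterations before stopping.
#' @slot restarts number of restarts (first is the knowledge-centroid warm
#'   start, the rest random unit vectors).
#' @slot seed integer seed (NA for none).
#' @name SpsaControl-class
#' @aliases SpsaControl-class
#' @exportClass SpsaControl
setClass("SpsaControl",
    representation(
        maxIter = "integer",
        a0 = "numeric",
        c0 = "numeric",
        alpha = "numeric",
        gamma = "numeric",
        tol = "numeric",
        patience = "integer",
        restarts = "integer",
        seed = "integer"
    )
)

setValidity("SpsaControl", function(object) {
    if (object@maxIter < 1L) return("maxIter must be positive")
    if (object@a0 <= 0 || object@c0 <= 0) return("a0 and c0 must be positive")
    if (!(object@gamma > 0 && object@gamma < object@alpha && object@alpha <= 1)) {
        return("gain exponents must satisfy 0 < gamma < alpha <= 1")
    }
    if (object@tol < 0) return("tol must be non-negative")
    if (object@patience < 1L) return("patience must be positive")
    if (object@restarts < 1L) return("restarts must be positive")
    TRUE
})

#' @rdname SpsaControl-class
#' @param maxIter,a0,c0,alpha,gamma,tol,patience,restarts,seed see slot
#'   documentation; defaults are the package's standard SPSA settings.
#' @return An [SpsaControl-class] object.
#' @examples
#' spsaControl(maxIter = 200, restarts = 2)
#' @export
spsaControl <- function(maxIter = 500L, a0 = 0.1, c0 = 0.05, alpha = 0.602,
                        gamma = 0.101, tol = 1e-6, patience = 20L,
                        restarts = 4L, seed = NA_integer_) {
    methods::new("SpsaControl",
        maxIter = as.integer(maxIter), a0 = a0, c0 = c0, alpha = alpha,
        gamma = gamma, tol = tol, patience = as.integer(patience),
        restarts = as.integer(restarts), seed = as.integer(seed))
}

#' Bootstrap plan for bagged COCA
#'
#' @slot nBoot number of bootstrap replicates B.
#' @slot backgroundSize number of background genes drawn (with replacement)
#'   per replicate; NA means "match the knowledge set size".
#' @slot pool character vector of background gene ids to sample from;
#'   length 0 means "all genes outside the knowledge set".
#' @name BootstrapPlan-class
#' @aliases BootstrapPlan-class
#' @exportClass BootstrapPlan
setClass("BootstrapPlan",
    representation(
        nBoot = "integer",
        backgroundSize = "integer",
        pool = "character"
    )
)

setValidity("BootstrapPlan", function(object) {
    if (object@nBoot < 1L) return("nBoot must be at least 1")
    if (!is.na(object@backgroundSize) && object@backgroundSize < 2L) {
        return("backgroundSize must be at least 2")
    }
    TRUE
})

#' @rdname BootstrapPlan-class
#' @param nBoot,backgroundSize,pool see slot documentation.
#' @return A [BootstrapPlan-class] object.
#' @examples
#' bootstrapPlan(nBoot = 100)
#' @export
bootstrapPlan <- function(nBoot = 100L, backgroundSize = NA_integer_,
                          pool = character(0)) {
    methods::new("BootstrapPlan", nBoot = as.integer(nBoot),
        backgroundSize = as.integer(backgroundSize),
        pool = as.character(pool))
}

#' Bagged participation result
#'
#' Output of [runCOCA()]: per-gene bagged participation values, per-replicate
#' participation and (sign-corrected) directions, and the final ranking by
#' absolute bagged participation.
#'
#' @slot aBagged named numeric, bagged participation per gene.
#' @slot aSd named numeric, across-replicate standard deviation.
#' @slot aReplicates B x N matrix of replicate participation vectors.
#' @slot wReplicates B x M matrix of sign-corrected replicate directions.
#' @slot ranking character, gene ids in rank order (|aBagged| descending,
#'   ties by gene id).
#' @slot knowledge character, the matched knowledge gene ids.
#' @slot conditions character, per-sample condition labels (length 0 for the
#'   one-condition analysis).
#' @slot seed integer master seed (NA if none).
#' @name ParticipationResult-class
#' @aliases ParticipationResult-class
#' @exportClass ParticipationResult
setClass("ParticipationResult",
    representation(
        aBagged = "numeric",
        aSd = "numeric",
        aReplicates = "matrix",
        wReplicates = "matrix",
        ranking = "character",
        knowledge = "character",
        conditions = "character",
        seed = "integer"
    )
)

setValidity("ParticipationResult", function(object) {
    ids <- names(object@aBagged)
    if (is.null(ids)) return("aBagged must be named by gene id")
    if (length(object@ranking) != length(ids) ||
        !setequal(object@ranking, ids)) {
        return("ranking must be a permutation of the gene ids")
    }
    a <- abs(object@aBagged[object@ranking])
    if (is.unsorted(rev(a))) {
        return("|aBagged| must be non-increasing along the ranking")
    }
    TRUE
})

#' Ground truth of a simulated dataset
#'
#' Bookkeeping for the linear latent-model simulators: the generating
#' participation and activity matrices, the ground-truth and knowledge gene
#' sets, and the requested/realized signal-to-noise ratios.
#'
#' @slot aTrue N x L participation matrix (condition 1).
#' @slot aTrue2 N x L participation matrix for condition 2 (0 x 0 for the
#'   one-condition design).
#' @slot tTrue list of L x M latent activity matrices, one per condition.
#' @slot groundTruth character, gene ids the method is scored on.
#' @slot knowledge character, gene ids given to the method as guidance.
#' @slot snrDb requested SNR in decibels (Inf for noiseless).
#' @slot snrRealized realized SNR in decibels per condition.
#' @slot design `"one_condition"` or `"two_condition"`.
#' @slot seed integer seed.
#' @name SimulationTruth-class
#' @aliases SimulationTruth-class
#' @exportClass SimulationTruth
setClass("SimulationTruth",
    representation(
        aTrue = "matrix",
        aTrue2 = "matrix",
        tTrue = "list",
        groundTruth = "character",
        knowledge = "character",
        snrDb = "numeric",
        snrRealized = "numeric",
        design = "character",
        seed = "integer"
    )
)

#' Simulation design parameters
#'
#' @slot nGenes,nSamples,nProcesses,nKnowledge,nGroundTruth dataset shape:
#'   genes, samples per condition, latent processes, knowledge genes given to
#'   the method, ground-truth genes scored. Defaults mirror the benchmark
#'   designs: one-condition 5000 x 8 with 5 processes, 200 ground-truth and
#'   50 knowledge genes; two-condition 10000 x 20(+20) with 100 ground-truth
#'   and 50 knowledge genes.
#' @slot design `"one_condition"` or `"two_condition"`.
#' @slot snrDb target signal-to-noise ratio in decibels (Inf = noiseless).
#' @slot overlap fraction of each process block shared with the next process.
#' @name SimulationDesign-class
#' @aliases SimulationDesign-class
#' @exportClass SimulationDesign
setClass("SimulationDesign",
    representation(
        nGenes = "integer",
        nSamples = "integer",
        nProcesses = "integer",
        nKnowledge = "integer",
        nGroundTruth = "integer",
        design = "character",
        snrDb = "numeric",
        overlap = "numeric"
    )
)

setValidity("SimulationDesign", function(object) {
    if (!object@design %in% c("one_condition", "two_condition")) {
        return("design must be 'one_condition' or 'two_condition'")
    }
    if (object@nProcesses < 1L) return("nProcesses must be positive")
    if (object@nGenes < object@nProcesses) {
        return("need at least one gene per process")
    }
    if (is.finite(object@snrDb) && is.na(object@snrDb)) {
        return("snrDb must be finite or Inf")
    }
    if (object@overlap < 0 || object@overlap >= 1) {
        return("overlap must be in [0, 1)")
    }
    if (object@nKnowledge < 2L) return("nKnowledge must be at least 2")
    TRUE
})

#' @rdname SimulationDesign-class
#' @param design,nGenes,nSamples,nProcesses,nKnowledge,nGroundTruth,snrDb,overlap
#'   see slot documentation; unspecified shape parameters default per design.
#' @return A [SimulationDesign-class] object.
#' @examples
#' simulationDesign("one_condition", snrDb = 10)
#' simulationDesign("two_condition", nGenes = 3000)
#' @export
simulationDesign <- function(design = c("one_condition", "two_condition"),
                             nGenes = NULL, nSamples = NULL, nProcesses = 5L,
                             nKnowledge = 50L, nGroundTruth = NULL,
                             snrDb = 10, overlap = 0.1) {
    design <- match.arg(design)
    if (design == "one_condition") {
        if (is.null(nGenes)) nGenes <- 5000L
        if (is.null(nSamples)) nSamples <- 8L
        if (is.null(nGroundTruth)) nGroundTruth <- 200L
    } else {
        if (is.null(nGenes)) nGenes <- 10000L
        if (is.null(nSamples)) nSamples <- 20L
        if (is.null(nGroundTruth)) nGroundTruth <- 100L
    }
    methods::new("SimulationDesign",
        nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
        nProcesses = as.integer(nProcesses),
        nKnowledge = as.integer(nKnowledge),
        nGroundTruth = as.integer(nGroundTruth),
        design = design, snrDb = as.numeric(snrDb),
        overlap = as.numeric(overlap))
}
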