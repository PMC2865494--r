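# Accessor generics and show methods.

#' @rdname CoordinativeDirection-class
#' @param object,x a package object.
#' @export
setGeneric("direction", function(object) standardGeneric("direction"))

#' @rdname CoordinativeDirection-class
#' @export
setMethod("direction", "CoordinativeDirection", function(object) object@w)

#' @rdname CoordinativeDirection-class
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname CoordinativeDirection-class
#' @export
setMethod("objectiveValue", "CoordinativeDirection",
          function(object) object@objective)

#' @rdname CoordinativeDirection-class
#' @export
setGeneric("optimTrace", function(object) standardGeneric("optimTrace"))

#' @rdname CoordinativeDirection-class
#' @export
setMethod("optimTrace", "CoordinativeDirection", function(object) object@trace)

#' @rdname ParticipationResult-class
#' @param object,x a package object.
#' @export
setGeneric("baggedParticipation",
           function(object) standardGeneric("baggedParticipation"))

#' @rdname ParticipationResult-class
#' @export
setMethod("baggedParticipation", "ParticipationResult",
          function(object) object@aBagged)

#' @rdname ParticipationResult-class
#' @export
setGeneric("participationSd", function(object) standardGeneric("participationSd"))

#' @rdname ParticipationResult-class
#' @export
setMethod("participationSd", "ParticipationResult", function(object) object@aSd)

#' @rdname ParticipationResult-class
#' @export
setGeneric("replicateParticipation",
           function(object) standardGeneric("replicateParticipation"))

#' @rdname ParticipationResult-class
#' @export
setMethod("replicateParticipation", "ParticipationResult",
          function(object) object@aReplicates)

#' @rdname ParticipationResult-class
#' @export
setGeneric("replicateDirections",
           function(object) standardGeneric("replicateDirections"))

#' @rdname ParticipationResult-class
#' @export
setMethod("replicateDirections", "ParticipationResult",
          function(object) object@wReplicates)

#' @rdname ParticipationResult-class
#' @export
setGeneric("geneRanking", function(object) standardGeneric("geneRanking"))

#' @rdname ParticipationResult-class
#' @export
setMethod("geneRanking", "ParticipationResult", function(object) object@ranking)

#' Ranking table of a bagged COCA result
#'
#' @param object a [ParticipationResult-class].
#' @return data.frame with columns `rank`, `gene`, `score` (bagged
#'   participation), `abs_score`, `sd` (across replicates), `method`.
#' @rdname ParticipationResult-class
#' @export
setGeneric("rankingTable", function(object) standardGeneric("rankingTable"))

#' @rdname ParticipationResult-class
#' @export
setMethod("rankingTable", "ParticipationResult", function(object) {
    ids <- object@ranking
    data.frame(
        rank = seq_along(ids),
        gene = ids,
        score = unname(object@aBagged[ids]),
        abs_score = abs(unname(object@aBagged[ids])),
        sd = unname(object@aSd[ids]),
        method = "coca",
        stringsAsFactors = FALSE
    )
})

#' @rdname SimulationTruth-class
#' @param object,x a package object.
#' @export
setGeneric("truthGenes", function(object) standardGeneric("truthGenes"))

#' @rdname SimulationTruth-class
#' @export
setMethod("truthGenes", "SimulationTruth", function(object) object@groundTruth)

#' @rdname SimulationTruth-class
#' @export
setGeneric("knowledgeGenes", function(object) standardGeneric("knowledgeGenes"))

#' @rdname SimulationTruth-class
#' @export
setMethod("knowledgeGenes", "SimulationTruth", function(object) object@knowledge)

#' @rdname SimulationTruth-class
#' @export
setGeneric("realizedSnr", function(object) standardGeneric("realizedSnr"))

#' @rdname SimulationTruth-class
#' @export
setMethod("realizedSnr", "SimulationTruth", function(object) object@snrRealized)

#' @rdname KnowledgeMask-class
#' @param object,x a package object.
#' @export
setGeneric("positiveWeights", function(object) standardGeneric("positiveWeights"))

#' @rdname KnowledgeMask-class
#' @export
setMethod("positiveWeights", "KnowledgeMask", function(object) {
    stats::setNames(object@positive, object@geneIds)
})

#' @rdname KnowledgeMask-class
#' @export
setGeneric("negativeWeights", function(object) standardGeneric("negativeWeights"))

#' @rdname KnowledgeMask-class
#' @export
setMethod("negativeWeights", "KnowledgeMask", function(object) {
    stats::setNames(object@negative, object@geneIds)
})

setMethod("show", "KnowledgeMask", function(object) {
    cat("KnowledgeMask over", length(object@geneIds), "genes\n")
    cat("  positive: ", sum(object@positive > 0), " genes (total weight ",
        format(sum(object@positive)), ")\n", sep = "")
    cat("  negative: ", sum(object@negative > 0), " genes (total weight ",
        format(sum(object@negative)), ")\n", sep = "")
})

setMethod("show", "CoordinativeDirection", function(object) {
    cat("CoordinativeDirection over", length(object@w), "samples\n")
    cat("  objective:", format(object@objective, digits = 6), "\n")
    cat("  iterations:", max(object@trace$iteration), "\n")
    if (object@degenerate) cat("  [degenerate: objective identically zero]\n")
})

setMethod("show", "ParticipationResult", function(object) {
    cat("ParticipationResult:", length(object@aBagged), "genes,",
        nrow(object@aReplicates), "bootstrap replicates\n")
    if (length(object@conditions)) {
        cat("  two-condition differential participation\n")
    }
    cat("  top genes:", paste(utils::head(object@ranking, 5L), collapse = ", "),
        "...\n")
})

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth (", object@design, ")\n", sep = "")
    cat("  genes:", nrow(object@aTrue), " processes:", ncol(object@aTrue), "\n")
    cat("  ground truth:", length(object@groundTruth),
        " knowledge:", length(object@knowledge), "\n")
    cat("  SNR requested:", object@snrDb, "dB, realized:",
        paste(format(object@snrRealized, digits = 4), collapse = ", "), "dB\n")
})

setMethod("show", "SpsaControl", function(object) {
    cat("SpsaControl: maxIter=", object@maxIter, " a0=", object@a0,
        " c0=", object@c0, " alpha=", object@alpha, " gamma=", object@gamma,
        " tol=", object@tol, " patience=", object@patience,
        " restarts=", object@restarts, "\n", sep = "")
})

setMethod("show", "BootstrapPlan", function(object) {
    cat("BootstrapPlan: B=", object@nBoot, ", background size=",
        ifelse(is.na(object@backgroundSize), "auto (match knowledge)",
               object@backgroundSize),
        ", pool=", ifelse(length(object@pool), length(object@pool),
                          "all non-knowledge genes"), "\n", sep = "")
})
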