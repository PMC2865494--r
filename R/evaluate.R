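# ROC/AUC evaluation of a ranking against a labeled positive gene set.

# Normalize (scores, positives) input: named score vector or ranking
# data.frame (gene/score columns).
.labeledScores <- function(ranking, positives) {
    if (is.data.frame(ranking)) {
        if (!all(c("gene", "score") %in% names(ranking))) {
            stop("ranking data.frame needs 'gene' and 'score' columns")
        }
        scores <- stats::setNames(abs(ranking$score), ranking$gene)
    } else {
        if (is.null(names(ranking))) {
            stop("scores must be named by gene id")
        }
        scores <- ranking
    }
    positives <- as.character(positives)
    missing <- setdiff(positives, names(scores))
    if (length(missing)) {
        stop("positive genes absent from the ranking: ",
             paste(utils::head(missing, 10L), collapse = ", "))
    }
    lab <- names(scores) %in% positives
    if (all(lab) || !any(lab)) {
        stop("need at least one positive and one negative gene")
    }
    list(scores = as.numeric(scores), labels = lab)
}

#' ROC curve of a labeled ranking
#'
#' Standard sensitivity/1-specificity sweep over score thresholds,
#' descending. Tied scores are grouped into a single step so the curve has
#' one point per distinct threshold, starting at (0, 0) and ending at (1, 1).
#'
#' @param ranking named numeric scores (higher = ranked higher) or a ranking
#'   data.frame with `gene` and `score` columns (`abs(score)` is used).
#' @param positives character vector of positive gene ids.
#' @return data.frame with columns `fpr`, `tpr`, `threshold` (the threshold
#'   at and above which genes are called positive; `Inf` for the (0,0) point).
#' @examples
#' sc <- c(a = 4, b = 3, c = 2, d = 1)
#' rocCurve(sc, c("a", "c"))
#' @export
rocCurve <- function(ranking, positives) {
    ls <- .labeledScores(ranking, positives)
    ord <- order(ls$scores, decreasing = TRUE)
    sc <- ls$scores[ord]
    lab <- ls$labels[ord]
    P <- sum(lab); Ng <- sum(!lab)
    grp <- cumsum(!duplicated(sc))          # tie groups along descending scores
    tp <- cumsum(lab); fp <- cumsum(!lab)
    last <- !duplicated(grp, fromLast = TRUE)  # last index of each tie group
    data.frame(
        fpr = c(0, fp[last] / Ng),
        tpr = c(0, tp[last] / P),
        threshold = c(Inf, sc[last])
    )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [rocCurve()]. Equals the Mann-Whitney concordance
#' probability: the fraction of (positive, negative) pairs in which the
#' positive gene outscores the negative one, ties counting 1/2.
#'
#' @inheritParams rocCurve
#' @return A number in \[0, 1\].
#' @examples
#' rankingAUC(c(a = 4, b = 3, c = 2, d = 1), c("a", "c"))  # 0.75
#' @export
rankingAUC <- function(ranking, positives) {
    roc <- rocCurve(ranking, positives)
    sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' Evaluate a ranking against a positive gene set
#'
#' Convenience wrapper computing the ROC curve and AUC, optionally excluding
#' a set of genes (typically the knowledge genes used as guidance, so the
#' score reflects only genes the method had to discover).
#'
#' @inheritParams rocCurve
#' @param exclude gene ids dropped from the evaluation before the sweep
#'   (default none).
#' @return list with elements `auc` (number) and `roc` (data.frame).
#' @export
evaluateRanking <- function(ranking, positives, exclude = NULL) {
    if (is.data.frame(ranking)) {
        scores <- stats::setNames(abs(ranking$score), ranking$gene)
    } else if (methods::is(ranking, "ParticipationResult")) {
        scores <- abs(baggedParticipation(ranking))
    } else {
        scores <- ranking
    }
    if (!is.null(exclude)) {
        scores <- scores[!names(scores) %in% exclude]
        positives <- setdiff(positives, exclude)
    }
    list(auc = rankingAUC(scores, positives),
         roc = rocCurve(scores, positives))
}
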