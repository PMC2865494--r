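#' Simultaneous-perturbation gradient estimate
#'
#' Estimates the full gradient of `f` at `w` from exactly two function
#' evaluations: with `s` a random vector of independent +/-1 signs,
#' `g_k = (f(w + c s) - f(w - c s)) / (2 c s_k)`. For smooth `f` the
#' estimate is unbiased to second order in `c`; averaging over the sign
#' distribution recovers the true gradient.
#'
#' @param f function of a numeric vector returning a scalar.
#' @param w numeric evaluation point.
#' @param c positive perturbation magnitude.
#' @param s perturbation vector of +/-1 entries, same length as `w`.
#' @return Numeric gradient estimate, same length as `w`.
#' @examples
#' f <- function(w) w[1]
#' spsaGradient(f, c(0, 0), 0.1, c(1, 1))  # c(1, 1)
#' @export
spsaGradient <- function(f, w, c, s) {
    if (c <= 0) {
        stop("perturbation magnitude c must be positive")
    }
    s <- as.numeric(s)
    if (length(s) != length(w) || !all(abs(s) == 1)) {
        stop("s must be a vector of +/-1 entries matching w in length")
    }
    fp <- f(w + c * s)
    fm <- f(w - c * s)
    if (!is.finite(fp) || !is.finite(fm)) {
        bad <- if (!is.finite(fp)) w + c * s else w - c * s
        stop("objective non-finite at perturbed point w = (",
             paste(format(utils::head(bad, 8L), digits = 4), collapse = ", "),
             if (length(bad) > 8L) ", ..." else "", ")")
    }
    # 1/s_k == s_k for +/-1 entries
    (fp - fm) / (2 * c) * s
}

# One SPSA ascent run from w0; returns best unit iterate, its objective,
# the per-iteration objective trace, and whether any evaluation was positive.
.spsaAscent <- function(f, w0, control) {
    maxIter <- control@maxIter
    a0 <- control@a0; c0 <- control@c0
    alpha <- control@alpha; gamma <- control@gamma
    A <- 0.1 * maxIter
    tol <- control@tol; patience <- control@patience
    M <- length(w0)

    w <- w0 / sqrt(sum(w0^2))
    fw <- f(w)
    anyPositive <- fw > 0
    bestW <- w; bestF <- fw
    objTrace <- numeric(maxIter + 1L)
    objTrace[1L] <- fw
    stall <- 0L
    n <- 0L
    while (n < maxIter) {
        n <- n + 1L
        cn <- c0 / (n + 1)^gamma
        an <- a0 / (n + 1 + A)^alpha
        s <- sample(c(-1, 1), M, replace = TRUE)
        fp <- f(w + cn * s)
        fm <- f(w - cn * s)
        if (!is.finite(fp) || !is.finite(fm)) {
            stop("objective non-finite during SPSA ascent at iteration ", n)
        }
        if (fp > 0 || fm > 0) anyPositive <- TRUE
        g <- (fp - fm) / (2 * cn) * s
        w2 <- w + an * g
        nrm <- sqrt(sum(w2^2))
        if (nrm > 0) w <- w2 / nrm     # stay on the unit sphere
        fw <- f(w)
        if (fw > 0) anyPositive <- TRUE
        objTrace[n + 1L] <- fw
        if (fw - bestF > tol * max(bestF, 1e-12)) {
            stall <- 0L
        } else {
            stall <- stall + 1L
        }
        if (fw > bestF) {
            bestF <- fw; bestW <- w
        }
        if (stall >= patience) break
    }
    list(w = bestW, objective = bestF,
         trace = data.frame(iteration = 0:n, objective = objTrace[1:(n + 1L)]),
         anyPositive = anyPositive)
}

#' Learn the coordinative direction by SPSA ascent
#'
#' Maximizes the masked coordination ratio ([cocaObjective()]) over unit
#' directions by simultaneous-perturbation stochastic gradient ascent with
#' restarts. The first restart warm-starts from the normalized mean profile
#' of the knowledge genes; remaining restarts use isotropic random unit
#' vectors. Each iterate is renormalized to the unit sphere (the objective is
#' scale-invariant). The restart attaining the highest objective anywhere
#' along its trace wins, and the reported direction/objective are that best
#' iterate, not the last one.
#'
#' @param x genes x samples expression matrix.
#' @param mask a [KnowledgeMask-class] over the genes of `x`.
#' @param control an [SpsaControl-class]; see [spsaControl()].
#' @param p norm order of the objective (1 or 2).
#' @param seed integer seed; overrides `control@seed` when given. Restart r
#'   uses a deterministic substream so runs are reproducible.
#' @param center row-center each gene profile first (default TRUE).
#' @return A [CoordinativeDirection-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 25, 8, dimnames = list(paste0("g", 1:25), NULL))
#' m <- knowledgeMask(rownames(x), paste0("g", 1:5), paste0("g", 11:25))
#' d <- optimizeDirection(x, m, spsaControl(maxIter = 100, restarts = 2), seed = 7)
#' objectiveValue(d)
#' @export
optimizeDirection <- function(x, mask, control = spsaControl(), p = 1,
                              seed = NULL, center = TRUE) {
    x <- .asExpressionMatrix(x)
    stopifnot(methods::is(mask, "KnowledgeMask"))
    methods::validObject(mask)
    methods::validObject(control)
    if (center) {
        x <- .preprocess(x, center = TRUE)
    }
    if (is.null(seed) && !is.na(control@seed)) {
        seed <- control@seed
    }
    wts <- .maskWeights(mask, rownames(x))
    ip <- which(wts$positive > 0)
    ineg <- which(wts$negative > 0)
    Xp <- x[ip, , drop = FALSE]
    f <- .makeObjective(Xp, wts$positive[ip],
                        x[ineg, , drop = FALSE], wts$negative[ineg], p = p)
    M <- ncol(x)

    # knowledge-centroid warm start (weighted mean positive profile)
    centroid <- drop(wts$positive[ip] %*% Xp)
    if (sqrt(sum(centroid^2)) < 1e-12) {
        centroid <- rep(1, M)
    }

    best <- NULL
    anyPositive <- FALSE
    w0first <- centroid / sqrt(sum(centroid^2))
    for (r in seq_len(control@restarts)) {
        res <- .withSeed(.deriveSeed(seed, r), function() {
            w0 <- if (r == 1L) {
                w0first
            } else {
                v <- stats::rnorm(M)
                while (sum(v^2) == 0) v <- stats::rnorm(M)
                v / sqrt(sum(v^2))
            }
            .spsaAscent(f, w0, control)
        })
        anyPositive <- anyPositive || res$anyPositive
        if (is.null(best) || res$objective > best$objective) {
            best <- res
        }
    }

    degenerate <- !anyPositive
    if (degenerate) {
        warning("objective identically zero across all evaluations; ",
                "returning the initial direction (degenerate)")
        best$w <- w0first
        best$objective <- 0
    }
    names(best$w) <- colnames(x)
    methods::new("CoordinativeDirection",
        w = best$w, objective = best$objective, trace = best$trace,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        degenerate = degenerate)
}
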