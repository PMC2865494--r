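# Independent oracles and fixture builders shared across the suite.

# Brute-force masked coordination ratio: explicit double loop over genes,
# no guard term (independent of the package's vectorized path).
bruteObjective <- function(x, posIdx, negIdx, w, p = 1,
                           posW = NULL, negW = NULL) {
    if (is.null(posW)) posW <- rep(1, length(posIdx))
    if (is.null(negW)) negW <- rep(1, length(negIdx))
    num <- 0
    for (k in seq_along(posIdx)) {
        num <- num + posW[k] * abs(sum(x[posIdx[k], ] * w))^p
    }
    den <- 0
    for (k in seq_along(negIdx)) {
        den <- den + negW[k] * abs(sum(x[negIdx[k], ] * w))^p
    }
    num^(1 / p) / den^(1 / p)
}

# Brute-force Mann-Whitney concordance: all positive-negative pairs,
# ties count 1/2.
bruteAUC <- function(scores, isPos) {
    pos <- scores[isPos]
    neg <- scores[!isPos]
    tot <- 0
    for (p in pos) {
        for (n in neg) {
            tot <- tot + (p > n) + 0.5 * (p == n)
        }
    }
    tot / (length(pos) * length(neg))
}

# Noiseless rank-1 fixture: nPos signal genes with |loading| in [2, 3]
# sharing one latent activity profile, nNull background genes with zero
# rows. Returns the matrix, loadings, latent profile and gene groups.
rank1Fixture <- function(nPos = 20L, nNull = 80L, M = 8L, seed = 1L) {
    set.seed(seed)
    a <- sample(c(-1, 1), nPos, replace = TRUE) * runif(nPos, 2, 3)
    tt <- rnorm(M)
    x <- rbind(outer(a, tt), matrix(0, nNull, M))
    ids <- sprintf("g%03d", seq_len(nPos + nNull))
    dimnames(x) <- list(ids, paste0("s", seq_len(M)))
    list(x = x, a = c(a, rep(0, nNull)), t = tt,
         signal = ids[seq_len(nPos)], null = ids[nPos + seq_len(nNull)])
}

# Random small expression matrix with named genes.
randomExpr <- function(N, M, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(rnorm(N * M), N, M,
           dimnames = list(sprintf("g%03d", seq_len(N)),
                           paste0("s", seq_len(M))))
}
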