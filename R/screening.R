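# Unbiased feature screening: random-forest Gini importance, a permutation
# null of the importances obtained by refitting under label permutation
# (PIMP, 50 permutations by default), right-tail permutation p-values with
# add-one smoothing, and Benjamini-Hochberg FDR control at 0.05.

#' Random-forest Gini importance
#'
#' Mean-decrease-in-impurity importances from a random forest, normalised
#' to sum to 1 across features (set \code{normalize = FALSE} for the raw
#' impurity decreases, the scale on which the permutation test operates).
#' Deterministic for a fixed seed.
#'
#' @param X data.frame or matrix of n samples x d features.
#' @param y class labels (factor or character), at least two classes.
#' @param nTrees number of trees (default 500).
#' @param seed integer seed.
#' @param normalize divide by the total so importances sum to 1 (default).
#' @return Named numeric(d).
#' @export
giniImportance <- function(X, y, nTrees = 500, seed = 1L, normalize = TRUE) {
    X <- as.data.frame(X)
    y <- factor(y)
    if (nlevels(droplevels(y)) < 2L)
        stop("y must contain at least two classes")
    if (nrow(X) < ncol(X)) stop("need at least as many samples as features")
    fit <- ranger::ranger(x = X, y = y, num.trees = nTrees,
                          importance = "impurity", seed = as.integer(seed),
                          num.threads = 1L)
    imp <- fit$variable.importance
    if (!normalize) return(imp)
    if (sum(imp) <= 0) imp <- rep(1, length(imp))  # degenerate: no splits
    imp / sum(imp)
}

#' Permutation null distribution of Gini importances (PIMP)
#'
#' Repeats \code{\link{giniImportance}} B times with the sample labels
#' randomly permuted, building the importance distribution of each feature
#' under the null hypothesis of no feature-label association. Permutations
#' and forest seeds are derived reproducibly from the master seed.
#'
#' @inheritParams giniImportance
#' @param B number of label permutations (default 50).
#' @param normalize normalise each permutation's importances to sum 1;
#'   FALSE (default) keeps the raw impurity decreases that the permutation
#'   p-value compares.
#' @return B x d matrix of null importances (rows = permutations).
#' @export
pimpNull <- function(X, y, B = 50, nTrees = 500, seed = 1L,
                     normalize = FALSE) {
    if (B < 1) stop("B must be at least 1")
    seeds <- deriveSeeds(seed, 2L * B)
    d <- ncol(as.data.frame(X))
    out <- matrix(NA_real_, B, d)
    for (b in seq_len(B)) {
        yb <- withSeed(seeds[b], sample(y))
        out[b, ] <- giniImportance(X, yb, nTrees = nTrees,
                                   seed = seeds[B + b],
                                   normalize = normalize)
    }
    colnames(out) <- colnames(as.data.frame(X))
    out
}

#' Right-tail permutation p-value with add-one smoothing
#'
#' \eqn{p = (1 + \#\{null_b \ge observed\}) / (1 + B)}: the probability
#' mass of the permutation distribution at or to the right of the observed
#' importance, smoothed so p is never exactly 0. Ties count against the
#' observed value.
#'
#' @param observed observed importance (scalar).
#' @param null numeric vector of B null importances.
#' @return p-value in \eqn{(0, 1]}.
#' @export
#' @examples
#' pimpPvalue(0.9, rep(0.1, 50))  # 1/51
pimpPvalue <- function(observed, null) {
    (1 + sum(null >= observed)) / (1 + length(null))
}

#' Benjamini-Hochberg adjustment and retention
#'
#' Step-up BH adjusted p-values (with the usual monotonicity enforcement,
#' via \code{stats::p.adjust}); a feature is retained when its adjusted
#' p-value is below \code{alpha}.
#'
#' @param pRaw numeric vector of raw p-values in \eqn{[0, 1]}.
#' @param alpha FDR level (default 0.05).
#' @return list(pAdj, retained): adjusted p-values and the logical
#'   retention vector \code{pAdj < alpha}.
#' @export
bhAdjust <- function(pRaw, alpha = 0.05) {
    if (any(pRaw < 0 | pRaw > 1)) stop("p-values must lie in [0, 1]")
    pAdj <- stats::p.adjust(pRaw, method = "BH")
    list(pAdj = pAdj, retained = pAdj < alpha)
}

#' Screen features by PIMP-corrected importance
#'
#' Full screening procedure: fit a random forest on the original labels for
#' Gini importances; build the B-permutation null; convert each observed
#' importance to a right-tail permutation p-value; adjust by
#' Benjamini-Hochberg and retain features with adjusted p below alpha. The
#' permutation test compares raw impurity decreases (observed vs null);
#' the reported gini column is normalised to sum 1 across features. A
#' Kruskal-Wallis inter-group p-value per feature is reported alongside for
#' context but never used for retention.
#'
#' @inheritParams pimpNull
#' @param alpha FDR level (default 0.05).
#' @return A \linkS4class{ScreeningResult}.
#' @export
#' @examples
#' prm <- lapply(lamenessClasses(), gaitClassParams, targetCv = 0.15)
#' X <- do.call(rbind, lapply(seq_along(prm), function(i)
#'     sampleFeatureVectors(prm[[i]], 30, seed = i)))
#' res <- screenFeatures(X[featureNames()], X$label, B = 10, nTrees = 50)
#' retainedFeatures(res)
screenFeatures <- function(X, y, B = 50, alpha = 0.05, nTrees = 500,
                           seed = 1L) {
    X <- as.data.frame(X)
    y <- factor(y)
    rawImp <- giniImportance(X, y, nTrees = nTrees, seed = seed,
                             normalize = FALSE)
    gini <- if (sum(rawImp) > 0) rawImp / sum(rawImp)
            else rep(1 / length(rawImp), length(rawImp))
    null <- pimpNull(X, y, B = B, nTrees = nTrees, seed = seed)
    pRaw <- vapply(seq_len(ncol(X)), function(j)
        pimpPvalue(rawImp[j], null[, j]), numeric(1))
    adj <- bhAdjust(pRaw, alpha)
    pKw <- vapply(seq_len(ncol(X)), function(j) {
        if (stats::var(X[[j]]) == 0) return(1)
        stats::kruskal.test(X[[j]], y)$p.value
    }, numeric(1))
    tab <- data.frame(feature = colnames(X), gini = as.numeric(gini),
                      p_kw = pKw, p_raw = pRaw, p_adj = adj$pAdj,
                      retained = adj$retained, stringsAsFactors = FALSE)
    new("ScreeningResult", table = tab, nullImportances = null,
        B = as.integer(B), alpha = alpha, seed = as.integer(seed))
}
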