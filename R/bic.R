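#' BIC score of an exemplar clustering
#'
#' Scores a clustering by modelling each cluster as a spherical Gaussian
#' centred on its exemplar's profile with one pooled variance. Because the
#' exemplars are data points that fit themselves exactly, the variance is
#' estimated from the residual degrees of freedom,
#' \eqn{\hat\sigma^2 = RSS/(d(n-K))}, where RSS is the total squared
#' Euclidean distance of the n points to their exemplars, d the profile
#' length and K the number of exemplars. The score is
#' \deqn{BIC = nd\,\ln\hat\sigma^2 + \kappa \ln n, \quad \kappa = Kd + 1,}
#' lower is better. \eqn{\hat\sigma^2} is floored at 1e-12; the saturated
#' clustering K = n leaves no residual degrees of freedom and is assigned
#' \code{+Inf} (it memorizes the data and is never selectable).
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param profiles the clustered \linkS4class{TimeProfiles} or matrix.
#' @return the BIC value (also stored when called via
#'   \code{\link{sweepPreferences}}).
#' @export
bicScore <- function(result, profiles) {
    m <- if (is(profiles, "TimeProfiles")) profileMatrix(profiles) else
        as.matrix(profiles)
    assign <- result@assignment
    if (length(assign) != nrow(m))
        stopf("clustering covers %d points but %d profiles were given",
              length(assign), nrow(m))
    n <- nrow(m)
    d <- ncol(m)
    K <- length(result@exemplars)
    if (K >= n)
        return(Inf)
    rss <- sum((m - m[assign, , drop = FALSE])^2)
    sigma2 <- max(rss / (d * (n - K)), 1e-12)
    n * d * log(sigma2) + (K * d + 1) * log(n)
}

#' Sweep the preference and score candidate clusterings
#'
#' Runs affinity propagation over a grid of preference values and fills in
#' each result's BIC. The default grid is \code{nGrid} values log-spaced
#' between the minimum and the median off-diagonal similarity — the range
#' over which the number of exemplars typically grows from few to many.
#'
#' @param profiles \linkS4class{TimeProfiles} or matrix.
#' @param grid explicit preference values; overrides the default grid.
#' @param nGrid size of the default grid (15).
#' @param damping,maxIter,convIter,seed passed to
#'   \code{\link{runAffinityPropagation}}.
#' @param metric passed to \code{\link{buildSimilarity}}.
#' @return list of \linkS4class{ClusterResult}, one per preference value.
#' @export
sweepPreferences <- function(profiles, grid = NULL, nGrid = 15L,
                             damping = 0.9, maxIter = 1000L,
                             convIter = 100L, seed = 1L,
                             metric = "sqeuclidean") {
    S <- buildSimilarity(profiles, preference = 0, metric = metric)
    off <- S[upper.tri(S) | lower.tri(S)]
    if (is.null(grid))
        grid <- preferenceGrid(min(off), stats::median(off), nGrid)
    if (!length(grid))
        stopf("preference grid must be nonempty")
    lapply(grid, function(p) {
        diag(S) <- p
        attr(S, "preference") <- p
        res <- runAffinityPropagation(S, damping = damping,
                                      maxIter = maxIter,
                                      convIter = convIter, seed = seed)
        res@bic <- bicScore(res, profiles)
        res
    })
}

# Log-spaced grid between two nonpositive similarities (linear fallback
# when the upper end is 0, e.g. duplicate profiles).
preferenceGrid <- function(lo, hi, nGrid) {
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    if (hi >= -.Machine$double.eps) {
        if (lo >= -.Machine$double.eps)
            return(rep(0, nGrid))
        hi <- lo * 1e-3
    }
    -exp(seq(log(-lo), log(-hi), length.out = nGrid))
}

#' Select the optimal clustering by BIC
#'
#' Returns the minimum-BIC result from a preference sweep; ties are broken
#' toward the smaller number of clusters, then the smaller preference.
#'
#' @param results list of scored \linkS4class{ClusterResult}.
#' @return the selected \linkS4class{ClusterResult}.
#' @export
selectClustering <- function(results) {
    if (!length(results))
        stopf("no clusterings to select from")
    bic <- vapply(results, function(r) r@bic, numeric(1))
    if (anyNA(bic))
        stopf("all results must carry a BIC; run sweepPreferences or bicScore first")
    K <- vapply(results, function(r) length(r@exemplars), numeric(1))
    pref <- vapply(results, function(r) r@preference, numeric(1))
    results[[order(bic, K, pref)[1L]]]
}
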