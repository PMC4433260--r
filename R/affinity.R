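#' Build the pairwise similarity matrix for affinity propagation
#'
#' Off-diagonal similarities are the negative squared Euclidean distances
#' between temporal profiles (the standard similarity of the
#' exemplar-based message-passing formulation; plain negative distance is
#' available behind \code{metric}). The diagonal carries the preference,
#' which controls how readily points become exemplars; \code{"median"}
#' resolves to the median off-diagonal similarity, the customary default.
#'
#' @param profiles a \linkS4class{TimeProfiles} or a numeric matrix (rows =
#'   profiles).
#' @param preference a real value or \code{"median"}.
#' @param metric \code{"sqeuclidean"} (default) or \code{"euclidean"}.
#' @return symmetric n x n similarity matrix with the preference on its
#'   diagonal and in \code{attr(, "preference")}.
#' @examples
#' buildSimilarity(rbind(c(0, 0), c(3, 4)), preference = -1)[1, 2]  # -25
#' @export
buildSimilarity <- function(profiles, preference = "median",
                            metric = c("sqeuclidean", "euclidean")) {
    metric <- match.arg(metric)
    m <- if (is(profiles, "TimeProfiles")) profileMatrix(profiles) else
        as.matrix(profiles)
    if (nrow(m) < 2L)
        stopf("at least two profiles are required")
    if (!all(is.finite(m)))
        stopf("profiles must be finite and of equal length")
    d2 <- as.matrix(stats::dist(m))^2
    s <- if (metric == "sqeuclidean") -d2 else -sqrt(d2)
    pref <- resolvePreference(s, preference)
    diag(s) <- pref
    attr(s, "preference") <- pref
    s
}

resolvePreference <- function(s, preference) {
    if (identical(preference, "median"))
        stats::median(s[upper.tri(s) | lower.tri(s)])
    else as.numeric(preference)
}

#' Affinity propagation by responsibility/availability message passing
#'
#' Implements the exemplar-based clustering message updates: the
#' responsibility r(i,k) accumulates evidence that k should serve as the
#' exemplar for i, the availability a(i,k) the evidence that i should choose
#' k, iterated with damping until the exemplar set (points with positive
#' self-responsibility plus self-availability) is unchanged for
#' \code{convIter} iterations or \code{maxIter} is reached. A tiny seeded
#' jitter (~1e-12 of the similarity scale) breaks exact ties that would
#' otherwise make the messages oscillate. After convergence each cluster's
#' exemplar is refined to the member maximizing within-cluster similarity
#' and points are assigned to their most similar exemplar.
#'
#' @param S similarity matrix from \code{\link{buildSimilarity}} (diagonal =
#'   preference).
#' @param damping message damping factor in [0.5, 1); default 0.9.
#' @param maxIter maximum iterations (default 1000).
#' @param convIter convergence window (default 100).
#' @param seed integer seed for the tie-breaking jitter.
#' @return a \linkS4class{ClusterResult}; non-convergence yields
#'   \code{converged = FALSE} with a warning, never an error.
#' @export
runAffinityPropagation <- function(S, damping = 0.9, maxIter = 1000L,
                                   convIter = 100L, seed = 1L) {
    S <- as.matrix(S)
    n <- nrow(S)
    if (n != ncol(S))
        stopf("similarity matrix must be square")
    if (damping < 0.5 || damping >= 1)
        stopf("damping must lie in [0.5, 1)")
    pref <- if (!is.null(attr(S, "preference"))) attr(S, "preference") else
        stats::median(diag(S))
    # Degenerate geometry: all off-diagonal similarities equal. Message
    # passing has no gradient to work with (it oscillates around an exact
    # tie), but the optimum is closed-form: every point its own exemplar
    # when the preference exceeds the common similarity, one cluster
    # otherwise (ties resolve to one cluster).
    off <- S[upper.tri(S) | lower.tri(S)]
    if (max(off) - min(off) < 1e-12 * max(abs(S), 1)) {
        ex <- if (pref > off[1L]) seq_len(n) else 1L
        assign <- assignToExemplars(S, ex)
        return(new("ClusterResult", exemplars = as.integer(ex),
                   assignment = assign,
                   netSimilarity = netSimilarityOf(S, assign, pref),
                   bic = NA_real_, preference = pref, converged = TRUE,
                   nIterations = 0L))
    }
    scale <- max(abs(S))
    if (!is.finite(scale) || scale == 0) scale <- 1
    # Tie-breaking jitter ~1e-12 of the similarity scale; the diagonal part
    # is strictly negative so exact ties resolve toward fewer exemplars.
    J <- withSeed(seed, {
        J <- matrix(stats::runif(n * n, -1, 1), n, n)
        diag(J) <- -stats::runif(n, 0.5, 1)
        J
    })
    Sj <- S + J * 1e-12 * scale

    R <- A <- matrix(0, n, n)
    ii <- seq_len(n)
    exPrev <- integer()
    stable <- 0L
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        # responsibilities: r(i,k) = s(i,k) - max_{k' != k} [a(i,k') + s(i,k')]
        AS <- A + Sj
        i1 <- max.col(AS, ties.method = "first")
        m1 <- AS[cbind(ii, i1)]
        AS[cbind(ii, i1)] <- -Inf
        m2 <- AS[cbind(ii, max.col(AS, ties.method = "first"))]
        Rnew <- Sj - m1
        Rnew[cbind(ii, i1)] <- Sj[cbind(ii, i1)] - m2
        R <- damping * R + (1 - damping) * Rnew
        # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' != i,k} max(0, r(i',k)))
        Rp <- pmax(R, 0)
        diag(Rp) <- diag(R)
        cs <- colSums(Rp)
        Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
        dA <- diag(Anew)            # a(k,k) = sum_{i' != k} max(0, r(i',k))
        Anew <- pmin(Anew, 0)
        diag(Anew) <- dA
        A <- damping * A + (1 - damping) * Anew

        ex <- which(diag(A) + diag(R) > 0)
        if (length(ex) && identical(ex, exPrev)) {
            stable <- stable + 1L
            if (stable >= convIter) break
        } else {
            stable <- 0L
            exPrev <- ex
        }
    }
    converged <- stable >= convIter
    if (!converged)
        warnf("affinity propagation did not converge in %d iterations", maxIter)
    ex <- which(diag(A) + diag(R) > 0)
    if (!length(ex))
        ex <- which.max(diag(A) + diag(R))
    ex <- refineExemplars(S, ex)
    assign <- assignToExemplars(S, ex)
    new("ClusterResult", exemplars = as.integer(sort(ex)),
        assignment = assign,
        netSimilarity = netSimilarityOf(S, assign, pref),
        bic = NA_real_, preference = pref, converged = converged,
        nIterations = iter)
}

# Assign every point to its most similar exemplar (self for exemplars).
assignToExemplars <- function(S, ex) {
    ex <- sort(ex)
    assign <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
    assign[ex] <- ex
    as.integer(assign)
}

# One refinement pass: within each current cluster, move the exemplar to
# the member maximizing total within-cluster similarity.
refineExemplars <- function(S, ex) {
    assign <- assignToExemplars(S, ex)
    newEx <- vapply(sort(unique(assign)), function(e) {
        members <- which(assign == e)
        if (length(members) == 1L) return(members)
        Sm <- S[members, members, drop = FALSE]
        diag(Sm) <- 0
        members[which.max(rowSums(Sm))]
    }, integer(1))
    sort(unique(newEx))
}

netSimilarityOf <- function(S, assign, pref) {
    ex <- sort(unique(assign))
    nonEx <- setdiff(seq_along(assign), ex)
    sum(S[cbind(nonEx, assign[nonEx])]) + length(ex) * pref
}

#' Exhaustive exemplar-set oracle
#'
#' Brute-force reference for affinity propagation on tiny instances:
#' enumerates every non-empty exemplar subset, assigns each point to its
#' best exemplar, and returns the subset maximizing net similarity (sum of
#' similarities to exemplars plus one preference per exemplar). Ties are
#' broken toward the lexicographically smallest exemplar set. Refuses
#' instances with more than 12 points.
#'
#' @param S similarity matrix with the preference on its diagonal.
#' @return a \linkS4class{ClusterResult} with the optimal net similarity.
#' @export
exhaustiveExemplarOracle <- function(S) {
    S <- as.matrix(S)
    n <- nrow(S)
    if (n > 12L)
        stopf("exhaustive oracle refuses n > 12 (got %d)", n)
    pref <- if (!is.null(attr(S, "preference"))) attr(S, "preference") else
        stats::median(diag(S))
    Soff <- S
    diag(Soff) <- 0
    best <- -Inf
    bestEx <- integer()
    for (mask in seq_len(2^n - 1L)) {
        ex <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
        sc <- length(ex) * pref
        if (length(ex) < n)
            sc <- sc + sum(apply(Soff[-ex, ex, drop = FALSE], 1L, max))
        if (sc > best + 1e-12 ||
            (abs(sc - best) <= 1e-12 && lexLess(ex, bestEx))) {
            best <- sc
            bestEx <- ex
        }
    }
    assign <- assignToExemplars(S, bestEx)
    new("ClusterResult", exemplars = as.integer(bestEx), assignment = assign,
        netSimilarity = best, bic = NA_real_, preference = pref,
        converged = TRUE, nIterations = 0L)
}

lexLess <- function(a, b) {
    if (!length(b)) return(TRUE)
    for (i in seq_len(min(length(a), length(b)))) {
        if (a[i] < b[i]) return(TRUE)
        if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
}

#' @rdname ClusterResult-accessors
#' @export
setMethod("exemplars", "ClusterResult", function(x) x@exemplars)

#' @rdname ClusterResult-accessors
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x)
    match(x@assignment, x@exemplars))

#' @rdname ClusterResult-accessors
#' @export
setMethod("nClusters", "ClusterResult", function(x) length(x@exemplars))

#' @rdname ClusterResult-accessors
#' @export
setMethod("netSimilarity", "ClusterResult", function(x) x@netSimilarity)

#' @rdname ClusterResult-accessors
#' @export
setMethod("clusterBIC", "ClusterResult", function(x) x@bic)

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult: K =", length(object@exemplars), "exemplars;",
        "net similarity =", format(object@netSimilarity, digits = 6), "\n")
    cat(sprintf("  preference = %.6g, BIC = %s, converged = %s (%d iterations)\n",
                object@preference,
                if (is.na(object@bic)) "unscored" else
                    format(object@bic, digits = 6),
                object@converged, object@nIterations))
})

#' Accessors for ClusterResult
#'
#' \code{exemplars} returns exemplar indices; \code{clusterAssignments} a
#' cluster id (1..K) per point; \code{nClusters} K; \code{netSimilarity} the
#' net similarity; \code{clusterBIC} the BIC (NA until scored).
#'
#' @param x a \linkS4class{ClusterResult}.
#' @name ClusterResult-accessors
#' @aliases exemplars clusterAssignments nClusters netSimilarity clusterBIC
NULL
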