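test_that("similarity matrix encodes negative squared Euclidean distance", {
    expect_equal(buildSimilarity(rbind(c(0, 0), c(3, 4)),
                                 preference = -1)[1, 2], -25)  # 3-4-5
    m <- rbind(c(1, 2, 3), c(1, 2, 3))
    expect_equal(buildSimilarity(m, preference = -1)[1, 2], 0)
    # symmetry against an explicit pairwise loop
    set.seed(31)
    m <- matrix(rnorm(6 * 4), 6, 4)
    S <- buildSimilarity(m, "median")
    for (i in 1:6) for (k in 1:6) {
        if (i == k) next
        expect_equal(S[i, k], -sum((m[i, ] - m[k, ])^2))
        expect_equal(S[i, k], S[k, i])
    }
    expect_equal(unname(diag(S)), rep(attr(S, "preference"), 6))
    expect_equal(attr(S, "preference"),
                 median(S[upper.tri(S) | lower.tri(S)]))
    expect_error(buildSimilarity(matrix(1, 1, 4)), "two profiles")
})

test_that("degenerate and limiting geometries resolve as they must", {
    # identical points, median preference -> one cluster
    r <- runAffinityPropagation(buildSimilarity(matrix(1, 6, 4), "median"),
                                seed = 1)
    expect_equal(nClusters(r), 1L)
    # preference at the maximum similarity -> every point its own exemplar
    set.seed(7)
    S <- buildSimilarity(matrix(rnorm(20), 5, 4), preference = 0)
    r <- runAffinityPropagation(S, seed = 1)
    expect_equal(nClusters(r), 5L)
    expect_identical(clusterAssignments(r), 1:5)
})

test_that("well-separated 1-D pairs match the exhaustive oracle", {
    m <- matrix(rep(c(0, 0.1, 10, 10.1), 4), 4, 4)
    S <- buildSimilarity(m, "median")
    r <- runAffinityPropagation(S, seed = 1)
    o <- exhaustiveExemplarOracle(S)
    expect_equal(nClusters(r), 2L)
    expect_identical(clusterAssignments(r), c(1L, 1L, 2L, 2L))
    expect_equal(netSimilarity(r), netSimilarity(o), tolerance = 1e-9)
})

test_that("the exhaustive oracle handles its boundary cases", {
    # n = 1 inside a 2-point matrix is impossible; test n = 2 identical
    S <- matrix(0, 2, 2)
    diag(S) <- -1           # preference < 0
    o <- exhaustiveExemplarOracle(S)
    expect_equal(length(exemplars(o)), 1L)  # one exemplar beats paying two
    expect_equal(netSimilarity(o), -1)
    expect_error(exhaustiveExemplarOracle(matrix(0, 13, 13)), "n > 12")
})

test_that("AP never beats the oracle and usually matches it", {
    matched <- 0L
    for (s in 1:20) {
        inst <- separatedInstance(s)
        S <- buildSimilarity(inst$points, "median")
        a <- suppressWarnings(runAffinityPropagation(S, seed = s))
        o <- exhaustiveExemplarOracle(S)
        expect_lte(netSimilarity(a), netSimilarity(o) + 1e-9)
        if (abs(netSimilarity(a) - netSimilarity(o)) < 1e-9)
            matched <- matched + 1L
    }
    expect_gte(matched, 19L)
})

test_that("every result satisfies the exemplar/assignment invariants", {
    for (s in c(2, 13)) {
        set.seed(s)
        m <- matrix(rnorm(12 * 4), 12, 4)
        r <- suppressWarnings(
            runAffinityPropagation(buildSimilarity(m, "median"), seed = s))
        expect_true(all(r@assignment %in% r@exemplars))
        expect_true(all(r@assignment[r@exemplars] == r@exemplars))
        expect_equal(length(r@assignment), 12L)
        expect_gte(nClusters(r), 1L)
        # determinism: identical input and seed -> identical exemplars
        r2 <- suppressWarnings(
            runAffinityPropagation(buildSimilarity(m, "median"), seed = s))
        expect_identical(exemplars(r2), exemplars(r))
    }
})

test_that("BIC matches hand arithmetic and penalizes overfitting", {
    # 4 points, K = 2, exemplars at rows 1 and 3
    m <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
    res <- new("ClusterResult", exemplars = c(1L, 3L),
               assignment = c(1L, 1L, 3L, 3L), netSimilarity = -2,
               bic = NA_real_, preference = -8, converged = TRUE,
               nIterations = 0L)
    rss <- 1 + 1                       # each satellite 1 away
    sigma2 <- rss / (2 * (4 - 2))      # residual df: d * (n - K)
    expect_equal(bicScore(res, m),
                 4 * 2 * log(sigma2) + (2 * 2 + 1) * log(4),
                 tolerance = 1e-9)
    # K = n on noisy data scores worse than the truth-K clustering
    sim <- generateDataset(syntheticConfig(n_sites = 40L, seed = 21L))
    pr <- toLog2Profiles(normalizeChannels(sim$table), quiet = TRUE)
    sel <- selectClustering(suppressWarnings(
        sweepPreferences(pr, nGrid = 8L, seed = 21L)))
    n <- nrow(profileMatrix(pr))
    kn <- new("ClusterResult", exemplars = seq_len(n),
              assignment = seq_len(n), netSimilarity = 0, bic = NA_real_,
              preference = 0, converged = TRUE, nIterations = 0L)
    expect_gt(bicScore(kn, pr), clusterBIC(sel))
    # single tight blob: K = 1 beats K = n
    set.seed(3)
    blob <- matrix(rnorm(20 * 4, sd = 0.05), 20, 4)
    one <- new("ClusterResult", exemplars = 1L,
               assignment = rep(1L, 20), netSimilarity = 0, bic = NA_real_,
               preference = 0, converged = TRUE, nIterations = 0L)
    all20 <- new("ClusterResult", exemplars = 1:20,
                 assignment = 1:20, netSimilarity = 0, bic = NA_real_,
                 preference = 0, converged = TRUE, nIterations = 0L)
    expect_lt(bicScore(one, blob), bicScore(all20, blob))
})

test_that("preference sweep produces scored results with sensible K trend", {
    sim <- generateDataset(syntheticConfig(n_sites = 30L, seed = 17L))
    pr <- toLog2Profiles(normalizeChannels(sim$table), quiet = TRUE)
    # single-value grid
    one <- sweepPreferences(pr, grid = -5, seed = 1L)
    expect_length(one, 1L)
    expect_false(is.na(clusterBIC(one[[1]])))
    # K non-decreasing across the default grid (statistical property;
    # occasional single-step violations from non-convergence tolerated)
    sw <- suppressWarnings(sweepPreferences(pr, nGrid = 10L, seed = 17L))
    Ks <- vapply(sw, nClusters, integer(1))
    expect_lte(sum(diff(Ks) < 0), 1L)
    expect_gte(Ks[length(Ks)], Ks[1])
    # all-identical data: K = 1 at every grid point
    same <- matrix(1, 8, 4)
    swSame <- sweepPreferences(same, grid = c(-3, -1, -0.1), seed = 1L)
    expect_identical(vapply(swSame, nClusters, integer(1)), rep(1L, 3))
})

test_that("BIC selection takes the minimum with smallest-K tie-breaks", {
    mk <- function(bic, K, pref) {
        new("ClusterResult", exemplars = seq_len(K),
            assignment = c(seq_len(K), rep(1L, 10L - K)),
            netSimilarity = 0, bic = bic, preference = pref,
            converged = TRUE, nIterations = 0L)
    }
    a <- mk(10, 3L, -5)
    b <- mk(10, 5L, -2)
    c3 <- mk(12, 2L, -9)
    expect_identical(selectClustering(list(c3)), c3)     # list of one
    sel <- selectClustering(list(b, a, c3))
    expect_equal(nClusters(sel), 3L)                     # tie -> smaller K
    expect_error(selectClustering(list()), "no clusterings")
})
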