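test_that("FCR values and categories follow the threshold table exactly", {
    expect_equal(computeFCR(2, 2)$fcr, 1)
    expect_equal(as.character(computeFCR(2, 2)$category), "unchanged")
    expect_equal(as.character(computeFCR(1, 0.25)$category),
                 "strongly_attenuated")                 # fcr = 0.25 < 0.3
    r <- computeFCR(2.0, 1.0)                           # fcr = 0.5
    expect_equal(r$fcr, 0.5)
    expect_equal(as.character(r$category), "attenuated")
    # boundary sides: strong classes open, +/-50% screen closed
    fcr <- c(0.3 - 1e-9, 0.3, 0.5, 0.5 + 1e-9, 1.5 - 1e-9, 1.5, 1.9,
             1.9 + 1e-9)
    got <- as.character(computeFCR(rep(1, 8), fcr)$category)
    expect_identical(got, c("strongly_attenuated", "attenuated",
                            "attenuated", "unchanged", "unchanged",
                            "amplified", "amplified", "strongly_amplified"))
    expect_error(computeFCR(1, -2, site = "EGFR-Y1068"), "EGFR-Y1068")
})

test_that("swapping vehicle and treated inverts the FCR", {
    set.seed(5)
    fv <- runif(50, 0.2, 4)
    ft <- runif(50, 0.2, 4)
    a <- computeFCR(fv, ft)
    b <- computeFCR(ft, fv)
    expect_equal(b$fcr, 1 / a$fcr, tolerance = 1e-12)
    expect_equal(computeFCR(fv, ft, invert = TRUE)$fcr, b$fcr)
    # the strong-attenuation class inverts into strong amplification
    # (1/0.3 > 1.9), and a <=0.5 fold attenuation inverts into the screen
    sa <- a$category == "strongly_attenuated"
    expect_true(all(b$category[sa] == "strongly_amplified"))
    expect_true(all(b$category[a$fcr <= 0.5] != "unchanged"))
})

test_that("fractionFCRAltered counts every non-unchanged category", {
    recs <- computeFCR(rep(1, 5), c(1, 0.2, 0.5, 1.5, 2.5))
    expect_equal(fractionFCRAltered(recs), 0.8)
    expect_equal(fractionFCRAltered(computeFCR(c(1, 2), c(1, 2))), 0)
    expect_error(fractionFCRAltered(data.frame()), "nonempty")
})

test_that("early-response classes use the paper-faithful boundaries", {
    # at least two-fold decrease: boundary inclusive
    expect_equal(as.character(classifyEarlyResponse(-1)), "decreased_2fold")
    # more than 1.5-fold increase: strict
    expect_equal(as.character(classifyEarlyResponse(log2(1.5))),
                 "unclassified")
    expect_equal(as.character(classifyEarlyResponse(log2(1.5) + 1e-9)),
                 "increased_1p5fold")
    expect_equal(as.character(classifyEarlyResponse(0)), "unclassified")
    pr <- toLog2Profiles(toyTable(matrix(
        c(8, 2, 8, 8,
          8, 16, 8, 8), 2, 4, byrow = TRUE,
        dimnames = list(NULL, paste0("ch", 1:4)))), quiet = TRUE)
    expect_identical(as.character(classifyEarlyResponse(pr)),
                     c("decreased_2fold", "increased_1p5fold"))
    noOne <- new("TimeProfiles",
                 profiles = matrix(0, 1, 2), timepoints = c(0, 5),
                 siteData = S4Vectors::DataFrame(site_key = "x"))
    expect_error(classifyEarlyResponse(noOne), "1-min")
})

test_that("Welch t statistic matches explicit textbook arithmetic", {
    a <- c(1.1, 1.9, 1.3)
    b <- c(2.6, 3.4, 3.1)
    got <- siteTTest(a, b)
    # independent Welch arithmetic
    se <- sqrt(var(a) / 3 + var(b) / 3)
    tstat <- (mean(a) - mean(b)) / se
    df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
    expect_equal(got$statistic, tstat, tolerance = 1e-9)
    expect_equal(got$df, df, tolerance = 1e-9)
    expect_equal(got$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-9)
    # identical groups
    same <- siteTTest(c(1, 1, 2), c(1, 2, 1))
    expect_equal(same$p_value, 1)
    # degenerate zero variance
    expect_equal(siteTTest(c(1, 1), c(1, 1))$p_value, 1)
    expect_warning(z <- siteTTest(c(1, 1), c(2, 2)), "degenerate")
    expect_equal(z$p_value, 0)
    expect_error(siteTTest(1, c(1, 2)), "two replicate")
})

test_that("tests are invariant under addition of a constant", {
    set.seed(9)
    a <- rnorm(4); b <- rnorm(4) + 0.5
    g <- list(rnorm(4), rnorm(4), rnorm(4) + 1)
    expect_equal(siteTTest(a + 3, b + 3)$p_value,
                 siteTTest(a, b)$p_value, tolerance = 1e-12)
    expect_equal(siteANOVA(lapply(g, `+`, 3))$p_value,
                 siteANOVA(g)$p_value, tolerance = 1e-12)
})

test_that("one-way ANOVA reduces to the pooled t-test for two groups", {
    set.seed(11)
    a <- rnorm(5); b <- rnorm(5) + 0.4
    pAnova <- siteANOVA(list(a, b))
    pT <- siteTTest(a, b, varEqual = TRUE)
    expect_equal(pAnova$p_value, pT$p_value, tolerance = 1e-9)
    expect_equal(pAnova$statistic, pT$statistic^2, tolerance = 1e-9)
    # all groups identical
    g <- siteANOVA(list(c(1, 2), c(1, 2), c(1, 2)))
    expect_equal(g$statistic, 0)
    expect_equal(g$p_value, 1)
    expect_error(siteANOVA(list(c(1, 2))), "two groups")
})

test_that("BH adjustment matches step-up arithmetic", {
    expect_equal(adjustPvalues(0.03), 0.03)
    expect_equal(adjustPvalues(rep(0.02, 5)), rep(0.02, 5))
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    p <- c(0.001, 0.008, 0.039, 0.041, 0.27)
    adj <- adjustPvalues(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))
    expect_error(adjustPvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted FCR effects are detected with high sensitivity", {
    sens <- vapply(1:10, function(s) {
        sim <- generateTSAExperiment(syntheticConfig(
            n_sites = 150L, fcr_altered_fraction = 0.1,
            noise_sd_log2 = 0.1, seed = s))
        res <- suppressWarnings(crosstalkAnalysis(sim$table))
        tr <- sim$truth[match(res$tests$site, sim$truth$site_key), ]
        mean(res$tests$significant_raw[tr$altered])
    }, numeric(1))
    expect_gte(median(sens), 0.8)
})
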