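.FCR_LEVELS <- c("strongly_attenuated", "attenuated", "unchanged",
                 "amplified", "strongly_amplified")

#' Fold-change ratio (FCR) between pretreated and vehicle responses
#'
#' The FCR quantifies how a deacetylase-inhibitor pretreatment reshapes the
#' ligand-induced response at a site: the ratio of the EGF-induced fold
#' change under TSA pretreatment to that under vehicle,
#' \code{fcr = fc_tsa / fc_vehicle}. Categories follow the screen
#' thresholds: \code{fcr < 0.3} strongly attenuated; \code{[0.3, 0.5]}
#' attenuated; \code{(0.5, 1.5)} unchanged; \code{[1.5, 1.9]} amplified;
#' \code{> 1.9} strongly amplified. "Altered by at least fifty percent"
#' corresponds to any category other than unchanged, i.e. \code{fcr <= 0.5}
#' or \code{fcr >= 1.5}.
#'
#' @param fc_vehicle,fc_tsa positive linear fold changes (5-min stimulated
#'   over unstimulated), vectorized.
#' @param site optional site labels for error messages and output.
#' @param thresholds named numeric \code{c(strong_low, low, high,
#'   strong_high)}; must satisfy 0 < strong_low < low < 1 < high <
#'   strong_high.
#' @param invert set \code{TRUE} to use the vehicle-over-TSA convention.
#' @return data.frame with \code{site}, \code{fc_vehicle}, \code{fc_tsa},
#'   \code{fcr}, \code{category} (factor over the five categories).
#' @examples
#' computeFCR(2.0, 1.0)  # fcr = 0.5, attenuated
#' @export
computeFCR <- function(fc_vehicle, fc_tsa, site = NULL,
                       thresholds = c(strong_low = 0.3, low = 0.5,
                                      high = 1.5, strong_high = 1.9),
                       invert = FALSE) {
    if (length(fc_vehicle) != length(fc_tsa))
        stopf("fc_vehicle and fc_tsa must have equal length")
    if (is.null(site))
        site <- as.character(seq_along(fc_vehicle))
    checkThresholds(thresholds)
    bad <- which(!is.finite(fc_vehicle) | !is.finite(fc_tsa) |
                 fc_vehicle <= 0 | fc_tsa <= 0)
    if (length(bad))
        stopf("nonpositive fold change for site(s): %s",
              paste(site[bad], collapse = ", "))
    fcr <- if (invert) fc_vehicle / fc_tsa else fc_tsa / fc_vehicle
    data.frame(site = site, fc_vehicle = fc_vehicle, fc_tsa = fc_tsa,
               fcr = fcr, category = fcrCategory(fcr, thresholds))
}

checkThresholds <- function(th) {
    need <- c("strong_low", "low", "high", "strong_high")
    if (!all(need %in% names(th)))
        stopf("thresholds must be named %s", paste(need, collapse = ", "))
    th <- th[need]
    if (!(0 < th[1] && th[1] < th[2] && th[2] < 1 && 1 < th[3] &&
          th[3] < th[4]))
        stopf("thresholds must satisfy 0 < strong_low < low < 1 < high < strong_high")
    invisible(th)
}

# Boundary sides follow the screen wording: the strong classes are open
# (< 0.3, > 1.9); "at least fifty percent" closes 0.5 and 1.5 into the
# altered classes.
fcrCategory <- function(fcr, thresholds = c(strong_low = 0.3, low = 0.5,
                                            high = 1.5, strong_high = 1.9)) {
    th <- checkThresholds(thresholds)
    out <- ifelse(fcr < th["strong_low"], "strongly_attenuated",
           ifelse(fcr <= th["low"], "attenuated",
           ifelse(fcr < th["high"], "unchanged",
           ifelse(fcr <= th["strong_high"], "amplified",
                  "strongly_amplified"))))
    factor(out, levels = .FCR_LEVELS)
}

#' Fraction of sites with an altered fold-change ratio
#'
#' Fraction of FCR records whose ligand response was decreased or increased
#' by at least fifty percent by the pretreatment (category other than
#' unchanged; equivalently \code{fcr <= 0.5} or \code{fcr >= 1.5}).
#'
#' @param records data.frame from \code{\link{computeFCR}}.
#' @return fraction in [0, 1].
#' @export
fractionFCRAltered <- function(records) {
    if (is.null(records$category) || !nrow(records))
        stopf("records must be a nonempty computeFCR() result")
    mean(records$category != "unchanged")
}

#' Classify the early (1-minute) response of a temporal profile
#'
#' Labels each profile by its value at the 1-minute timepoint:
#' \code{decreased_2fold} when reduced by at least two-fold (ratio <= 0.5,
#' boundary inclusive), \code{increased_1p5fold} when increased by more
#' than 1.5-fold (ratio > 1.5, strict), otherwise \code{unclassified}.
#'
#' @param profiles a \linkS4class{TimeProfiles}, or a numeric vector of
#'   1-minute log2 fold changes.
#' @param timepoint the early timepoint in minutes (default 1).
#' @return factor of labels, one per profile.
#' @export
classifyEarlyResponse <- function(profiles, timepoint = 1) {
    v <- if (is(profiles, "TimeProfiles")) {
        tp <- profileTimepoints(profiles)
        if (!timepoint %in% tp)
            stopf("profiles lack the %g-min timepoint", timepoint)
        profileMatrix(profiles)[, match(timepoint, tp)]
    } else as.numeric(profiles)
    lab <- ifelse(v <= -1, "decreased_2fold",
           ifelse(v > log2(1.5), "increased_1p5fold", "unclassified"))
    factor(lab, levels = c("decreased_2fold", "increased_1p5fold",
                           "unclassified"))
}

#' Per-site two-sample t-test
#'
#' Two-sided t-test comparing replicate measurements of one site between
#' two conditions, on the log2 scale; unequal-variance (Welch) by default,
#' pooled-variance behind \code{varEqual}. Zero within-group variance in
#' both groups yields p = 1 for equal means, and p ~ 0 with a
#' degenerate-variance warning for unequal means.
#'
#' @param values_a,values_b numeric vectors of log2 replicate measurements,
#'   length >= 2 each.
#' @param varEqual pool the variance (classic t-test) instead of Welch.
#' @param alpha significance level for the raw flag (default 0.05).
#' @return one-row data.frame: \code{statistic}, \code{df}, \code{p_value},
#'   \code{significant_raw}.
#' @export
siteTTest <- function(values_a, values_b, varEqual = FALSE, alpha = 0.05) {
    if (length(values_a) < 2L || length(values_b) < 2L)
        stopf("at least two replicate values per group are required")
    sc <- max(abs(c(values_a, values_b)), 1)
    degen <- sqrt(stats::var(values_a)) <= 1e-10 * sc &&
        sqrt(stats::var(values_b)) <= 1e-10 * sc
    if (degen) {
        if (abs(mean(values_a) - mean(values_b)) <= 1e-8 * sc) {
            stat <- 0; p <- 1; df <- length(values_a) + length(values_b) - 2L
        } else {
            warnf("degenerate zero within-group variance with unequal means")
            stat <- sign(mean(values_a) - mean(values_b)) * Inf
            p <- 0; df <- NA_real_
        }
    } else {
        ht <- stats::t.test(values_a, values_b, var.equal = varEqual)
        stat <- unname(ht$statistic)
        df <- unname(ht$parameter)
        p <- ht$p.value
    }
    data.frame(statistic = stat, df = df, p_value = p,
               significant_raw = p < alpha)
}

#' Per-site one-way ANOVA across timepoints
#'
#' Classic (pooled-variance) one-way ANOVA of log2 replicate measurements
#' across groups (e.g. timepoints). With two groups its p-value equals the
#' pooled-variance t-test's (F = t^2). Degenerate cases are handled as in
#' \code{\link{siteTTest}}.
#'
#' @param groups list of numeric vectors, one per group; >= 2 groups with
#'   >= 2 values each.
#' @param alpha significance level for the raw flag.
#' @return one-row data.frame: \code{statistic} (F), \code{df1}, \code{df2},
#'   \code{p_value}, \code{significant_raw}.
#' @export
siteANOVA <- function(groups, alpha = 0.05) {
    if (length(groups) < 2L || any(lengths(groups) < 2L))
        stopf("at least two groups with two replicate values each are required")
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    df1 <- nlevels(g) - 1L
    df2 <- length(y) - nlevels(g)
    sc <- max(abs(y), 1)
    withinVar <- vapply(groups, stats::var, numeric(1))
    if (all(sqrt(withinVar) <= 1e-10 * sc)) {
        means <- vapply(groups, mean, numeric(1))
        if (max(means) - min(means) <= 1e-8 * sc) {
            stat <- 0; p <- 1
        } else {
            warnf("degenerate zero within-group variance with unequal means")
            stat <- Inf; p <- 0
        }
    } else {
        ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
        stat <- unname(ht$statistic)
        p <- ht$p.value
    }
    data.frame(statistic = stat, df1 = df1, df2 = df2, p_value = p,
               significant_raw = p < alpha)
}

#' Benjamini-Hochberg adjustment of per-site p-values
#'
#' Step-up false-discovery-rate adjustment; adjusted values are monotone
#' and never below the raw p-values. Provided as a documented extension of
#' the raw p < 0.05 screen, never silently substituted for it.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values, same length.
#' @export
adjustPvalues <- function(p_values) {
    if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
        stopf("p-values must lie in [0, 1]")
    stats::p.adjust(p_values, method = "BH")
}

#' Per-site vehicle/TSA fold changes and tests from a paired table
#'
#' Convenience wrapper over a paired-design \linkS4class{ReporterTable}
#' (two conditions, timepoints 0 and a stimulated timepoint, replicates):
#' computes per-site linear fold changes per condition (replicate-mean of
#' stimulated/reference ratios), their FCR and category, and a per-site
#' t-test of the log2 stimulated-response between the two conditions across
#' replicates.
#'
#' @param table a paired \linkS4class{ReporterTable}.
#' @param vehicle,treated condition labels (defaults \code{"vehicle"},
#'   \code{"TSA"}).
#' @param timepoint stimulated timepoint in minutes (default 5).
#' @param alpha raw significance level.
#' @param thresholds,invert passed to \code{\link{computeFCR}}.
#' @return list with \code{fcr} (data.frame from \code{computeFCR}) and
#'   \code{tests} (data.frame with per-site t statistics, raw and
#'   BH-adjusted p-values).
#' @export
crosstalkAnalysis <- function(table, vehicle = "vehicle", treated = "TSA",
                              timepoint = 5, alpha = 0.05,
                              thresholds = c(strong_low = 0.3, low = 0.5,
                                             high = 1.5, strong_high = 1.9),
                              invert = FALSE) {
    cd <- colData(table)
    for (cond in c(vehicle, treated))
        if (!cond %in% cd$condition)
            stopf("condition '%s' not present in the channel map", cond)
    ratioOf <- function(cond) {
        sel <- cd$condition == cond
        reps <- unique(cd$replicate[sel])
        r <- vapply(reps, function(rr) {
            ref <- cd$channel[sel & cd$replicate == rr & cd$is_reference]
            stim <- cd$channel[sel & cd$replicate == rr &
                               cd$timepoint_min == timepoint]
            intensityMatrix(table)[, stim] / intensityMatrix(table)[, ref]
        }, numeric(nrow(table)))
        if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
        r
    }
    rv <- ratioOf(vehicle)
    rt <- ratioOf(treated)
    keep <- apply(is.finite(rv) & rv > 0, 1L, all) &
        apply(is.finite(rt) & rt > 0, 1L, all)
    keys <- siteKeys(table)
    fcr <- computeFCR(rowMeans(rv[keep, , drop = FALSE]),
                      rowMeans(rt[keep, , drop = FALSE]),
                      site = keys[keep], thresholds = thresholds,
                      invert = invert)
    tests <- NULL
    if (ncol(rv) >= 2L && ncol(rt) >= 2L) {
        tests <- do.call(rbind, lapply(which(keep), function(i)
            siteTTest(log2(rv[i, ]), log2(rt[i, ]), alpha = alpha)))
        tests <- cbind(site = keys[keep], tests)
        tests$p_adjusted <- adjustPvalues(tests$p_value)
    }
    list(fcr = fcr, tests = tests)
}
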