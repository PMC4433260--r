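#' Per-channel mean ratios to the reference channel
#'
#' For each channel, the mean over peptide rows of
#' intensity(channel) / intensity(reference channel of the same
#' (condition, replicate) block), computed on rows with a present, positive
#' value in both channels. This is the loading-correction statistic of
#' reporter-ion quantification: under the assumption that most peptides do
#' not change, departures of the mean ratio from 1 measure per-channel
#' loading bias.
#'
#' @param table a \linkS4class{ReporterTable}.
#' @param method \code{"mean"} (arithmetic mean of per-row ratios; default),
#'   \code{"median"}, or \code{"logmean"} (geometric mean).
#' @return named numeric vector, one ratio per channel; reference channels
#'   are exactly 1.
#' @export
computeChannelRatios <- function(table, method = c("mean", "median",
                                                   "logmean")) {
    method <- match.arg(method)
    cd <- colData(table)
    x <- intensityMatrix(table)
    refs <- referenceChannels(table)
    blocks <- blockId(cd)
    out <- numeric(ncol(x))
    names(out) <- cd$channel
    for (j in seq_len(ncol(x))) {
        refCol <- refs[[blocks[j]]]
        num <- x[, j]
        den <- x[, refCol]
        ok <- !is.na(num) & !is.na(den) & den > 0 & num >= 0
        if (!any(ok))
            stopf("cannot normalize: channel '%s' has no row complete with its reference",
                  cd$channel[j])
        r <- num[ok] / den[ok]
        out[j] <- switch(method,
                         mean = mean(r),
                         median = stats::median(r),
                         logmean = exp(mean(log(r[r > 0]))))
    }
    out
}

#' Normalize channels by their mean ratios
#'
#' Divides each channel by its loading ratio (from
#' \code{\link{computeChannelRatios}}); after normalization the recomputed
#' mean ratios are all 1 to within 1e-9, and the operation is idempotent.
#'
#' @param table a \linkS4class{ReporterTable}.
#' @param ratios named per-channel ratios; computed from \code{table} when
#'   omitted.
#' @param method passed to \code{\link{computeChannelRatios}} when
#'   \code{ratios} is missing.
#' @return the normalized \linkS4class{ReporterTable}.
#' @export
normalizeChannels <- function(table, ratios = NULL,
                              method = c("mean", "median", "logmean")) {
    if (is.null(ratios))
        ratios <- computeChannelRatios(table, match.arg(method))
    cd <- colData(table)
    if (is.null(names(ratios)))
        names(ratios) <- cd$channel
    if (any(!is.finite(ratios)) || any(ratios <= 0))
        stopf("channel ratios must be positive and finite")
    x <- intensityMatrix(table)
    x <- sweep(x, 2L, ratios[colnames(x)], "/")
    assay(table, "intensity") <- x
    table
}

#' Convert a reporter table to temporal log2 fold-change profiles
#'
#' Within each (condition, replicate) block, per-site intensity ratios to
#' the block's reference channel are formed; ratios are then pooled across
#' replicates (mean in linear space by default) and log2-transformed. The
#' reference timepoint is exactly 0 in every profile. Sites with a missing
#' channel or a nonpositive reference intensity in any replicate of a
#' condition are dropped from that condition's profiles and logged.
#'
#' @param table a (normalized) \linkS4class{ReporterTable}.
#' @param pool replicate pooling: \code{"mean"} (default) or \code{"median"}.
#' @param quiet suppress drop logging.
#' @return a \linkS4class{TimeProfiles}; dropped sites are recorded in
#'   \code{attr(, "dropped")} as a data.frame (site_key, condition, reason).
#' @export
toLog2Profiles <- function(table, pool = c("mean", "median"), quiet = FALSE) {
    pool <- match.arg(pool)
    cd <- colData(table)
    x <- intensityMatrix(table)
    keys <- siteKeys(table)
    conds <- unique(cd$condition)
    tp <- sort(unique(cd$timepoint_min))
    poolFun <- if (pool == "mean") rowMeans else
        function(m) apply(m, 1L, stats::median)

    profRows <- list()
    annRows <- list()
    dropped <- data.frame(site_key = character(), condition = character(),
                          reason = character())
    for (cond in conds) {
        sel <- cd$condition == cond
        ctp <- sort(unique(cd$timepoint_min[sel]))
        reps <- unique(cd$replicate[sel])
        # ratio array: sites x timepoints x replicates
        ratios <- array(NA_real_, c(nrow(x), length(ctp), length(reps)))
        badRef <- badMiss <- rep(FALSE, nrow(x))
        for (ri in seq_along(reps)) {
            b <- sel & cd$replicate == reps[ri]
            refCol <- cd$channel[b & cd$is_reference]
            ref <- x[, refCol]
            badRef <- badRef | is.na(ref) | ref <= 0
            for (ti in seq_along(ctp)) {
                col <- cd$channel[b & cd$timepoint_min == ctp[ti]]
                v <- x[, col]
                badMiss <- badMiss | is.na(v)
                ratios[, ti, ri] <- v / ref
            }
        }
        keep <- !(badRef | badMiss)
        if (!all(keep)) {
            reason <- ifelse(badRef[!keep], "missing or nonpositive reference",
                             "missing channel intensity")
            dropped <- rbind(dropped,
                             data.frame(site_key = keys[!keep],
                                        condition = cond, reason = reason))
        }
        if (!any(keep)) next
        pooled <- apply(ratios[keep, , , drop = FALSE], c(1L, 2L),
                        if (pool == "mean") mean else stats::median)
        prof <- log2(pooled)
        prof[, ctp == min(ctp)] <- 0  # exact anchoring (ratio is exactly 1)
        profRows[[cond]] <- prof
        annRows[[cond]] <- cbind(as.data.frame(siteData(table))[keep, ,
                                                                drop = FALSE],
                                 condition = cond)
    }
    if (!quiet && nrow(dropped))
        message(sprintf("toLog2Profiles: dropped %d site/condition row(s) (%s)",
                        nrow(dropped),
                        paste(unique(dropped$reason), collapse = "; ")))
    prof <- do.call(rbind, profRows)
    ann <- do.call(rbind, annRows)
    if (is.null(prof))
        prof <- matrix(numeric(), 0L, length(tp))
    rownames(prof) <- NULL
    out <- new("TimeProfiles", profiles = prof, timepoints = tp,
               siteData = if (is.null(ann)) DataFrame() else
                   DataFrame(ann, row.names = NULL))
    attr(out, "dropped") <- dropped
    out
}

#' SILAC stimulated/unstimulated fold change
#'
#' Heavy (stimulated) over light (unstimulated) intensity ratio, as a linear
#' fold change with its log2.
#'
#' @param heavy,light positive intensities (vectorized).
#' @return data.frame with \code{fold_change} and \code{log2_fold_change}.
#' @examples
#' silacFoldChange(5e6, 1e6)  # five-fold induction
#' @export
silacFoldChange <- function(heavy, light) {
    if (length(heavy) != length(light))
        stopf("heavy and light must have equal length")
    if (any(!is.finite(heavy)) || any(!is.finite(light)) ||
        any(heavy <= 0) || any(light <= 0))
        stopf("SILAC intensities must be positive and finite")
    fc <- heavy / light
    data.frame(fold_change = fc, log2_fold_change = log2(fc))
}

#' @rdname TimeProfiles-accessors
#' @export
setMethod("profileMatrix", "TimeProfiles", function(x) x@profiles)

#' @rdname TimeProfiles-accessors
#' @export
setMethod("profileTimepoints", "TimeProfiles", function(x) x@timepoints)

#' @rdname ReporterTable-accessors
#' @export
setMethod("siteData", "TimeProfiles", function(x) x@siteData)

setMethod("show", "TimeProfiles", function(object) {
    cat("TimeProfiles:", nrow(object@profiles), "profiles over timepoints {",
        paste(object@timepoints, collapse = ", "), "} min\n")
})

#' Accessors for TimeProfiles
#'
#' \code{profileMatrix} returns the log2 fold-change matrix (rows =
#' site/condition, columns = timepoints); \code{profileTimepoints} the
#' ordered timepoints in minutes; \code{siteData} the row annotation.
#'
#' @param x a \linkS4class{TimeProfiles}.
#' @name TimeProfiles-accessors
#' @aliases profileMatrix profileTimepoints
NULL
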