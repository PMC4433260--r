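#' Run the full PTM-dynamics pipeline
#'
#' Orchestrates simulate/load, channel normalization, log2 profile
#' construction, affinity-propagation clustering with BIC selection, early
#' response classification and (for paired designs) the FCR crosstalk
#' analysis, with a reproducible JSON run manifest.
#'
#' @param config a named list with elements:
#'   \describe{
#'     \item{simulate}{list of \code{\link{syntheticConfig}} arguments
#'       (mutually exclusive with \code{input}); \code{design = "tsa"}
#'       selects \code{\link{generateTSAExperiment}} instead of the time
#'       course.}
#'     \item{input}{list(\code{path}, \code{channel_map}) for
#'       \code{\link{readQuantTable}}.}
#'     \item{normalization}{list(\code{method}); default mean-ratio.}
#'     \item{clustering}{list(\code{enabled}, \code{damping}, \code{nGrid},
#'       \code{maxIter}, \code{convIter}, \code{seed}); enabled by default
#'       for time-course designs.}
#'     \item{crosstalk}{list(\code{enabled}, \code{vehicle}, \code{treated},
#'       \code{timepoint}, \code{alpha}, \code{thresholds}).}
#'     \item{out_dir}{optional output directory for
#'       \code{\link{writeResults}}.}
#'     \item{seed}{master seed; sub-stage seeds derive from it.}
#'   }
#' @return a result bundle: list with \code{table}, \code{truth} (synthetic
#'   runs), \code{ratios}, \code{profiles}, \code{sweep}, \code{clustering},
#'   \code{earlyResponse}, \code{fcr}, \code{tests}, \code{summary},
#'   \code{manifest}.
#' @examples
#' bundle <- runPipeline(list(simulate = list(n_sites = 40), seed = 7,
#'                            clustering = list(nGrid = 6)))
#' summarizeRun(bundle)
#' @export
runPipeline <- function(config) {
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    manifest <- list(config = config, seed = seed, stages = list())
    bundle <- list(manifest = manifest)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    }

    truth <- NULL
    isTSA <- FALSE
    if (!is.null(config$simulate)) {
        simArgs <- config$simulate
        isTSA <- identical(simArgs$design, "tsa")
        simArgs$design <- NULL
        if (is.null(simArgs$seed)) simArgs$seed <- seed
        sim <- stage("simulate", {
            cfg <- do.call(syntheticConfig, simArgs)
            if (isTSA) generateTSAExperiment(cfg) else generateDataset(cfg)
        })
        tab <- sim$table
        truth <- sim$truth
    } else if (!is.null(config$input)) {
        tab <- stage("load", readQuantTable(config$input$path,
                                            config$input$channel_map))
        isTSA <- length(unique(channelMap(tab)$condition)) == 2L &&
            length(unique(channelMap(tab)$timepoint_min)) == 2L
    } else {
        stopf("config must provide either 'simulate' or 'input'")
    }
    bundle$table <- tab
    bundle$truth <- truth
    manifest$stages$load <- list(n_sites = nrow(tab), n_channels = ncol(tab),
                                 counts = as.list(countUnique(tab)))

    method <- if (is.null(config$normalization$method)) "mean" else
        config$normalization$method
    bundle$ratios <- stage("normalize", computeChannelRatios(tab, method))
    norm <- stage("normalize", normalizeChannels(tab, bundle$ratios))
    bundle$normalized <- norm

    profiles <- stage("profiles", toLog2Profiles(norm, quiet = TRUE))
    bundle$profiles <- profiles
    manifest$stages$profiles <- list(
        n_profiles = nrow(profileMatrix(profiles)),
        n_dropped = nrow(attr(profiles, "dropped")))

    cl <- config$clustering
    doCluster <- if (!is.null(cl$enabled)) cl$enabled else
        (!isTSA && nrow(profileMatrix(profiles)) >= 4L)
    if (doCluster) {
        sweep <- stage("cluster", sweepPreferences(
            profiles,
            nGrid = if (is.null(cl$nGrid)) 15L else cl$nGrid,
            damping = if (is.null(cl$damping)) 0.9 else cl$damping,
            maxIter = if (is.null(cl$maxIter)) 1000L else cl$maxIter,
            convIter = if (is.null(cl$convIter)) 100L else cl$convIter,
            seed = if (is.null(cl$seed)) deriveSeed(seed, 11L) else cl$seed))
        bundle$sweep <- sweep
        bundle$clustering <- stage("cluster", selectClustering(sweep))
        manifest$stages$cluster <- list(
            K = nClusters(bundle$clustering),
            bic = clusterBIC(bundle$clustering),
            preference = bundle$clustering@preference,
            converged = bundle$clustering@converged,
            n_iterations = bundle$clustering@nIterations,
            cluster_sizes = as.list(table(clusterAssignments(bundle$clustering))))
    }

    if (!isTSA && 1 %in% profileTimepoints(profiles)) {
        lab <- stage("classify", classifyEarlyResponse(profiles))
        bundle$earlyResponse <- data.frame(
            site_key = siteData(profiles)$site_key,
            condition = siteData(profiles)$condition,
            log2fc_1min = profileMatrix(profiles)[,
                match(1, profileTimepoints(profiles))],
            early_response = lab)
        manifest$stages$classify <- as.list(table(lab))
    }

    ct <- config$crosstalk
    doCrosstalk <- if (!is.null(ct$enabled)) ct$enabled else isTSA
    if (doCrosstalk) {
        # FCR is a within-replicate ratio of ratios: per-channel loading
        # bias cancels up to one global factor, whereas mean-ratio
        # normalization would distort the FCR when a nontrivial fraction
        # of sites respond. Crosstalk therefore runs on the raw table.
        res <- stage("crosstalk", crosstalkAnalysis(
            tab,
            vehicle = if (is.null(ct$vehicle)) "vehicle" else ct$vehicle,
            treated = if (is.null(ct$treated)) "TSA" else ct$treated,
            timepoint = if (is.null(ct$timepoint)) 5 else ct$timepoint,
            alpha = if (is.null(ct$alpha)) 0.05 else ct$alpha))
        bundle$fcr <- res$fcr
        bundle$tests <- res$tests
        manifest$stages$crosstalk <- list(
            n_sites = nrow(res$fcr),
            fraction_fcr_altered = fractionFCRAltered(res$fcr),
            n_significant_raw = if (is.null(res$tests)) NA_integer_ else
                sum(res$tests$significant_raw))
    }

    bundle$manifest <- manifest
    bundle$summary <- summarizeRun(bundle, print = FALSE)
    if (!is.null(config$out_dir))
        writeResults(bundle, config$out_dir)
    bundle
}

#' Summarize a pipeline run
#'
#' One-page summary of a \code{\link{runPipeline}} bundle: site and protein
#' counts, selected number of clusters and cluster sizes, early-response
#' class counts, number of significant sites and the fraction of
#' FCR-altered sites.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @param print print the summary to the console.
#' @return invisibly, a two-column data.frame (\code{metric},
#'   \code{value}).
#' @export
summarizeRun <- function(bundle, print = TRUE) {
    rows <- list()
    add <- function(metric, value)
        rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                                 value = as.character(value))
    cnt <- countUnique(bundle$table)
    add("n_peptide_sites", cnt[["n_peptide_sites"]])
    add("n_proteins", cnt[["n_proteins"]])
    if (!is.null(bundle$profiles))
        add("n_profiles", nrow(profileMatrix(bundle$profiles)))
    if (!is.null(bundle$clustering)) {
        add("K_selected", nClusters(bundle$clustering))
        sizes <- table(clusterAssignments(bundle$clustering))
        add("cluster_sizes", paste(sizes, collapse = ","))
        add("bic", format(clusterBIC(bundle$clustering), digits = 8))
    }
    if (!is.null(bundle$earlyResponse)) {
        tab <- table(bundle$earlyResponse$early_response)
        for (l in names(tab)) add(paste0("early_", l), tab[[l]])
    }
    if (!is.null(bundle$fcr))
        add("fraction_fcr_altered",
            format(fractionFCRAltered(bundle$fcr), digits = 8))
    if (!is.null(bundle$tests))
        add("n_significant_raw", sum(bundle$tests$significant_raw))
    out <- do.call(rbind, rows)
    if (print) {
        cat("Pipeline run summary\n")
        for (i in seq_len(nrow(out)))
            cat(sprintf("  %-24s %s\n", out$metric[i], out$value[i]))
    }
    invisible(out)
}
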