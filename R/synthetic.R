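#' Temporal archetype profiles
#'
#' The four fixed log2 fold-change archetypes over the study's time course
#' (0, 1, 5, 30 min): a rapid deacetylation sustained across the course, a
#' late decrease, an unchanged profile, and a slight increase. Magnitudes
#' are fixed constants chosen so that the sustained decrease crosses the
#' at-least-two-fold class (log2 <= -1) by 1 minute and the increase
#' approaches the >1.5-fold class; shapes follow the four observed cluster
#' behaviours.
#'
#' @return named list of numeric length-4 profiles; all are 0 at t = 0.
#' @examples
#' archetypeProfiles()$sustained_decrease
#' @export
archetypeProfiles <- function() {
    list(sustained_decrease = c(0, -1.2, -1.2, -1.2),
         late_decrease      = c(0,  0.0, -0.2, -1.0),
         unchanged          = c(0,  0.0,  0.0,  0.0),
         slight_increase    = c(0,  0.3,  0.45, 0.6))
}

#' Configuration for synthetic reporter-table generation
#'
#' See \linkS4class{SyntheticConfig} for the meaning and calibration of the
#' defaults.
#'
#' @param n_sites number of modified peptide sites to simulate.
#' @param timepoints ordered timepoints in minutes; the first is the
#'   unstimulated reference.
#' @param archetype_weights named probability vector over the four
#'   archetypes of \code{\link{archetypeProfiles}}.
#' @param noise_sd_log2 SD of per-channel measurement noise on the log2
#'   scale (default 0.15).
#' @param channel_bias positive per-channel loading multiplier; length 1 or
#'   one per generated channel (default 1, no bias).
#' @param n_replicates biological replicates (default 4).
#' @param cv_target per-site coefficient of variation of reference-channel
#'   intensity across replicates (default 0.08, i.e. 8\%).
#' @param fcr_altered_fraction fraction of sites with a planted non-unit
#'   fold-change ratio in \code{\link{generateTSAExperiment}} (default 0.1).
#' @param site_offset_sd SD of the per-site log2 offset around the
#'   archetype at non-reference timepoints (default 0.1).
#' @param seed integer seed governing every draw.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(n_sites = 200L,
                            timepoints = c(0, 1, 5, 30),
                            archetype_weights = c(sustained_decrease = 0.25,
                                                  late_decrease = 0.25,
                                                  unchanged = 0.3,
                                                  slight_increase = 0.2),
                            noise_sd_log2 = 0.15,
                            channel_bias = 1,
                            n_replicates = 4L,
                            cv_target = 0.08,
                            fcr_altered_fraction = 0.1,
                            site_offset_sd = 0.1,
                            seed = 1L) {
    new("SyntheticConfig", n_sites = as.integer(n_sites),
        timepoints = as.numeric(timepoints),
        archetype_weights = archetype_weights,
        noise_sd_log2 = noise_sd_log2, channel_bias = channel_bias,
        n_replicates = as.integer(n_replicates), cv_target = cv_target,
        fcr_altered_fraction = fcr_altered_fraction,
        site_offset_sd = site_offset_sd, seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@n_sites, "sites,",
        object@n_replicates, "replicates, timepoints {",
        paste(object@timepoints, collapse = ", "), "} min\n")
    cat(sprintf("  noise_sd_log2 = %g, cv_target = %g, site_offset_sd = %g, seed = %d\n",
                object@noise_sd_log2, object@cv_target,
                object@site_offset_sd, object@seed))
})

# Site annotation for n synthetic acetylation sites spread over ~n/1.4
# proteins so some proteins carry multiple sites, as observed in real data.
syntheticSites <- function(n, residue = "K", modification = "acetyl") {
    nProt <- max(1L, ceiling(n / 1.4))
    prot <- sort(sample.int(nProt, n, replace = TRUE))
    pos <- integer(n)
    for (p in unique(prot)) {
        i <- which(prot == p)
        pos[i] <- sort(sample(5:400, length(i)))
    }
    aa <- c("A", "G", "L", "S", "V", "E", "D", "T", "N", "Q", "F", "R")
    pep <- vapply(seq_len(n), function(i)
        paste0(paste(sample(aa, 6, TRUE), collapse = ""), residue,
               paste(sample(aa, 5, TRUE), collapse = "")), character(1))
    data.frame(protein_id = sprintf("SYNP%04d", prot),
               gene_name = sprintf("SYNG%04d", prot),
               residues = residue, positions = as.character(pos),
               modification = modification, peptide = pep)
}

# lognormal sdlog giving a target CV: CV^2 = exp(sdlog^2) - 1.
cvToSdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic multiplexed reporter table with ground truth
#'
#' Emulates the data-generating process of a multiplexed (iTRAQ-style)
#' acetylation time course. Per site: an archetype is drawn from
#' \code{archetype_weights}; the true log2 profile is the archetype plus a
#' per-site Gaussian offset at non-reference timepoints; the
#' reference-channel intensity is drawn log-normal around 1e6 arbitrary
#' units; each biological replicate applies a multiplicative log-normal
#' effect calibrated so the per-site CV of reference intensities across
#' replicates targets \code{cv_target}; non-reference channel intensities
#' are reference x 2^(profile + N(0, noise_sd_log2)) x channel bias.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with elements \code{table} (\linkS4class{ReporterTable}) and
#'   \code{truth} (\code{DataFrame} with per-site archetype, true log2
#'   profile columns \code{true_log2_t*}), plus the channel bias used in
#'   \code{metadata(truth)} terms: \code{attr(truth, "metadata")} via
#'   \code{S4Vectors::metadata}.
#' @examples
#' sim <- generateDataset(syntheticConfig(n_sites = 20, seed = 42))
#' sim$table
#' table(sim$truth$archetype)
#' @export
generateDataset <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    arch <- archetypeProfiles()
    tp <- config@timepoints
    if (length(tp) != 4L)
        stopf("archetype profiles are defined over 4 timepoints; got %d",
              length(tp))
    n <- config@n_sites
    R <- config@n_replicates

    cm <- expand.grid(timepoint_min = tp, replicate = seq_len(R),
                      KEEP.OUT.ATTRS = FALSE)
    cm <- data.frame(channel = sprintf("rep%d_t%g", cm$replicate,
                                       cm$timepoint_min),
                     condition = "stimulated",
                     timepoint_min = cm$timepoint_min,
                     replicate = cm$replicate)
    bias <- rep_len(config@channel_bias, nrow(cm))
    names(bias) <- cm$channel

    withSeed(config@seed, {
        sites <- syntheticSites(n)
        labels <- sample(names(config@archetype_weights), n, replace = TRUE,
                         prob = config@archetype_weights)
        trueProf <- t(vapply(labels, function(l) arch[[l]], numeric(4)))
        offs <- matrix(stats::rnorm(n * 3L, 0, config@site_offset_sd), n, 3L)
        trueProf[, -1L] <- trueProf[, -1L] + offs
        base <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 0.5)
        sdRep <- cvToSdlog(config@cv_target)
        repEff <- matrix(stats::rlnorm(n * R, -sdRep^2 / 2, sdRep), n, R)
        inten <- matrix(NA_real_, n, nrow(cm),
                        dimnames = list(NULL, cm$channel))
        for (j in seq_len(nrow(cm))) {
            r <- cm$replicate[j]
            ti <- match(cm$timepoint_min[j], tp)
            refI <- base * repEff[, r]
            inten[, j] <- if (ti == 1L) refI * bias[j] else
                refI * 2^(trueProf[, ti] +
                          stats::rnorm(n, 0, config@noise_sd_log2)) * bias[j]
        }
        tab <- ReporterTable(inten, sites, cm)
    })

    truthProf <- trueProf
    colnames(truthProf) <- paste0("true_log2_t", tp)
    truth <- DataFrame(site_key = siteKeys(tab), archetype = labels,
                       truthProf)
    metadata(truth)$channel_bias <- bias
    metadata(truth)$config <- config
    list(table = tab, truth = truth)
}

#' Generate a paired vehicle / deacetylase-inhibitor experiment
#'
#' Simulates the crosstalk design: per replicate, four channels (vehicle
#' unstimulated, vehicle 5-min EGF, TSA-pretreated unstimulated,
#' TSA-pretreated 5-min EGF). Each site has a true vehicle EGF response
#' (log2 ~ N(0, 0.8)); a planted fraction of sites receives a true
#' fold-change ratio (FCR) drawn uniformly from [0.2, 0.5] U [1.5, 3.0]
#' (proportional to interval length), all others have true FCR = 1; the
#' TSA response is the vehicle response times the FCR.
#'
#' @param config a \linkS4class{SyntheticConfig};
#'   \code{fcr_altered_fraction} controls the planted fraction and the
#'   number of planted sites is \code{round(n_sites * fraction)}.
#' @return list with \code{table} (\linkS4class{ReporterTable} with
#'   conditions \code{"vehicle"} and \code{"TSA"}, timepoints {0, 5}) and
#'   \code{truth} (\code{DataFrame}: \code{site_key}, \code{fc_vehicle_true},
#'   \code{fc_tsa_true}, \code{fcr_true}, \code{altered}).
#' @examples
#' sim <- generateTSAExperiment(syntheticConfig(n_sites = 50, seed = 3))
#' mean(sim$truth$altered)
#' @export
generateTSAExperiment <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    n <- config@n_sites
    R <- config@n_replicates
    cm <- expand.grid(timepoint_min = c(0, 5), condition = c("vehicle", "TSA"),
                      replicate = seq_len(R), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    cm <- data.frame(channel = sprintf("%s_t%g_r%d", cm$condition,
                                       cm$timepoint_min, cm$replicate),
                     condition = cm$condition,
                     timepoint_min = cm$timepoint_min,
                     replicate = cm$replicate)
    bias <- rep_len(config@channel_bias, nrow(cm))
    names(bias) <- cm$channel

    withSeed(deriveSeed(config@seed, 77L), {
        sites <- syntheticSites(n, residue = "Y", modification = "phospho")
        log2Veh <- stats::rnorm(n, 0, 0.8)
        nAlt <- round(n * config@fcr_altered_fraction)
        altered <- rep(FALSE, n)
        altered[sample.int(n, nAlt)] <- TRUE
        fcr <- rep(1, n)
        if (nAlt) {
            lo <- stats::runif(nAlt) < (0.3 / 1.8)  # |[0.2,0.5]| vs |[1.5,3.0]|
            fcr[altered] <- ifelse(lo, stats::runif(nAlt, 0.2, 0.5),
                                   stats::runif(nAlt, 1.5, 3.0))
        }
        log2Tsa <- log2Veh + log2(fcr)
        base <- stats::rlnorm(n, log(1e6), 0.5)
        sdRep <- cvToSdlog(config@cv_target)
        inten <- matrix(NA_real_, n, nrow(cm),
                        dimnames = list(NULL, cm$channel))
        for (r in seq_len(R)) {
            eff <- stats::rlnorm(n, -sdRep^2 / 2, sdRep)
            for (cond in c("vehicle", "TSA")) {
                ref <- base * eff
                j0 <- which(cm$condition == cond & cm$replicate == r &
                            cm$timepoint_min == 0)
                j5 <- which(cm$condition == cond & cm$replicate == r &
                            cm$timepoint_min == 5)
                resp <- if (cond == "vehicle") log2Veh else log2Tsa
                inten[, j0] <- ref * bias[j0]
                inten[, j5] <- ref * 2^(resp +
                    stats::rnorm(n, 0, config@noise_sd_log2)) * bias[j5]
            }
        }
        tab <- ReporterTable(inten, sites, cm)
    })
    truth <- DataFrame(site_key = siteKeys(tab),
                       fc_vehicle_true = 2^log2Veh, fc_tsa_true = 2^log2Tsa,
                       fcr_true = fcr, altered = altered)
    metadata(truth)$channel_bias <- bias
    metadata(truth)$config <- config
    list(table = tab, truth = truth)
}

#' Generate synthetic SILAC heavy/light intensity pairs
#'
#' Stimulated (heavy) over unstimulated (light) intensity pairs with known
#' per-site fold changes, for testing SILAC ratio quantification.
#'
#' @param n number of sites.
#' @param log2fc_sd SD of the true log2 fold change (default 1).
#' @param noise_sd_log2 measurement noise on each intensity, log2 scale.
#' @param seed integer seed.
#' @return data.frame with \code{site_key}, \code{heavy}, \code{light},
#'   \code{fold_change_true}.
#' @export
generateSilacPairs <- function(n = 50L, log2fc_sd = 1, noise_sd_log2 = 0.1,
                               seed = 1L) {
    withSeed(seed, {
        fc <- 2^stats::rnorm(n, 0, log2fc_sd)
        light <- stats::rlnorm(n, log(1e6), 0.5) *
            2^stats::rnorm(n, 0, noise_sd_log2)
        heavy <- light * fc * 2^stats::rnorm(n, 0, noise_sd_log2)
        data.frame(site_key = sprintf("SILAC%04d", seq_len(n)),
                   heavy = heavy, light = light, fold_change_true = fc)
    })
}
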