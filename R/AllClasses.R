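#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData rowData<- colData<-
NULL

#' ReporterTable: peptide-level PTM quantification container
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{"intensity"} assay
#' (modified peptides x reporter channels), with the channel map in
#' \code{colData} (columns \code{channel}, \code{condition},
#' \code{timepoint_min}, \code{replicate}, \code{is_reference}) and the PTM
#' site annotation in \code{rowData} (columns \code{protein_id},
#' \code{gene_name}, \code{residues}, \code{positions}, \code{modification},
#' \code{peptide}, \code{site_key}).
#'
#' The site key is \code{protein_id|residue-position list (sorted)|peptide},
#' so a doubly modified peptide (e.g. histone H4 K6+K9 acetylation) is one
#' site. Intensities are nonnegative; missing values are allowed. Each
#' (condition, replicate) labeling block designates exactly one reference
#' channel (the unstimulated / timepoint-0 channel).
#'
#' @export
setClass("ReporterTable", contains = "SummarizedExperiment")

.CHANNEL_COLS <- c("channel", "condition", "timepoint_min", "replicate",
                   "is_reference")
.SITE_COLS <- c("protein_id", "gene_name", "residues", "positions",
                "modification", "peptide", "site_key")

setValidity("ReporterTable", function(object) {
    msg <- character()
    if (!"intensity" %in% assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    cd <- colData(object)
    miss <- setdiff(.CHANNEL_COLS, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("channel map lacks column(s): ",
                             paste(miss, collapse = ", ")))
    rd <- rowData(object)
    miss <- setdiff(.SITE_COLS, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("site annotation lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg))
        return(msg)
    x <- assay(object, "intensity")
    if (any(x[!is.na(x)] < 0))
        msg <- c(msg, "intensities must be nonnegative")
    if (anyDuplicated(rd$site_key))
        msg <- c(msg, "duplicate site keys present; deduplicate first")
    blocks <- paste(cd$condition, cd$replicate, sep = "\r")
    nref <- vapply(split(cd$is_reference, blocks), sum, 0)
    if (nrow(cd) && any(nref != 1L))
        msg <- c(msg,
                 "each (condition, replicate) block needs exactly one reference channel")
    if (length(msg)) msg else TRUE
})

#' Temporal log2 fold-change profiles
#'
#' Per-site log2 fold changes relative to the reference (unstimulated,
#' timepoint-0) channel, over an ordered set of timepoints. The value at the
#' reference timepoint is exactly 0 and all values are finite; sites with a
#' missing or nonpositive channel in any replicate are excluded upstream.
#'
#' @slot profiles numeric matrix, one row per site (and per condition when a
#'   table carries several stimulation conditions), one column per timepoint.
#' @slot timepoints ordered numeric vector of timepoints in minutes; the
#'   first entry is the reference timepoint.
#' @slot siteData \code{DataFrame} of row annotation (site key, protein,
#'   condition, ...), parallel to the rows of \code{profiles}.
#' @export
setClass("TimeProfiles",
    representation(profiles = "matrix", timepoints = "numeric",
                   siteData = "DataFrame"))

setValidity("TimeProfiles", function(object) {
    msg <- character()
    p <- object@profiles
    tp <- object@timepoints
    if (ncol(p) != length(tp))
        msg <- c(msg, "ncol(profiles) must equal length(timepoints)")
    if (is.unsorted(tp))
        msg <- c(msg, "timepoints must be increasing")
    if (nrow(p) != nrow(object@siteData))
        msg <- c(msg, "siteData rows must match profile rows")
    if (length(p) && !all(is.finite(p)))
        msg <- c(msg, "profiles must be finite")
    if (length(p) && ncol(p) && any(p[, 1L] != 0))
        msg <- c(msg, "profiles must be 0 at the reference timepoint")
    if (length(msg)) msg else TRUE
})

#' Result of one affinity-propagation clustering
#'
#' @slot exemplars sorted integer indices of exemplar points.
#' @slot assignment integer vector mapping every point to its exemplar's
#'   index; exemplars map to themselves.
#' @slot netSimilarity sum of s(i, exemplar(i)) over non-exemplars plus the
#'   preference once per exemplar.
#' @slot bic spherical-Gaussian BIC of the clustering (lower is better);
#'   \code{NA} until scored.
#' @slot preference diagonal similarity used.
#' @slot converged whether the exemplar set was stable for the convergence
#'   window.
#' @slot nIterations message-passing iterations executed.
#' @export
setClass("ClusterResult",
    representation(exemplars = "integer", assignment = "integer",
                   netSimilarity = "numeric", bic = "numeric",
                   preference = "numeric", converged = "logical",
                   nIterations = "integer"))

setValidity("ClusterResult", function(object) {
    msg <- character()
    ex <- object@exemplars
    as <- object@assignment
    if (length(ex) < 1L)
        msg <- c(msg, "at least one exemplar is required")
    if (!all(as %in% ex))
        msg <- c(msg, "every point must be assigned to an exemplar")
    if (!all(as[ex] == ex))
        msg <- c(msg, "exemplars must be assigned to themselves")
    if (anyNA(as) || length(as) < length(ex))
        msg <- c(msg, "assignment must cover all points")
    if (length(msg)) msg else TRUE
})

#' Configuration for the synthetic reporter-table generator
#'
#' Defaults encode the calibration of the emulated study design: 4
#' timepoints (0, 1, 5, 30 min), 4 biological replicates, per-channel log2
#' measurement noise of 0.15, per-site replicate coefficient of variation of
#' 8\% (under the <10\% reproducibility bound reported for unstimulated
#' acetylation sites), per-site archetype offsets of 0.1 log2 units, and no
#' channel loading bias.
#'
#' @export
setClass("SyntheticConfig",
    representation(n_sites = "integer", timepoints = "numeric",
                   archetype_weights = "numeric", noise_sd_log2 = "numeric",
                   channel_bias = "numeric", n_replicates = "integer",
                   cv_target = "numeric", fcr_altered_fraction = "numeric",
                   site_offset_sd = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@n_sites < 1L)
        msg <- c(msg, "n_sites must be positive")
    if (abs(sum(object@archetype_weights) - 1) > 1e-8 ||
        any(object@archetype_weights < 0))
        msg <- c(msg, "archetype_weights must be nonnegative and sum to 1")
    if (!setequal(names(object@archetype_weights), names(archetypeProfiles())))
        msg <- c(msg, "archetype_weights must be named by the four archetypes")
    if (object@cv_target <= 0 || object@cv_target >= 1)
        msg <- c(msg, "cv_target must lie in (0, 1)")
    if (object@noise_sd_log2 < 0 || object@site_offset_sd < 0)
        msg <- c(msg, "noise SDs must be nonnegative")
    if (any(object@channel_bias <= 0))
        msg <- c(msg, "channel_bias entries must be positive")
    if (object@n_replicates < 1L)
        msg <- c(msg, "n_replicates must be positive")
    if (object@fcr_altered_fraction < 0 || object@fcr_altered_fraction > 1)
        msg <- c(msg, "fcr_altered_fraction must lie in [0, 1]")
    if (length(object@timepoints) < 2L || is.unsorted(object@timepoints))
        msg <- c(msg, "timepoints must be an increasing vector, length >= 2")
    if (length(msg)) msg else TRUE
})
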