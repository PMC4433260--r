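#' Construct a ReporterTable
#'
#' Assembles peptide-level reporter intensities, PTM site annotation and a
#' channel map into a validated \linkS4class{ReporterTable}.
#'
#' @param intensities numeric matrix, sites x channels; nonnegative, \code{NA}
#'   allowed. Column order must match \code{channelMap$channel}.
#' @param sites \code{data.frame} or \code{DataFrame} with columns
#'   \code{protein_id}, \code{peptide}, and either \code{residues} +
#'   \code{positions} (comma-separated for multiply modified peptides) or a
#'   precomputed \code{site_key}. Optional: \code{gene_name},
#'   \code{modification}.
#' @param channelMap \code{data.frame}/\code{DataFrame} with columns
#'   \code{channel}, \code{condition}, \code{timepoint_min},
#'   \code{replicate}; \code{is_reference} is derived (timepoint 0) when
#'   absent.
#'
#' @return A \linkS4class{ReporterTable}.
#' @examples
#' tab <- ReporterTable(
#'     matrix(c(100, 200, 50, 400), 1, 4,
#'            dimnames = list(NULL, paste0("ch", 1:4))),
#'     data.frame(protein_id = "P04406", gene_name = "GAPDH",
#'                residues = "K", positions = "194", modification = "acetyl",
#'                peptide = "LISWYDNEFGYSNR"),
#'     data.frame(channel = paste0("ch", 1:4), condition = "EGF",
#'                timepoint_min = c(0, 1, 5, 30), replicate = 1L))
#' countUnique(tab)
#' @export
ReporterTable <- function(intensities, sites, channelMap) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    sites <- as.data.frame(sites)
    channelMap <- completeChannelMap(channelMap)
    if (ncol(intensities) != nrow(channelMap))
        stopf("intensity matrix has %d columns but the channel map has %d channels",
              ncol(intensities), nrow(channelMap))
    if (!is.null(colnames(intensities)) &&
        !identical(colnames(intensities), channelMap$channel))
        intensities <- intensities[, channelMap$channel, drop = FALSE]
    sites <- completeSiteData(sites)
    if (nrow(sites) != nrow(intensities))
        stopf("site annotation has %d rows but the intensity matrix has %d",
              nrow(sites), nrow(intensities))
    colnames(intensities) <- channelMap$channel
    rownames(intensities) <- sites$site_key
    se <- SummarizedExperiment(assays = list(intensity = intensities),
                               rowData = DataFrame(sites),
                               colData = DataFrame(channelMap,
                                                   row.names = channelMap$channel))
    new("ReporterTable", se)
}

# Fill derivable channel-map columns and coerce types.
completeChannelMap <- function(cm) {
    cm <- as.data.frame(cm)
    need <- c("channel", "condition", "timepoint_min", "replicate")
    miss <- setdiff(need, colnames(cm))
    if (length(miss))
        stopf("channel map lacks mandatory column(s): %s",
              paste(miss, collapse = ", "))
    cm$channel <- as.character(cm$channel)
    cm$condition <- as.character(cm$condition)
    cm$timepoint_min <- as.numeric(cm$timepoint_min)
    cm$replicate <- as.integer(cm$replicate)
    if (is.null(cm$is_reference)) {
        ref <- stats::ave(cm$timepoint_min, blockId(cm), FUN = min)
        cm$is_reference <- cm$timepoint_min == ref
    }
    cm$is_reference <- as.logical(cm$is_reference)
    if (anyDuplicated(cm$channel))
        stopf("duplicate channel labels in channel map")
    key <- paste(blockId(cm), cm$timepoint_min)
    if (anyDuplicated(key))
        stopf("channel map must have exactly one channel per (condition, timepoint, replicate)")
    cm
}

# Fill derivable site-annotation columns; derive modification from residue
# (K -> acetyl, Y -> phospho) when absent.
completeSiteData <- function(sites) {
    for (col in c("protein_id", "peptide"))
        if (is.null(sites[[col]]))
            stopf("site annotation lacks mandatory column '%s'", col)
    sites$protein_id <- as.character(sites$protein_id)
    sites$peptide <- toupper(as.character(sites$peptide))
    if (is.null(sites$gene_name)) sites$gene_name <- NA_character_
    if (is.null(sites$residues) || is.null(sites$positions))
        stopf("site annotation lacks mandatory column '%s'",
              if (is.null(sites$residues)) "residues" else "positions")
    sites$residues <- gsub(" ", "", toupper(as.character(sites$residues)))
    sites$positions <- gsub(" ", "", as.character(sites$positions))
    if (is.null(sites$modification)) {
        first <- substr(sites$residues, 1L, 1L)
        sites$modification <- ifelse(first == "K", "acetyl",
                              ifelse(first == "Y", "phospho", NA_character_))
    }
    sites$site_key <- makeSiteKey(sites$protein_id, sites$residues,
                                  sites$positions, sites$peptide)
    sites[, .SITE_COLS]
}

#' Accessors for ReporterTable
#'
#' \code{channelMap} returns the channel annotation (condition, timepoint,
#' replicate, reference flag); \code{intensityMatrix} the raw intensity
#' assay; \code{siteKeys} the canonical site keys; \code{siteData} the PTM
#' site annotation; \code{referenceChannels} the named map from
#' (condition, replicate) block to its reference channel.
#'
#' @param x a \linkS4class{ReporterTable}.
#' @return See the per-accessor description.
#' @name ReporterTable-accessors
#' @aliases channelMap intensityMatrix siteKeys siteData referenceChannels
NULL

#' @rdname ReporterTable-accessors
#' @export
setMethod("channelMap", "ReporterTable", function(x) colData(x))

#' @rdname ReporterTable-accessors
#' @export
setMethod("intensityMatrix", "ReporterTable",
          function(x) assay(x, "intensity"))

#' @rdname ReporterTable-accessors
#' @export
setMethod("siteKeys", "ReporterTable", function(x) rowData(x)$site_key)

#' @rdname ReporterTable-accessors
#' @export
setMethod("siteData", "ReporterTable", function(x) rowData(x))

#' @rdname ReporterTable-accessors
#' @export
setMethod("referenceChannels", "ReporterTable", function(x) {
    cd <- colData(x)
    ref <- cd$channel[cd$is_reference]
    names(ref) <- blockId(cd)[cd$is_reference]
    ref
})

setMethod("show", "ReporterTable", function(object) {
    cd <- colData(object)
    cat("ReporterTable:", nrow(object), "PTM sites x", ncol(object),
        "channels\n")
    cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
    cat("  timepoints (min):",
        paste(sort(unique(cd$timepoint_min)), collapse = ", "), "\n")
    cat("  replicates:", max(cd$replicate), "\n")
})
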