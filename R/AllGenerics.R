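#' @rdname ReporterTable-accessors
#' @export
setGeneric("channelMap", function(x) standardGeneric("channelMap"))

#' @rdname ReporterTable-accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname ReporterTable-accessors
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname ReporterTable-accessors
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' @rdname ReporterTable-accessors
#' @export
setGeneric("referenceChannels", function(x) standardGeneric("referenceChannels"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("exemplars", function(x) standardGeneric("exemplars"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("netSimilarity", function(x) standardGeneric("netSimilarity"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("clusterBIC", function(x) standardGeneric("clusterBIC"))

#' @rdname TimeProfiles-accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname TimeProfiles-accessors
#' @export
setGeneric("profileTimepoints", function(x) standardGeneric("profileTimepoints"))
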