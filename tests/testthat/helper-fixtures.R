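# Shared fixture builders; everything is generated in code.

# 4-plex single-replicate channel map over the study time course.
toyChannelMap <- function(condition = "insulin") {
    data.frame(channel = paste0("ch", 1:4), condition = condition,
               timepoint_min = c(0, 1, 5, 30), replicate = 1L)
}

# Small deterministic reporter table with hand-set intensities.
toyTable <- function(intensities = NULL, n = 5L) {
    if (is.null(intensities)) {
        intensities <- matrix(1e6 * (1:n), n, 4,
                              dimnames = list(NULL, paste0("ch", 1:4)))
    }
    n <- nrow(intensities)
    sites <- data.frame(protein_id = sprintf("P%05d", seq_len(n)),
                        gene_name = sprintf("G%d", seq_len(n)),
                        residues = "K",
                        positions = as.character(10 * seq_len(n)),
                        modification = "acetyl",
                        peptide = vapply(seq_len(n), function(i)
                            paste0("AAAK", paste(rep("L", i), collapse = ""),
                                   "R"), character(1)))
    ReporterTable(intensities, sites, toyChannelMap())
}

# Write a quant TSV in the dialect readQuantTable() expects.
writeToyTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

# Random well-separated two-cluster instance for AP-vs-oracle checks.
separatedInstance <- function(seed, nMax = 10L) {
    set.seed(seed)
    n <- sample(4:nMax, 1)
    centers <- matrix(stats::rnorm(2 * 4, sd = 5), 2, 4)
    lab <- sample(1:2, n, replace = TRUE)
    pts <- centers[lab, , drop = FALSE] +
        matrix(stats::rnorm(n * 4, sd = 0.1), n, 4)
    list(points = pts, labels = lab)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
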