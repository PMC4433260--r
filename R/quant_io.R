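#' Read a peptide-level quantification table
#'
#' Reads a delimited (TSV or CSV) quantification table with one row per
#' modified peptide and one intensity column per reporter channel, validates
#' it, collapses duplicate site rows, and returns a
#' \linkS4class{ReporterTable}. Rows that fail validation (negative
#' intensity, unparseable site annotation, inconsistent residue /
#' modification pairing) are dropped and logged with a reason; missing
#' mandatory columns are a hard error.
#'
#' Site annotation is taken from \code{residues} + \code{positions} columns
#' or from a single \code{sites} column of tokens like \code{"K6+K9"} or
#' \code{"Y354"} (residue letter followed by 1-based protein position).
#'
#' @param path path to the delimited file; \code{.csv} is read
#'   comma-separated, anything else tab-separated.
#' @param channelMap channel map \code{data.frame} (see
#'   \code{\link{ReporterTable}}) or path to a TSV/CSV with the same columns.
#' @param dedup how to collapse duplicate site keys: \code{"sum"} (reporter
#'   intensities are additive evidence; default) or \code{"max"}.
#' @param quiet suppress the per-file log messages.
#'
#' @return A \linkS4class{ReporterTable}; dropped rows and the number of
#'   collapsed duplicates are recorded in \code{metadata()} under
#'   \code{rejected} and \code{n_duplicates_collapsed}.
#' @export
readQuantTable <- function(path, channelMap, dedup = c("sum", "max"),
                           quiet = FALSE) {
    dedup <- match.arg(dedup)
    if (is.character(channelMap) && length(channelMap) == 1L)
        channelMap <- readChannelMap(channelMap)
    cm <- completeChannelMap(as.data.frame(channelMap))
    df <- readDelim(path)

    need <- c("protein_id", "peptide")
    if (!("sites" %in% colnames(df)))
        need <- c(need, "residues", "positions")
    miss <- setdiff(c(need, cm$channel), colnames(df))
    if (length(miss))
        stopf("quantification table '%s' lacks mandatory column(s): %s",
              path, paste(miss, collapse = ", "))

    rejected <- data.frame(row = integer(), reason = character())
    reject <- function(idx, reason) {
        rejected <<- rbind(rejected, data.frame(row = idx, reason = reason))
    }

    bad <- integer()
    if ("sites" %in% colnames(df) && is.null(df$residues)) {
        parsed <- parseSiteTokens(df$sites)
        bad <- which(is.na(parsed$residues))
        if (length(bad))
            reject(bad, "unparseable site annotation")
        df$residues <- parsed$residues
        df$positions <- parsed$positions
    }

    inten <- as.matrix(df[, cm$channel, drop = FALSE])
    suppressWarnings(storage.mode(inten) <- "double")
    neg <- which(apply(inten, 1L, function(r) any(!is.na(r) & r < 0)))
    if (length(neg))
        reject(neg, "negative intensity")

    first <- substr(gsub(" ", "", toupper(as.character(df$residues))), 1L, 1L)
    badres <- which(!(first %in% c("K", "Y")))
    if (length(badres))
        reject(badres, "residue must be K or Y")
    if (!is.null(df$modification)) {
        want <- ifelse(first == "K", "acetyl", "phospho")
        mism <- which(first %in% c("K", "Y") &
                      !is.na(df$modification) & df$modification != want)
        if (length(mism))
            reject(mism, "modification inconsistent with residue")
    }
    badpos <- which(!vapply(strsplit(as.character(df$positions), ","),
                            function(p) all(grepl("^[0-9]+$", trimws(p))) &&
                                all(as.integer(p) >= 1L),
                            logical(1)))
    badpos <- setdiff(badpos, bad_from(rejected, "unparseable site annotation"))
    if (length(badpos))
        reject(badpos, "positions must be positive integers")

    keep <- setdiff(seq_len(nrow(df)), unique(rejected$row))
    if (!quiet && nrow(rejected))
        message(sprintf("readQuantTable: dropped %d row(s): %s",
                        length(unique(rejected$row)),
                        paste(sprintf("row %d (%s)", rejected$row,
                                      rejected$reason), collapse = "; ")))
    df <- df[keep, , drop = FALSE]
    inten <- inten[keep, , drop = FALSE]

    sites <- completeSiteData(df)
    dd <- dedupSites(inten, sites, dedup)
    if (!quiet && dd$n_collapsed)
        message(sprintf("readQuantTable: collapsed %d duplicate row(s) by '%s'",
                        dd$n_collapsed, dedup))
    ambiguous <- grepl("[;]", dd$sites$protein_id)
    if (!quiet && any(ambiguous))
        message(sprintf("readQuantTable: %d row(s) map to multiple accessions",
                        sum(ambiguous)))

    tab <- ReporterTable(dd$intensities, dd$sites, cm)
    metadata(tab)$rejected <- rejected
    metadata(tab)$n_duplicates_collapsed <- dd$n_collapsed
    tab
}

bad_from <- function(rejected, reason) rejected$row[rejected$reason == reason]

readDelim <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE)
}

# "K6+K9" / "Y354" -> residues "K,K", positions "6,9"; NA when unparseable.
parseSiteTokens <- function(tokens) {
    res <- pos <- rep(NA_character_, length(tokens))
    for (i in seq_along(tokens)) {
        parts <- strsplit(trimws(tokens[i]), "+", fixed = TRUE)[[1L]]
        if (length(parts) && all(grepl("^[A-Za-z][0-9]+$", parts))) {
            res[i] <- paste(toupper(substr(parts, 1L, 1L)), collapse = ",")
            pos[i] <- paste(substring(parts, 2L), collapse = ",")
        }
    }
    list(residues = res, positions = pos)
}

# Collapse rows sharing a site key; intensities summed (or max'ed) per
# channel, NA treated as absent unless all contributions are NA.
dedupSites <- function(intensities, sites, method = c("sum", "max")) {
    method <- match.arg(method)
    key <- sites$site_key
    if (!anyDuplicated(key))
        return(list(intensities = intensities, sites = sites, n_collapsed = 0L))
    idx <- split(seq_along(key), factor(key, levels = unique(key)))
    fun <- if (method == "sum") sum else max
    collapse <- function(rows) {
        apply(intensities[rows, , drop = FALSE], 2L, function(v) {
            v <- v[!is.na(v)]
            if (length(v)) fun(v) else NA_real_
        })
    }
    out <- t(vapply(idx, collapse, numeric(ncol(intensities))))
    keepRow <- vapply(idx, `[`, integer(1), 1L)
    list(intensities = out, sites = sites[keepRow, , drop = FALSE],
         n_collapsed = length(key) - length(idx))
}

#' Read a channel-map configuration file
#'
#' The channel map is a small delimited file (or JSON object) with one entry
#' per reporter column: \code{channel}, \code{condition},
#' \code{timepoint_min}, \code{replicate}, optional \code{is_reference}.
#'
#' @param path TSV/CSV/JSON file path.
#' @return channel map \code{data.frame}.
#' @export
readChannelMap <- function(path) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        cm <- jsonlite::fromJSON(path)
        return(completeChannelMap(as.data.frame(cm)))
    }
    completeChannelMap(readDelim(path))
}

#' Count unique modified peptides and proteins
#'
#' Number of distinct site keys (peptide-level uniqueness: a multiply
#' modified peptide counts once) and distinct protein accessions in a table.
#' Rows listing multiple semicolon-separated accessions contribute each
#' accession once.
#'
#' @param table a \linkS4class{ReporterTable}.
#' @return named integer vector \code{c(n_peptide_sites, n_proteins)}.
#' @export
countUnique <- function(table) {
    rd <- rowData(table)
    accs <- unlist(strsplit(as.character(rd$protein_id), ";", fixed = TRUE))
    c(n_peptide_sites = length(unique(rd$site_key)),
      n_proteins = length(unique(trimws(accs[nzchar(accs)]))))
}

#' Write pipeline result tables
#'
#' Writes every table in a result bundle as TSV with a stable column order,
#' plus a JSON run manifest (configuration, seed, package version, per-stage
#' row counts). Numeric values are written at full double precision so a
#' write/read round trip preserves intensities to better than 1e-9 relative
#' error.
#'
#' @param bundle a named list; recognised elements are \code{table}
#'   (\linkS4class{ReporterTable}), \code{profiles}
#'   (\linkS4class{TimeProfiles}), \code{clustering}
#'   (\linkS4class{ClusterResult}), \code{earlyResponse}, \code{fcr},
#'   \code{tests} (data.frames) and \code{manifest} (list). A bare
#'   \linkS4class{ReporterTable} is accepted.
#' @param outDir output directory, created if needed.
#' @return invisibly, the named vector of files written.
#' @export
writeResults <- function(bundle, outDir) {
    if (is(bundle, "ReporterTable"))
        bundle <- list(table = bundle)
    ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                           showWarnings = FALSE)
    if (!ok || file.access(outDir, mode = 2L) != 0L)
        stopf("cannot write to output directory '%s'", outDir)
    files <- character()
    put <- function(df, name) {
        f <- file.path(outDir, name)
        utils::write.table(fullPrecision(df), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files[[name]] <<- f
    }
    if (!is.null(bundle$table)) {
        tab <- bundle$table
        df <- cbind(as.data.frame(siteData(tab)),
                    as.data.frame(intensityMatrix(tab), check.names = FALSE))
        put(df, "quant_table.tsv")
        put(as.data.frame(channelMap(tab)), "channel_map.tsv")
    }
    if (!is.null(bundle$profiles)) {
        pr <- bundle$profiles
        m <- profileMatrix(pr)
        colnames(m) <- paste0("log2fc_t", profileTimepoints(pr))
        put(cbind(as.data.frame(pr@siteData), as.data.frame(m)),
            "profiles.tsv")
    }
    if (!is.null(bundle$clustering)) {
        cl <- bundle$clustering
        keys <- if (!is.null(bundle$profiles))
            bundle$profiles@siteData$site_key else seq_along(cl@assignment)
        put(data.frame(site_key = keys,
                       cluster = match(cl@assignment, cl@exemplars),
                       exemplar_index = cl@assignment,
                       is_exemplar = seq_along(cl@assignment) %in% cl@exemplars),
            "cluster_assignments.tsv")
    }
    for (nm in c("earlyResponse", "fcr", "tests", "summary"))
        if (!is.null(bundle[[nm]]))
            put(as.data.frame(bundle[[nm]]),
                paste0(c(earlyResponse = "early_response", fcr = "fcr",
                         tests = "site_tests", summary = "run_summary")[nm],
                       ".tsv"))
    manifest <- bundle$manifest
    if (is.null(manifest)) manifest <- list()
    manifest$package_version <- as.character(utils::packageVersion("ptmDynamics"))
    manifest$r_version <- R.version.string
    manifest$files <- names(files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files[["manifest.json"]] <- file.path(outDir, "manifest.json")
    invisible(files)
}

# Format doubles with 15 significant digits for lossless-enough TSV output.
fullPrecision <- function(df) {
    for (j in seq_along(df))
        if (is.double(df[[j]]))
            df[[j]] <- sprintf("%.15g", df[[j]])
    df
}
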