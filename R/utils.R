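# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never clobber
# the user's stream.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    code
}

# Derive a sub-stream seed from a master seed; stays well below 2^31 for
# master seeds up to ~2e5 and offsets up to 9999.
deriveSeed <- function(seed, offset) {
    (as.integer(seed) %% 200000L) * 10000L + as.integer(offset)
}

# Build the canonical site key: protein accession, sorted residue-position
# tokens, peptide sequence. Uniqueness is peptide-level: a doubly modified
# peptide is one key.
makeSiteKey <- function(protein_id, residues, positions, peptide) {
    mapply(function(p, r, q, pep) {
        res <- strsplit(r, ",", fixed = TRUE)[[1L]]
        pos <- as.integer(strsplit(q, ",", fixed = TRUE)[[1L]])
        o <- order(pos, res)
        paste(p, paste0(res[o], pos[o], collapse = "+"), pep, sep = "|")
    }, protein_id, residues, positions, peptide, USE.NAMES = FALSE)
}

blockId <- function(cd) paste(cd$condition, cd$replicate, sep = "\r")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
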