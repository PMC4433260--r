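test_that("a well-formed table round-trips through write and read", {
    tab <- toyTable()
    dir <- withr::local_tempdir()
    writeResults(tab, dir)
    back <- readQuantTable(file.path(dir, "quant_table.tsv"),
                           file.path(dir, "channel_map.tsv"), quiet = TRUE)
    expect_identical(siteKeys(back), siteKeys(tab))
    expect_equal(intensityMatrix(back), intensityMatrix(tab),
                 tolerance = 1e-9)
    expect_identical(dim(back), dim(tab))
    expect_equal(as.data.frame(channelMap(back)),
                 as.data.frame(channelMap(tab)))
})

test_that("invalid rows are rejected with logged reasons", {
    df <- data.frame(protein_id = c("P1", "P2", "P3"),
                     peptide = c("AAKLR", "AAKMR", "AAKNR"),
                     residues = c("K", "K", "Q"),
                     positions = c("10", "20", "30"),
                     ch1 = c(100, 100, 100), ch2 = c(110, -3, 90),
                     ch3 = c(120, 80, 80), ch4 = c(130, 70, 70))
    f <- writeToyTSV(df, withr::local_tempfile(fileext = ".tsv"))
    expect_message(tab <- readQuantTable(f, toyChannelMap()), "dropped")
    expect_equal(nrow(tab), 1L)
    rej <- S4Vectors::metadata(tab)$rejected
    expect_setequal(rej$reason,
                    c("negative intensity", "residue must be K or Y"))
})

test_that("missing mandatory columns are a hard error naming the column", {
    df <- data.frame(protein_id = "P1", peptide = "AAKLR",
                     residues = "K", positions = "10",
                     ch1 = 1, ch2 = 2, ch3 = 3)  # ch4 absent
    f <- writeToyTSV(df, withr::local_tempfile(fileext = ".tsv"))
    expect_error(readQuantTable(f, toyChannelMap(), quiet = TRUE), "ch4")
    expect_error(readQuantTable(writeToyTSV(df[, -1], f), toyChannelMap(),
                                quiet = TRUE), "protein_id")
})

test_that("site token annotation is parsed, multi-site peptides keyed once", {
    df <- data.frame(protein_id = c("H4", "H4", "P9"),
                     peptide = c("GKGGKGLGK", "GKGGKGLGK", "AAYLR"),
                     sites = c("K6+K9", "K6+K9", "Y354"),
                     ch1 = c(10, 20, 5), ch2 = c(1, 2, 5),
                     ch3 = c(1, 2, 5), ch4 = c(1, 2, 5))
    f <- writeToyTSV(df, withr::local_tempfile(fileext = ".tsv"))
    tab <- readQuantTable(f, toyChannelMap(), quiet = TRUE)
    expect_equal(nrow(tab), 2L)
    expect_match(siteKeys(tab)[1], "K6\\+K9")
    expect_equal(unname(countUnique(tab)), c(2L, 2L))
    expect_equal(S4Vectors::metadata(tab)$n_duplicates_collapsed, 1L)
    # modification derived from residue type
    expect_equal(siteData(tab)$modification, c("acetyl", "phospho"))
})

test_that("duplicate rows collapse to the group-by oracle count", {
    set.seed(42)
    nUnique <- 7L
    dup <- sample(nUnique, 12L, replace = TRUE)  # 12 rows over 7 keys
    df <- data.frame(protein_id = sprintf("P%d", dup),
                     peptide = sprintf("AAK%sR",
                                       strrep("L", dup)),
                     residues = "K", positions = as.character(dup * 3),
                     ch1 = runif(12, 1, 2), ch2 = runif(12, 1, 2),
                     ch3 = runif(12, 1, 2), ch4 = runif(12, 1, 2))
    f <- writeToyTSV(df, withr::local_tempfile(fileext = ".tsv"))
    tab <- readQuantTable(f, toyChannelMap(), quiet = TRUE)
    # independent oracle: aggregate rows by the (protein, site, peptide) key
    key <- paste(df$protein_id, df$positions, df$peptide)
    oracle <- aggregate(df[, c("ch1", "ch2", "ch3", "ch4")],
                        by = list(key = key), FUN = sum)
    expect_equal(nrow(tab), nrow(oracle))
    got <- intensityMatrix(tab)
    ord <- match(paste(siteData(tab)$protein_id, siteData(tab)$positions,
                       siteData(tab)$peptide), oracle$key)
    expect_equal(unname(got),
                 unname(as.matrix(oracle[ord, c("ch1", "ch2", "ch3", "ch4")])),
                 tolerance = 1e-12)
    # "max" collapse is the documented alternative
    tabMax <- readQuantTable(f, toyChannelMap(), dedup = "max", quiet = TRUE)
    oracleMax <- aggregate(df$ch1, by = list(key = key), FUN = max)
    expect_equal(unname(intensityMatrix(tabMax)[, "ch1"]),
                 oracleMax$x[ord])
})

test_that("countUnique is invariant under row permutation and duplication", {
    sim <- generateDataset(syntheticConfig(n_sites = 10L, seed = 9))
    tab <- sim$table
    base <- countUnique(tab)
    expect_equal(base[["n_peptide_sites"]], 10L)
    # truth-record oracle: cardinality of the generator's site keys
    expect_equal(base[["n_peptide_sites"]],
                 length(unique(sim$truth$site_key)))
    expect_equal(base[["n_proteins"]],
                 length(unique(siteData(tab)$protein_id)))
    perm <- sample(nrow(tab))
    expect_equal(countUnique(tab[perm, ]), base)
    expect_equal(countUnique(tab[c(seq_len(nrow(tab)), 1L, 3L), ]), base)
    # empty table
    expect_equal(unname(countUnique(tab[0, ])), c(0L, 0L))
})

test_that("writeResults is deterministic and conserves cardinality", {
    bundle <- suppressWarnings(runPipeline(list(
        simulate = list(n_sites = 25L), seed = 11L,
        clustering = list(nGrid = 6L))))
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeResults(bundle, d1)
    writeResults(bundle, d2)
    for (f in c("quant_table.tsv", "profiles.tsv",
                "cluster_assignments.tsv")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }
    cl <- read.delim(file.path(d1, "cluster_assignments.tsv"))
    expect_equal(nrow(cl), nrow(profileMatrix(bundle$profiles)))
    expect_true(file.exists(file.path(d1, "manifest.json")))
    man <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
    expect_equal(man$stages$load$n_sites, 25L)
})
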