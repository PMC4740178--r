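test_that("beta matrix TSV/CSV round-trip preserves values, ids and missingness bitwise", {
    m <- makeBetaMatrix(20, 6, seed = 11, naCells = 7)
    m[3, 2] <- 1 / 3  # full-precision double must survive serialization
    for (dialect in c("tsv", "csv")) {
        path <- tempfile(fileext = paste0(".", dialect))
        writeBetaMatrix(m, path, dialect = dialect)
        bs <- readBetaMatrix(path, dialect = dialect)
        expect_identical(betaValues(bs), m)
        expect_identical(probeIds(bs), rownames(m))
        expect_identical(sampleIds(bs), colnames(m))
    }
})

test_that("beta reader rejects out-of-range values, duplicates and ragged rows", {
    path <- tempfile()
    writeLines(c("probe_id\tS1\tS2", "cg1\t0.5\t1.2", "cg2\t0.1\t0.2"), path)
    expect_error(readBetaMatrix(path), "cg1.*S2|S2.*cg1")

    writeLines(c("probe_id\tS1\tS1", "cg1\t0.5\t0.2"), path)
    expect_error(readBetaMatrix(path), "duplicate sample ids.*S1")

    writeLines(c("probe_id\tS1\tS2", "cg1\t0.5\t0.2", "cg1\t0.1\t0.2"),
               path)
    expect_error(readBetaMatrix(path), "duplicate probe ids.*cg1")

    writeLines(c("probe_id\tS1\tS2", "cg1\t0.5\t0.2", "cg2\t0.1"), path)
    expect_error(readBetaMatrix(path), "ragged")

    writeLines(c("probe_id\tS1\tS2", "cg1\t0.5\tabc"), path)
    expect_error(readBetaMatrix(path), "non-numeric.*abc")

    ## NA tokens become missing cells, not errors
    writeLines(c("probe_id\tS1\tS2", "cg1\tNA\tNaN", "cg2\t\t0.5"), path)
    bs <- readBetaMatrix(path)
    expect_identical(sum(is.na(betaValues(bs))), 3L)
})

test_that("sample sheet reader counts groups and enforces schema and pairing", {
    path <- tempfile(fileext = ".csv")
    df <- makeSheet(sprintf("s%03d", 1:92),
                    rep(c("N", "NADJ"), c(50, 42)))
    write.csv(df, path, row.names = FALSE)
    sheet <- readSampleSheet(path)
    expect_equal(as.vector(table(sheet$group)[c("N", "NADJ")]), c(50, 42))

    write.csv(data.frame(sample_id = "s1"), path, row.names = FALSE)
    expect_error(readSampleSheet(path), "group")

    ## two NADJ samples sharing a pair id violate the one-NADJ-one-C rule
    bad <- makeSheet(c("a", "b", "c"), c("NADJ", "NADJ", "C"),
                     c("p1", "p1", NA))
    write.csv(bad, path, row.names = FALSE)
    expect_error(readSampleSheet(path), "pair_id 'p1'")

    ## non-canonical labels are permitted but reported
    odd <- makeSheet(c("a", "b"), c("tumour", "normal"))
    write.csv(odd, path, row.names = FALSE)
    expect_message(readSampleSheet(path), "non-canonical")
})

test_that("BetaSet validity rejects values outside [0,1] and missing dimnames", {
    m <- makeBetaMatrix(4, 3)
    m2 <- m; m2[2, 1] <- -0.01
    expect_error(BetaSet(m2), "out of \\[0,1\\]")
    m3 <- m; rownames(m3) <- NULL
    expect_error(BetaSet(m3), "rownames")
    expect_error(BetaSet(m, makeSheet("S01", "N")), "absent from sample sheet")
})

test_that("probe annotation reader validates ids, positions and flag columns", {
    path <- tempfile()
    writeLines(c("probe_id\tchrom\tposition\tregion_class\tDHS",
                 "cg1\tchr1\t100\tTSS200\tTRUE",
                 "cg2\tchr1\t500\tBody\tFALSE"), path)
    ann <- readProbeAnnotation(path)
    expect_true(is.logical(ann$DHS))
    expect_identical(ann$DHS, c(TRUE, FALSE))

    writeLines(c("probe_id\tchrom\tposition\tregion_class",
                 "cg1\tchr1\t0\tBody"), path)
    expect_error(readProbeAnnotation(path), ">= 1")
    writeLines(c("probe_id\tchrom\tposition\tregion_class",
                 "cg1\tchr1\t10\tBody", "cg1\tchr2\t20\tBody"), path)
    expect_error(readProbeAnnotation(path), "duplicate probe_id")
})

test_that("BED membership uses 0-based half-open intervals converted to 1-based", {
    ann <- S4Vectors::DataFrame(probe_id = c("cg1", "cg2", "cg3"),
                                chrom = c("chr1", "chr1", "chr2"),
                                position = c(100L, 101L, 100L),
                                region_class = "Body")
    bed <- tempfile(fileext = ".bed")
    ## covers 1-based position 100 only, on chr1
    writeLines("chr1\t99\t100\tregion1", bed)
    out <- addBedMembership(ann, bed, "inPeak")
    expect_identical(out$inPeak, c(TRUE, FALSE, FALSE))
})

test_that("RRBS window averaging honours window, coverage, chromosome and row order", {
    ann <- S4Vectors::DataFrame(probe_id = c("cgA", "cgB"),
                                chrom = c("chr1", "chr1"),
                                position = c(1000L, 5000L),
                                region_class = "Body")
    rrbs <- S4Vectors::DataFrame(
        chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
        position = c(950L, 1080L, 1101L, 1000L, 900L),
        meth_fraction = c(0.2, 0.4, 0.9, 0.9, 0.5),
        coverage = c(25L, 30L, 50L, 50L, 5L))
    v <- mapArrayToRrbs(ann, rrbs)
    ## in-window loci: 950 (0.2) and 1080 (0.4); 1101 outside, chr2
    ## ignored, 900 (exactly 100 bp away) would qualify but fails coverage
    expect_equal(unname(v["cgA"]), 0.3)
    expect_true(is.na(v["cgB"]))

    ## boundary is inclusive: a covered locus exactly 100 bp away counts
    rrbs$coverage[5] <- 20L
    v2 <- mapArrayToRrbs(ann, rrbs)
    expect_equal(unname(v2["cgA"]), mean(c(0.5, 0.2, 0.4)))

    ## invariant to RRBS row order
    perm <- c(3, 5, 1, 4, 2)
    expect_identical(mapArrayToRrbs(ann, rrbs[perm, ]), v2)
    expect_error(mapArrayToRrbs(ann, rrbs, halfWindow = -1),
                 "non-negative")
})
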