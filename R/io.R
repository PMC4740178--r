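## Readers/writers for the plain-text interchange formats: beta matrices
## (TSV/CSV, probes x samples), sample sheets (CSV), probe annotation (TSV
## plus optional BED-derived membership flags) and RRBS locus tables.

.NA_TOKENS <- c("NA", "NaN", "")

.sepFor <- function(dialect) switch(match.arg(dialect, c("tsv", "csv")),
                                    tsv = "\t", csv = ",")

#' Read a beta-value matrix
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Cells must be numeric in \[0,1\] or one of the missing tokens
#' `"NA"`, `"NaN"`, `""`. Out-of-range or non-numeric values are an error
#' (never clipped); duplicate probe or sample ids and ragged rows are
#' errors.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param sampleInfo optional sample sheet forwarded to [BetaSet()].
#' @return a [BetaSet-class].
#' @export
readBetaMatrix <- function(path, dialect = c("tsv", "csv"),
                           sampleInfo = NULL) {
    sep <- .sepFor(dialect)
    lines <- readLines(path)
    if (length(lines) < 1L) stop("empty file: ", path)
    fields <- strsplit(lines, sep, fixed = TRUE)
    header <- fields[[1L]]
    ## header may or may not carry a leading cell for the probe-id column
    body <- fields[-1L]
    if (length(body) == 0L) stop("no data rows in ", path)
    ncell <- lengths(body)
    if (length(unique(ncell)) != 1L)
        stop("ragged rows in ", path, ": rows have ",
             paste(unique(ncell), collapse = ", "), " fields")
    nc <- ncell[1L] - 1L
    samples <- if (length(header) == nc) header else header[-1L]
    if (length(samples) != nc)
        stop("header of ", path, " has ", length(samples),
             " sample ids but rows have ", nc, " value fields")
    probes <- vapply(body, `[`, character(1L), 1L)
    raw <- t(vapply(body, function(f) f[-1L], character(nc)))
    if (nc == 1L) raw <- matrix(raw, ncol = 1L)
    vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
    miss <- raw %in% .NA_TOKENS
    dim(miss) <- dim(raw)
    badnum <- which(is.na(vals) & !miss, arr.ind = TRUE)
    if (nrow(badnum) > 0)
        stop(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                     raw[badnum[1, 1], badnum[1, 2]],
                     probes[badnum[1, 1]], samples[badnum[1, 2]]))
    vals[miss] <- NA_real_
    dimnames(vals) <- list(probes, samples)
    BetaSet(vals, sampleInfo = sampleInfo)
}

#' Write a beta-value matrix
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round-trip reproduces the double-precision matrix bitwise; missing cells
#' are written as `NA`.
#'
#' @param x a [BetaSet-class] or numeric matrix with dimnames.
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeBetaMatrix <- function(x, path, dialect = c("tsv", "csv")) {
    sep <- .sepFor(dialect)
    m <- if (is(x, "BetaSet")) betaValues(x) else as.matrix(x)
    chr <- vapply(seq_len(ncol(m)), function(j)
        formatC(m[, j], digits = 17, format = "g"), character(nrow(m)))
    if (nrow(m) == 1L) chr <- matrix(chr, nrow = 1L)
    chr[is.na(m)] <- "NA"
    chr <- gsub(" ", "", chr, fixed = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("probe_id", colnames(m)), collapse = sep), con)
    writeLines(paste(rownames(m),
                     apply(chr, 1L, paste, collapse = sep), sep = sep), con)
    invisible(path)
}

#' Read a sample sheet
#'
#' CSV with required columns `sample_id` and `group`; optional `pair_id`
#' and free covariate columns. Pairing and duplicate rules are enforced by
#' [validateSampleSheet()].
#'
#' @param path CSV file path.
#' @return a validated [S4Vectors::DataFrame].
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = .NA_TOKENS)
    validateSampleSheet(df)
}

#' Write a sample sheet
#' @param sheet sample sheet (`data.frame`/`DataFrame`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSampleSheet <- function(sheet, path) {
    utils::write.csv(as.data.frame(sheet), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Read probe annotation
#'
#' TSV with fixed columns `probe_id`, `chrom`, `position`, `region_class`;
#' every further column is interpreted as a logical set-membership flag
#' (TFBS sets, DHS, cross-reactive/polymorphic, ...). Positions are 1-based.
#'
#' @param path TSV file path.
#' @return a [S4Vectors::DataFrame] keyed by `probe_id`.
#' @export
readProbeAnnotation <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            na.strings = .NA_TOKENS)
    need <- c("probe_id", "chrom", "position", "region_class")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0)
        stop("probe annotation lacks column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$probe_id))
        stop("duplicate probe_id in annotation: ",
             paste(unique(df$probe_id[duplicated(df$probe_id)]),
                   collapse = ", "))
    if (any(df$position < 1, na.rm = TRUE))
        stop("probe positions must be >= 1 (1-based coordinates)")
    extra <- setdiff(colnames(df), need)
    for (col in extra) {
        v <- df[[col]]
        if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
        df[[col]] <- as.logical(v)
    }
    as(df, "DataFrame")
}

#' Flag probes falling in BED intervals
#'
#' Adds a logical membership column to a probe annotation from a BED file
#' (0-based half-open intervals, converted to 1-based positions on import).
#' A probe is flagged when its CpG position lies inside any interval;
#' strand is ignored.
#'
#' @param annotation probe annotation as from [readProbeAnnotation()].
#' @param bedPath BED file path.
#' @param name name of the new membership column.
#' @return the annotation with the added logical column.
#' @export
addBedMembership <- function(annotation, bedPath, name) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("rtracklayer is required to import BED files")
    iv <- rtracklayer::import(bedPath, format = "BED")
    pr <- GenomicRanges::GRanges(
        as.character(annotation$chrom),
        IRanges::IRanges(annotation$position, annotation$position))
    hits <- GenomicRanges::findOverlaps(pr, iv, ignore.strand = TRUE)
    flag <- logical(nrow(annotation))
    flag[unique(S4Vectors::queryHits(hits))] <- TRUE
    annotation[[name]] <- flag
    annotation
}

#' Read an RRBS locus table
#'
#' TSV with columns `chrom`, `position` (1-based), `meth_fraction` in
#' \[0,1\] and non-negative integer `coverage`; rows must be unique on
#' (chrom, position).
#'
#' @param path TSV file path.
#' @return a [S4Vectors::DataFrame].
#' @export
readRrbsTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            na.strings = .NA_TOKENS)
    need <- c("chrom", "position", "meth_fraction", "coverage")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0)
        stop("RRBS table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(df$meth_fraction < 0 | df$meth_fraction > 1, na.rm = TRUE))
        stop("RRBS meth_fraction outside [0,1]")
    if (any(df$coverage < 0, na.rm = TRUE))
        stop("RRBS coverage must be non-negative")
    key <- paste(df$chrom, df$position)
    if (anyDuplicated(key))
        stop("duplicate (chrom, position) rows in RRBS table: ",
             paste(utils::head(unique(key[duplicated(key)]), 3),
                   collapse = "; "))
    as(df, "DataFrame")
}

#' Average RRBS methylation around array probes
#'
#' Maps sequencing-based methylation fractions onto array probes: RRBS loci
#' with coverage at or above `minCoverage` that lie within `halfWindow`
#' base pairs on either side of a probe's CpG (closed interval, same
#' chromosome) are averaged without weighting. Probes with no qualifying
#' locus are returned as `NA`.
#'
#' @param annotation probe annotation with `probe_id`, `chrom`, `position`.
#' @param rrbs RRBS table as from [readRrbsTable()].
#' @param halfWindow window half-width in bp (default 100, so a 200-bp
#'   window centred on the probe).
#' @param minCoverage minimum read coverage for a locus to qualify
#'   (default 20).
#' @return named numeric vector of averaged methylation fractions, one per
#'   probe (`NA` when no locus qualifies).
#' @export
mapArrayToRrbs <- function(annotation, rrbs, halfWindow = 100,
                           minCoverage = 20) {
    if (halfWindow < 0) stop("halfWindow must be non-negative")
    rrbs <- rrbs[!is.na(rrbs$coverage) & rrbs$coverage >= minCoverage, ,
                 drop = FALSE]
    out <- rep(NA_real_, nrow(annotation))
    names(out) <- annotation$probe_id
    if (nrow(rrbs) == 0) return(out)
    win <- GenomicRanges::GRanges(
        as.character(annotation$chrom),
        IRanges::IRanges(pmax(1, annotation$position - halfWindow),
                         annotation$position + halfWindow))
    loci <- GenomicRanges::GRanges(
        as.character(rrbs$chrom),
        IRanges::IRanges(rrbs$position, rrbs$position))
    hits <- GenomicRanges::findOverlaps(win, loci)
    if (length(hits) > 0) {
        mf <- rrbs$meth_fraction[S4Vectors::subjectHits(hits)]
        agg <- tapply(mf, S4Vectors::queryHits(hits), mean)
        out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
}
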