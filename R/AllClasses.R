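#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
NULL

#' BetaSet: a probes x samples matrix of DNA methylation beta-values
#'
#' `BetaSet` extends [SummarizedExperiment::SummarizedExperiment] and holds a
#' single assay named `"beta"` of methylation fractions in \[0, 1\] (missing
#' values allowed as `NA`). `colData` carries the sample sheet (at minimum a
#' `group` column; optionally `pair_id` linking a normal-adjacent sample to
#' its matched tumour, and free covariate columns). `rowData` may carry probe
#' annotation (chromosome, position, gene-region class, set-membership
#' flags).
#'
#' @slot .. see SummarizedExperiment.
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

.validBetaMatrix <- function(m) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("beta matrix must have probe rownames and sample colnames")
    if (anyDuplicated(rownames(m))) {
        d <- unique(rownames(m)[duplicated(rownames(m))])
        return(sprintf("duplicate probe ids: %s",
                       paste(utils::head(d, 5), collapse = ", ")))
    }
    if (anyDuplicated(colnames(m))) {
        d <- unique(colnames(m)[duplicated(colnames(m))])
        return(sprintf("duplicate sample ids: %s",
                       paste(utils::head(d, 5), collapse = ", ")))
    }
    if (!is.numeric(m))
        return("beta values must be numeric")
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        return(sprintf(
            "beta value out of [0,1]: %.6g at probe '%s', sample '%s' (%d offending cell%s)",
            m[i, j], rownames(m)[i], colnames(m)[j], nrow(bad),
            if (nrow(bad) > 1) "s" else ""))
    }
    TRUE
}

setValidity("BetaSet", function(object) {
    if (!"beta" %in% assayNames(object))
        return("BetaSet requires an assay named 'beta'")
    .validBetaMatrix(assay(object, "beta"))
})

#' Validate a sample sheet
#'
#' Checks the sample-sheet contract: a `sample_id` and a `group` column are
#' required; when a `pair_id` column is present, every non-missing pair id
#' must link exactly two samples from two different groups (with the
#' canonical vocabulary, exactly one normal-adjacent `NADJ` and one cancer
#' `C` sample). Group labels outside the canonical `{N, NADJ, C}` set are
#' permitted but reported via a message.
#'
#' @param sheet a `data.frame` or `DataFrame`.
#' @return the sheet as a [S4Vectors::DataFrame], invisibly validated.
#' @export
validateSampleSheet <- function(sheet) {
    sheet <- as(as.data.frame(sheet), "DataFrame")
    for (col in c("sample_id", "group"))
        if (!col %in% colnames(sheet))
            stop("sample sheet lacks required column '", col, "'")
    if (anyDuplicated(sheet$sample_id))
        stop("duplicate sample_id in sample sheet: ",
             paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                   collapse = ", "))
    known <- c("N", "NADJ", "C")
    unknown <- setdiff(unique(as.character(sheet$group)), known)
    if (length(unknown) > 0)
        message("sample sheet contains non-canonical group label(s): ",
                paste(unknown, collapse = ", "))
    if ("pair_id" %in% colnames(sheet)) {
        pid <- as.character(sheet$pair_id)
        keep <- !is.na(pid) & pid != ""
        if (any(keep)) {
            for (p in unique(pid[keep])) {
                g <- as.character(sheet$group[keep & pid == p])
                if (length(g) != 2L || g[1L] == g[2L])
                    stop("pair_id '", p, "' must link exactly two samples ",
                         "from two different groups (got groups: ",
                         paste(g, collapse = ", "), ")")
                if (all(c("NADJ", "C") %in% sheet$group) &&
                    !setequal(g, c("NADJ", "C")))
                    stop("pair_id '", p, "' must link one NADJ and one C ",
                         "sample (got: ", paste(g, collapse = ", "), ")")
            }
        }
    }
    sheet
}

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta-values in \[0,1\] with probe rownames
#'   and sample colnames; `NA` marks missing values.
#' @param sampleInfo optional sample sheet (`data.frame`/`DataFrame`) with a
#'   `sample_id` column matching `colnames(beta)`; validated with
#'   [validateSampleSheet()].
#' @param probeInfo optional probe annotation with a `probe_id` column
#'   matching `rownames(beta)`.
#' @return a [BetaSet-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' bs <- BetaSet(b, data.frame(sample_id = c("s1", "s2"),
#'                             group = c("N", "NADJ")))
#' @export
BetaSet <- function(beta, sampleInfo = NULL, probeInfo = NULL) {
    beta <- as.matrix(beta)
    msg <- .validBetaMatrix(beta)
    if (!isTRUE(msg)) stop(msg)
    cd <- DataFrame(row.names = colnames(beta))
    if (!is.null(sampleInfo)) {
        sampleInfo <- validateSampleSheet(sampleInfo)
        miss <- setdiff(colnames(beta), sampleInfo$sample_id)
        if (length(miss) > 0)
            stop("samples absent from sample sheet: ",
                 paste(miss, collapse = ", "))
        cd <- sampleInfo[match(colnames(beta), sampleInfo$sample_id), ,
                         drop = FALSE]
        rownames(cd) <- colnames(beta)
    }
    rd <- DataFrame(row.names = rownames(beta))
    if (!is.null(probeInfo)) {
        probeInfo <- as(as.data.frame(probeInfo), "DataFrame")
        if (!"probe_id" %in% colnames(probeInfo))
            stop("probe annotation lacks 'probe_id' column")
        idx <- match(rownames(beta), probeInfo$probe_id)
        rd <- probeInfo[idx, , drop = FALSE]
        rownames(rd) <- rownames(beta)
    }
    new("BetaSet", SummarizedExperiment(
        assays = SimpleList(beta = beta), colData = cd, rowData = rd))
}

#' Differential-variability / differential-methylation results
#'
#' Output of [runIEVORA()]: the retained DVMC table (one row per probe
#' passing both the Bartlett FDR screen and the t-test filter, ranked by
#' absolute t-statistic), a side table of probes excluded from testing (too
#' few usable values or zero variance), and the run parameters.
#'
#' @slot table `DataFrame` with columns probe_id, t_stat, t_pvalue,
#'   log2_var_ratio, bartlett_stat, bartlett_pvalue, bartlett_qvalue,
#'   mean_control, mean_case, category, rank.
#' @slot excluded `DataFrame` with columns probe_id, reason.
#' @slot params list of run parameters (groups, thresholds, fdr method).
#' @slot nTested number of probes entering the Bartlett screen.
#' @slot nUniverse number of probes in the input matrix.
#' @export
setClass("DvmcResults",
    representation(table = "DataFrame", excluded = "DataFrame",
                   params = "list", nTested = "integer",
                   nUniverse = "integer"))

setValidity("DvmcResults", function(object) {
    tab <- object@table
    need <- c("probe_id", "t_stat", "t_pvalue", "log2_var_ratio",
              "bartlett_pvalue", "bartlett_qvalue", "category", "rank")
    if (!all(need %in% colnames(tab)))
        return("DVMC table lacks required columns")
    if (nrow(tab) > 0) {
        ok <- c("dvUPdmUP", "dvUPdmDN", "dvDNdmUP", "dvDNdmDN")
        if (!all(tab$category %in% ok))
            return("invalid DVMC category label")
        if (any(diff(abs(tab$t_stat)) > 1e-12))
            return("DVMC table must be ranked by |t_stat| descending")
    }
    TRUE
})

#' Per-sample deviation z-scores against a reference group
#'
#' Output of [deviationZ()]: z-statistics of each target sample's beta-value
#' relative to the reference-group mean and standard deviation at each
#' probe, the matching two-sided normal p-values, and the binary hit matrix
#' at the chosen p-value threshold.
#'
#' @slot z probes x samples matrix of z-statistics.
#' @slot p matching two-sided p-values.
#' @slot hits binary matrix, 1 where `p < pThreshold`.
#' @slot pThreshold the binarization cutoff.
#' @slot refStats `DataFrame` of per-probe reference mean, sd and n.
#' @slot excludedProbes probes excluded (reference n < 3 or sd = 0).
#' @export
setClass("DeviationSet",
    representation(z = "matrix", p = "matrix", hits = "matrix",
                   pThreshold = "numeric", refStats = "DataFrame",
                   excludedProbes = "character"))

setValidity("DeviationSet", function(object) {
    if (!all(dim(object@z) == dim(object@p)) ||
        !all(dim(object@z) == dim(object@hits)))
        return("z, p and hits matrices must share dimensions")
    exp_hits <- (object@p < object@pThreshold) * 1L
    exp_hits[is.na(object@p)] <- NA_integer_
    if (!identical(is.na(exp_hits), is.na(object@hits)) ||
        any(exp_hits != object@hits, na.rm = TRUE))
        return("hits must equal (p < pThreshold)")
    TRUE
})

#' Reference centroid profiles for cell-fraction deconvolution
#'
#' Marker-probe centroids for each cell type (e.g. HMEC and adipose), built
#' by [buildReference()] from two cell-type profiles: markers are the probes
#' with absolute beta difference strictly above the threshold that also lie
#' in DNase hypersensitive sites.
#'
#' @slot centroids markers x cell-types matrix of mean beta values.
#' @slot deltaThreshold beta-difference threshold used for selection.
#' @slot criteria list recording the selection criteria.
#' @export
setClass("ReferenceProfiles",
    representation(centroids = "matrix", deltaThreshold = "numeric",
                   criteria = "list"))

setValidity("ReferenceProfiles", function(object) {
    m <- object@centroids
    if (nrow(m) == 0) return("marker set is empty")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("centroids need marker rownames and cell-type colnames")
    if (any(is.na(m)) || any(m < 0 | m > 1))
        return("centroid values must lie in [0,1]")
    TRUE
})

#' Per-sample cell-type fractions from constrained projection
#'
#' Output of [estimateFractions()]: non-negative, sum-to-one weights per
#' sample (e.g. `w_HMEC`, `w_FAT`) and the residual sum of squares of the
#' projection.
#'
#' @slot weights samples x cell-types matrix of fractions.
#' @slot residuals per-sample residual sum of squares.
#' @export
setClass("CellFractions",
    representation(weights = "matrix", residuals = "numeric"))

setValidity("CellFractions", function(object) {
    w <- object@weights
    if (any(w < -1e-6)) return("weights must be non-negative")
    if (any(abs(rowSums(w) - 1) > 1e-6))
        return("weights must sum to one within 1e-6")
    if (length(object@residuals) != nrow(w))
        return("one residual per sample required")
    TRUE
})
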