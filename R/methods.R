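#' Accessors for BetaSet
#'
#' @param x a [BetaSet-class].
#' @return `betaValues` the beta matrix; `sampleGroups` the group factor;
#'   `pairIds` the matched-pair keys (NA when absent); `probeIds` /
#'   `sampleIds` the identifiers.
#' @name BetaSet-accessors
NULL

#' @rdname BetaSet-accessors
#' @export
setMethod("betaValues", "BetaSet", function(x) assay(x, "beta"))

#' @rdname BetaSet-accessors
#' @export
setMethod("sampleGroups", "BetaSet", function(x) {
    if (!"group" %in% colnames(colData(x)))
        stop("BetaSet carries no 'group' column in colData")
    as.character(colData(x)$group)
})

#' @rdname BetaSet-accessors
#' @export
setMethod("pairIds", "BetaSet", function(x) {
    if (!"pair_id" %in% colnames(colData(x)))
        return(rep(NA_character_, ncol(x)))
    as.character(colData(x)$pair_id)
})

#' @rdname BetaSet-accessors
#' @export
setMethod("probeIds", "BetaSet", function(x) rownames(x))

#' @rdname BetaSet-accessors
#' @export
setMethod("sampleIds", "BetaSet", function(x) colnames(x))

setMethod("show", "BetaSet", function(object) {
    cat(sprintf("BetaSet: %d probes x %d samples\n",
                nrow(object), ncol(object)))
    if ("group" %in% colnames(colData(object))) {
        tab <- table(colData(object)$group)
        cat("  groups:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
    nmiss <- sum(is.na(assay(object, "beta")))
    cat(sprintf("  missing cells: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(assay(object, "beta"))))
})

#' Accessors for DvmcResults
#'
#' @param x a [DvmcResults-class].
#' @name DvmcResults-accessors
NULL

#' @rdname DvmcResults-accessors
#' @export
setMethod("dvmcTable", "DvmcResults", function(x) x@table)

#' @rdname DvmcResults-accessors
#' @export
setMethod("excludedProbes", "DvmcResults", function(x) x@excluded)

#' Category counts of a DVMC table
#'
#' @param object a [DvmcResults-class].
#' @param ... ignored.
#' @return named integer vector of counts over the four DVMC categories,
#'   plus `n_selected`, `n_tested` and the selected fraction of the tested
#'   universe.
#' @export
setMethod("summary", "DvmcResults", function(object, ...) {
    cats <- c("dvUPdmUP", "dvUPdmDN", "dvDNdmUP", "dvDNdmDN")
    cnt <- vapply(cats, function(k) sum(object@table$category == k), 0L)
    c(cnt, n_selected = nrow(object@table), n_tested = object@nTested,
      frac_of_tested = if (object@nTested > 0)
          nrow(object@table) / object@nTested else NA_real_)
})

setMethod("show", "DvmcResults", function(object) {
    s <- summary(object)
    cat(sprintf("DvmcResults: %d DVMCs of %d probes tested (%.3g%%)\n",
                s[["n_selected"]], s[["n_tested"]],
                100 * s[["frac_of_tested"]]))
    cat(sprintf("  dvUPdmUP=%d dvUPdmDN=%d dvDNdmUP=%d dvDNdmDN=%d\n",
                s[["dvUPdmUP"]], s[["dvUPdmDN"]], s[["dvDNdmUP"]],
                s[["dvDNdmDN"]]))
    cat(sprintf("  excluded from testing: %d probes\n",
                nrow(object@excluded)))
    cat(sprintf("  thresholds: Bartlett %s-FDR < %g, t-test p < %g\n",
                object@params$fdrMethod, object@params$dvFdr,
                object@params$dmP))
})

#' Accessors for DeviationSet
#'
#' @param x a [DeviationSet-class].
#' @name DeviationSet-accessors
NULL

#' @rdname DeviationSet-accessors
#' @export
setMethod("zMatrix", "DeviationSet", function(x) x@z)

#' @rdname DeviationSet-accessors
#' @export
setMethod("pMatrix", "DeviationSet", function(x) x@p)

#' @rdname DeviationSet-accessors
#' @export
setMethod("hitMatrix", "DeviationSet", function(x) x@hits)

#' @rdname DeviationSet-accessors
#' @export
setMethod("pThreshold", "DeviationSet", function(x) x@pThreshold)

#' @rdname DeviationSet-accessors
#' @export
setMethod("refStats", "DeviationSet", function(x) x@refStats)

setMethod("show", "DeviationSet", function(object) {
    cat(sprintf("DeviationSet: %d probes x %d samples (p threshold %g)\n",
                nrow(object@z), ncol(object@z), object@pThreshold))
    cat(sprintf("  hits: %d (%.3g%% of entries); excluded probes: %d\n",
                sum(object@hits, na.rm = TRUE),
                100 * mean(object@hits, na.rm = TRUE),
                length(object@excludedProbes)))
})

#' Accessors for ReferenceProfiles
#'
#' @param x a [ReferenceProfiles-class].
#' @name ReferenceProfiles-accessors
NULL

#' @rdname ReferenceProfiles-accessors
#' @export
setMethod("markerIds", "ReferenceProfiles", function(x)
    rownames(x@centroids))

#' @rdname ReferenceProfiles-accessors
#' @export
setMethod("centroids", "ReferenceProfiles", function(x) x@centroids)

setMethod("show", "ReferenceProfiles", function(object) {
    cat(sprintf(
        "ReferenceProfiles: %d marker CpGs x %d cell types (%s); |delta beta| > %g\n",
        nrow(object@centroids), ncol(object@centroids),
        paste(colnames(object@centroids), collapse = ", "),
        object@deltaThreshold))
})

#' Accessors for CellFractions
#'
#' @param x a [CellFractions-class].
#' @name CellFractions-accessors
NULL

#' @rdname CellFractions-accessors
#' @export
setMethod("fractionWeights", "CellFractions", function(x) x@weights)

#' @rdname CellFractions-accessors
#' @export
setMethod("fitResiduals", "CellFractions", function(x) x@residuals)

setMethod("show", "CellFractions", function(object) {
    cat(sprintf("CellFractions: %d samples x %d cell types (%s)\n",
                nrow(object@weights), ncol(object@weights),
                paste(colnames(object@weights), collapse = ", ")))
    mu <- colMeans(object@weights)
    cat("  mean fractions:",
        paste(sprintf("%s=%.3f", names(mu), mu), collapse = ", "), "\n")
})
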