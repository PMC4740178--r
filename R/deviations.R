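## Outlier z-deviation calling against a normal reference group, and
## binarization into probes x samples hit matrices.

#' Per-sample deviation z-scores against a reference group
#'
#' For each probe and target sample, computes
#' \eqn{z = (\beta - \mu_{ref}) / s_{ref}} where \eqn{\mu_{ref}} and
#' \eqn{s_{ref}} are the mean and (n-1 denominator) standard deviation of
#' the probe over the reference-group samples, together with a two-sided
#' standard-normal p-value. Hits are entries with `p < pThreshold`
#' (strict). The sign of z is retained so hyper- and hypomethylation
#' deviations stay distinguishable.
#'
#' Probes with fewer than `minRefSize` non-missing reference values or
#' zero reference standard deviation are excluded and reported in
#' `excludedProbes`.
#'
#' @param bs a [BetaSet-class] with a `group` column.
#' @param refGroup reference group label (e.g. `"N"`).
#' @param targetSamples sample ids to score; default all samples outside
#'   the reference group.
#' @param pThreshold binarization cutoff (default 0.001; in the
#'   field-defect setting this corresponds roughly to an FDR of ~0.05).
#' @param minRefSize minimum reference values per probe (default 3).
#' @return a [DeviationSet-class].
#' @export
deviationZ <- function(bs, refGroup = "N", targetSamples = NULL,
                       pThreshold = 0.001, minRefSize = 3) {
    grp <- sampleGroups(bs)
    if (!refGroup %in% grp)
        stop("reference group '", refGroup, "' absent from sample sheet")
    if (is.null(targetSamples))
        targetSamples <- sampleIds(bs)[grp != refGroup]
    missing <- setdiff(targetSamples, sampleIds(bs))
    if (length(missing) > 0)
        stop("target sample(s) absent: ", paste(missing, collapse = ", "))
    m <- betaValues(bs)
    R <- m[, grp == refGroup, drop = FALSE]
    n <- rowSums(!is.na(R))
    mu <- rowMeans(R, na.rm = TRUE)
    sd <- sqrt(rowSums((R - mu)^2, na.rm = TRUE) / pmax(n - 1, 1))
    keep <- n >= minRefSize & sd > 0
    T <- m[keep, targetSamples, drop = FALSE]
    z <- (T - mu[keep]) / sd[keep]
    p <- 2 * stats::pnorm(-abs(z))
    hits <- (p < pThreshold) * 1L
    hits[is.na(p)] <- NA_integer_
    new("DeviationSet", z = z, p = p, hits = hits,
        pThreshold = pThreshold,
        refStats = DataFrame(probe_id = rownames(m)[keep],
                             mean = mu[keep], sd = sd[keep], n = n[keep]),
        excludedProbes = rownames(m)[!keep])
}

#' Re-binarize a deviation set at a new p-value threshold
#'
#' @param dev a [DeviationSet-class].
#' @param pThreshold new cutoff; hits are `p < pThreshold` (strict).
#' @return a [DeviationSet-class] with updated hits and threshold.
#' @export
binarize <- function(dev, pThreshold = 0.001) {
    hits <- (dev@p < pThreshold) * 1L
    hits[is.na(dev@p)] <- NA_integer_
    initialize(dev, hits = hits, pThreshold = pThreshold)
}

#' Alteration frequencies of a hit matrix
#'
#' Per-probe frequencies divide each probe's hit count by the number of
#' samples; per-sample frequencies divide each sample's hit count by the
#' number of probes.
#'
#' @param hits a [DeviationSet-class] or binary matrix.
#' @param axis `"per_probe"` (default) or `"per_sample"`.
#' @return named numeric vector of frequencies in \[0,1\].
#' @export
alterationFrequency <- function(hits, axis = c("per_probe", "per_sample")) {
    axis <- match.arg(axis)
    h <- if (is(hits, "DeviationSet")) hitMatrix(hits) else hits
    if (axis == "per_probe") rowMeans(h, na.rm = TRUE)
    else colMeans(h, na.rm = TRUE)
}
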