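## Per-sample progression scores over DVMC categories: mean z-deviation
## (progression Z), fraction of significant hits, personalized
## tumour-versus-matched-normal deviation, and AUC discrimination.

.resolveProbes <- function(have, want, what = "deviation set") {
    probes <- intersect(want, have)
    if (length(probes) == 0)
        stop("none of the requested probes are present in the ", what)
    probes
}

#' Progression Z-score per sample
#'
#' The unweighted mean of the deviation z-statistics over the probes of a
#' DVMC category, per sample. For hypermethylated categories larger
#' positive scores indicate stronger average deviation from the normal
#' state; for hypomethylated categories stronger hypomethylation shows as
#' larger negative scores.
#'
#' @param dev a [DeviationSet-class].
#' @param categoryProbes probe ids of the category.
#' @return `DataFrame` with sample_id, score, n_probes (probes
#'   contributing after pairwise NA dropping).
#' @export
progressionZ <- function(dev, categoryProbes) {
    probes <- .resolveProbes(rownames(zMatrix(dev)), categoryProbes)
    z <- zMatrix(dev)[probes, , drop = FALSE]
    DataFrame(sample_id = colnames(z),
              score = colMeans(z, na.rm = TRUE),
              n_probes = colSums(!is.na(z)))
}

#' Personalized deviation score per matched pair
#'
#' For each matched tumour / normal-adjacent pair (resolved through
#' `pair_id`), the mean over the category probes of the beta difference
#' tumour minus matched normal-adjacent. Positive scores over a
#' hypermethylated category mean the tumour methylation increased further
#' beyond its own adjacent-normal field defect.
#'
#' @param bs a [BetaSet-class] with `group` and `pair_id` columns.
#' @param categoryProbes probe ids of the category.
#' @param tumourGroup,normalGroup group labels of the pair members.
#' @return `DataFrame` with pair_id, tumour_id, normal_id, score,
#'   n_probes. Samples without a pair are skipped with a warning.
#' @export
personalizedDeviation <- function(bs, categoryProbes, tumourGroup = "C",
                                  normalGroup = "NADJ") {
    probes <- .resolveProbes(probeIds(bs), categoryProbes, "beta matrix")
    grp <- sampleGroups(bs)
    pid <- pairIds(bs)
    inPair <- !is.na(pid) & grp %in% c(tumourGroup, normalGroup)
    unpaired <- sampleIds(bs)[is.na(pid) &
                              grp %in% c(tumourGroup, normalGroup)]
    if (length(unpaired) > 0)
        warning("skipping unpaired sample(s): ",
                paste(unpaired, collapse = ", "))
    pids <- unique(pid[inPair])
    m <- betaValues(bs)[probes, , drop = FALSE]
    res <- lapply(pids, function(p) {
        tid <- sampleIds(bs)[inPair & pid == p & grp == tumourGroup]
        nid <- sampleIds(bs)[inPair & pid == p & grp == normalGroup]
        if (length(tid) != 1L || length(nid) != 1L) return(NULL)
        d <- m[, tid] - m[, nid]
        data.frame(pair_id = p, tumour_id = tid, normal_id = nid,
                   score = mean(d, na.rm = TRUE),
                   n_probes = sum(!is.na(d)))
    })
    as(do.call(rbind, res), "DataFrame")
}

#' Fraction of category probes hit per sample
#'
#' Hit count over the category probes divided by the category size (the
#' number of category probes present in the deviation set).
#'
#' @param dev a [DeviationSet-class].
#' @param categoryProbes probe ids of the category (must intersect the
#'   deviation set; empty category is an error).
#' @return `DataFrame` with sample_id, frac_hits, n_probes.
#' @export
fracHitsScore <- function(dev, categoryProbes) {
    probes <- .resolveProbes(rownames(hitMatrix(dev)), categoryProbes)
    h <- hitMatrix(dev)[probes, , drop = FALSE]
    DataFrame(sample_id = colnames(h),
              frac_hits = colSums(h, na.rm = TRUE) / length(probes),
              n_probes = length(probes))
}

#' AUC discrimination between two groups of scores
#'
#' Area under the ROC curve via the Mann–Whitney U identity (ties counted
#' as 1/2), with a 95% confidence interval from the Hanley–McNeil normal
#' approximation. The positive group is the one expected to score higher.
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels two-group labels, same length.
#' @param positive label of the positive group; default the second level.
#' @return list with `auc`, `ci` (length-2), `nPositive`, `nNegative`.
#' @export
discriminateAUC <- function(scores, labels, positive = NULL) {
    labels <- as.character(labels)
    lv <- unique(labels)
    if (length(lv) != 2) stop("exactly two groups required")
    if (is.null(positive)) positive <- lv[2]
    if (!positive %in% lv) stop("positive label not present")
    pos <- scores[labels == positive]
    neg <- scores[labels != positive]
    if (length(pos) == 0 || length(neg) == 0)
        stop("both groups must be non-empty")
    r <- rank(c(pos, neg))
    n1 <- length(pos); n2 <- length(neg)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    auc <- U / (n1 * n2)
    ## Hanley & McNeil (1982) variance approximation
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
    list(auc = auc,
         ci = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
         nPositive = n1, nNegative = n2)
}
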