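## iEVORA: two-stage differential-variability feature selection.
## Stage 1 screens every CpG with a two-group Bartlett test at a stringent
## FDR; stage 2 regularizes the (outlier-sensitive) variance screen by
## keeping only sites whose difference in mean methylation also reaches
## t-test p < 0.05, and re-ranks the survivors by |t|.

.rowStats <- function(m) {
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mean = mu, var = v)
}

## vectorized two-group Bartlett over rows; returns NA where either group
## has zero variance or fewer than 2 values
.rowBartlett <- function(n1, v1, n2, v2) {
    N <- n1 + n2
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - 2)
    C <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - 2)) / 3
    stat <- ((N - 2) * log(sp) - (n1 - 1) * log(v1) -
             (n2 - 1) * log(v2)) / C
    bad <- !is.finite(stat) | v1 <= 0 | v2 <= 0 | n1 < 2 | n2 < 2
    stat[bad] <- NA_real_
    list(statistic = stat,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

.rowWelch <- function(n1, m1, v1, n2, m2, v2) {
    se2 <- v1 / n1 + v2 / n2
    t <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    list(statistic = t, df = df,
         p.value = 2 * stats::pt(-abs(t), df = df))
}

.rowPooledT <- function(n1, m1, v1, n2, m2, v2) {
    df <- n1 + n2 - 2
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    t <- (m2 - m1) / sqrt(sp * (1 / n1 + 1 / n2))
    list(statistic = t, df = rep(df, length(t)),
         p.value = 2 * stats::pt(-abs(t), df = df))
}

#' Two-group Bartlett test of equal variances
#'
#' Bartlett's statistic for two groups with the standard correction factor,
#' referred to a chi-square distribution with one degree of freedom. Used
#' as the differential-variability screen on per-CpG beta values.
#'
#' @param x numeric values of the control group (NAs dropped).
#' @param y numeric values of the case group.
#' @return list with `statistic`, `p.value`, and `log2.var.ratio`
#'   (log2 of var(y)/var(x), case over control). When either group has
#'   fewer than 2 values or zero variance the statistic is `NA` and the
#'   result is flagged with `degenerate = TRUE`; such probes must be
#'   excluded from testing, never assigned p = 0.
#' @examples
#' bartlettTwoGroup(c(0.1, 0.2, 0.3), c(0.1, 0.3, 0.5))
#' @export
bartlettTwoGroup <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    v1 <- stats::var(x); v2 <- stats::var(y)
    r <- .rowBartlett(length(x), v1, length(y), v2)
    list(statistic = r$statistic, p.value = r$p.value,
         log2.var.ratio = log2(v2 / v1),
         degenerate = is.na(r$statistic))
}

#' Welch two-sample t-test, case minus control
#'
#' Unequal-variance (Welch) t with Welch–Satterthwaite degrees of freedom,
#' two-sided. The sign convention is `mean(y) - mean(x)`: positive
#' t-statistics mean higher methylation in the case group.
#'
#' @param x control-group values (NAs dropped).
#' @param y case-group values.
#' @param pooled use the pooled-variance t instead of Welch.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' welchT(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
#' @export
welchT <- function(x, y, pooled = FALSE) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    f <- if (pooled) .rowPooledT else .rowWelch
    r <- f(length(x), mean(x), stats::var(x),
           length(y), mean(y), stats::var(y))
    list(statistic = r$statistic, df = r$df, p.value = r$p.value)
}

#' Estimate false-discovery-rate q-values
#'
#' `"bh"` gives step-up Benjamini–Hochberg adjusted p-values. `"storey"`
#' scales the BH values by an estimated proportion of true nulls
#' \eqn{\hat\pi_0}, taken as the median over
#' \eqn{\lambda \in \{0.05, 0.10, \ldots, 0.95\}} of
#' \eqn{\#\{p > \lambda\} / (m(1-\lambda))}, clipped to (0, 1]. With a
#' single p-value \eqn{\hat\pi_0 = 1} so q = p.
#'
#' @param p vector of p-values in \[0,1\] (NAs propagated).
#' @param method `"bh"` (default) or `"storey"`.
#' @return q-values, same length and order as `p`, bounded by 1 and
#'   monotone non-decreasing in sorted p.
#' @examples
#' estimateFdr(c(0.01, 0.02, 0.04, 0.05))
#' @export
estimateFdr <- function(p, method = c("bh", "storey")) {
    method <- match.arg(method)
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0,1]")
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    if (method == "storey") {
        m <- sum(ok)
        if (m > 1) {
            lam <- seq(0.05, 0.95, by = 0.05)
            pi0 <- stats::median(vapply(
                lam, function(l) sum(p[ok] > l) / (m * (1 - l)), 0))
            pi0 <- min(max(pi0, .Machine$double.eps), 1)
        } else pi0 <- 1
        q[ok] <- pmin(q[ok] * pi0, 1)
    }
    q
}

#' Run the iEVORA feature-selection algorithm
#'
#' Two-stage selection of differentially variable and differentially
#' methylated CpGs (DVMCs) between a control and a case group of samples.
#' Stage 1: a two-group Bartlett test per probe; probes with FDR q-value
#' below `dvFdr` are differentially variable CpGs (DVCs). Stage 2: because
#' the variance test is overly sensitive to single outliers, DVCs are kept
#' only if their (default Welch) t-test of mean methylation has unadjusted
#' p below `dmP`, and the survivors are re-ranked by absolute t-statistic
#' descending, so sites whose variability reflects a genuine shift in mean
#' methylation rank highest. Each DVMC is labelled with its four-way
#' category: `dvUP`/`dvDN` for higher/lower variance in the case group and
#' `dmUP`/`dmDN` for higher/lower mean methylation (case minus control).
#'
#' Probes where either group has fewer than `minGroupSize` non-missing
#' values, or zero variance, are excluded from testing and reported in the
#' `excluded` side table, never silently dropped.
#'
#' @param bs a [BetaSet-class] with a `group` column in its colData.
#' @param controlGroup,caseGroup group labels (e.g. `"N"` and `"NADJ"`).
#' @param dvFdr FDR threshold of the Bartlett screen (default 0.001).
#' @param dmP unadjusted t-test p threshold (default 0.05).
#' @param fdrMethod `"bh"` (default) or `"storey"`, see [estimateFdr()].
#' @param tVariant `"welch"` (default) or `"pooled"`.
#' @param minGroupSize minimum non-missing values per group (default 3).
#' @return a [DvmcResults-class]. Ties in |t| are broken by smaller
#'   Bartlett q-value, then probe id.
#' @export
runIEVORA <- function(bs, controlGroup = "N", caseGroup = "NADJ",
                      dvFdr = 0.001, dmP = 0.05,
                      fdrMethod = c("bh", "storey"),
                      tVariant = c("welch", "pooled"), minGroupSize = 3) {
    fdrMethod <- match.arg(fdrMethod)
    tVariant <- match.arg(tVariant)
    grp <- sampleGroups(bs)
    for (g in c(controlGroup, caseGroup))
        if (!g %in% grp) stop("group label '", g, "' absent from sample sheet")
    m <- betaValues(bs)
    X <- m[, grp == controlGroup, drop = FALSE]
    Y <- m[, grp == caseGroup, drop = FALSE]
    sx <- .rowStats(X); sy <- .rowStats(Y)

    usable <- sx$n >= minGroupSize & sy$n >= minGroupSize
    nonconst <- sx$var > 0 & sy$var > 0
    reason <- rep(NA_character_, nrow(m))
    reason[!usable] <- sprintf("fewer than %d non-missing values in a group",
                               minGroupSize)
    reason[usable & !nonconst] <- "zero variance in a group"
    test <- usable & nonconst
    excluded <- DataFrame(probe_id = rownames(m)[!test],
                          reason = reason[!test])

    bt <- .rowBartlett(sx$n[test], sx$var[test], sy$n[test], sy$var[test])
    qv <- estimateFdr(bt$p.value, method = fdrMethod)
    tfun <- if (tVariant == "pooled") .rowPooledT else .rowWelch
    tt <- tfun(sx$n[test], sx$mean[test], sx$var[test],
               sy$n[test], sy$mean[test], sy$var[test])

    log2vr <- log2(sy$var[test] / sx$var[test])
    sel <- which(qv < dvFdr & tt$p.value < dmP)
    tab <- DataFrame(
        probe_id = rownames(m)[test][sel],
        t_stat = tt$statistic[sel],
        t_pvalue = tt$p.value[sel],
        log2_var_ratio = log2vr[sel],
        bartlett_stat = bt$statistic[sel],
        bartlett_pvalue = bt$p.value[sel],
        bartlett_qvalue = qv[sel],
        mean_control = sx$mean[test][sel],
        mean_case = sy$mean[test][sel],
        category = paste0(ifelse(log2vr[sel] > 0, "dvUP", "dvDN"),
                          ifelse(tt$statistic[sel] > 0, "dmUP", "dmDN")))
    ord <- order(-abs(tab$t_stat), tab$bartlett_qvalue, tab$probe_id)
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL

    new("DvmcResults", table = tab, excluded = excluded,
        params = list(controlGroup = controlGroup, caseGroup = caseGroup,
                      dvFdr = dvFdr, dmP = dmP, fdrMethod = fdrMethod,
                      tVariant = tVariant, minGroupSize = minGroupSize),
        nTested = sum(test), nUniverse = nrow(m))
}
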