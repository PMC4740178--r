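## Reference-based cell-fraction deconvolution by constrained projection:
## marker selection from two cell-type centroids, simplex-constrained
## least squares for the per-sample weights, and covariate adjustment of
## beta values for estimated fat content.

#' Build reference centroid profiles for deconvolution
#'
#' Markers are exactly the probes whose absolute beta difference between
#' the two cell-type profiles is strictly greater than `deltaThreshold`
#' AND that lie in a DNase hypersensitive site (open chromatin regions
#' being more likely to carry tissue-specific methylation).
#'
#' @param profileA,profileB named numeric vectors of per-probe mean beta
#'   values over a shared probe universe (e.g. an epithelial HMEC centroid
#'   and an averaged adipose centroid).
#' @param dhsProbes character vector of probe ids in DHS regions.
#' @param deltaThreshold strict beta-difference cutoff (default 0.7).
#' @param cellTypeNames names for the two cell types.
#' @return a [ReferenceProfiles-class].
#' @export
buildReference <- function(profileA, profileB, dhsProbes,
                           deltaThreshold = 0.7,
                           cellTypeNames = c("HMEC", "FAT")) {
    shared <- intersect(names(profileA), names(profileB))
    if (length(shared) == 0)
        stop("profiles share no probes")
    a <- profileA[shared]; b <- profileB[shared]
    sel <- !is.na(a) & !is.na(b) & abs(a - b) > deltaThreshold &
        shared %in% dhsProbes
    if (!any(sel))
        stop("no marker passes |delta beta| > ", deltaThreshold,
             " within DHS; consider lowering the threshold")
    cent <- cbind(a[sel], b[sel])
    dimnames(cent) <- list(shared[sel], cellTypeNames)
    new("ReferenceProfiles", centroids = cent,
        deltaThreshold = deltaThreshold,
        criteria = list(delta = deltaThreshold, dhs = TRUE,
                        n_markers = sum(sel)))
}

## exact minimizer of ||y - C w||^2 subject to w >= 0, sum(w) = 1.
## Enumerates support sets and solves each equality-constrained KKT
## system; with a handful of cell types this is exact and fast.
.solveSimplexLS <- function(C, y, tol = 1e-9) {
    k <- ncol(C)
    best <- NULL; bestObj <- Inf
    for (bits in seq_len(2^k - 1)) {
        S <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
        Cs <- C[, S, drop = FALSE]
        A <- rbind(cbind(2 * crossprod(Cs), rep(1, length(S))),
                   c(rep(1, length(S)), 0))
        rhs <- c(2 * crossprod(Cs, y), 1)
        sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        w <- sol[seq_along(S)]
        if (any(w < -tol)) next
        w <- pmax(w, 0); w <- w / sum(w)
        r <- y - Cs %*% w
        obj <- sum(r^2)
        if (obj < bestObj) {
            full <- numeric(k); full[S] <- w
            best <- full; bestObj <- obj
        }
    }
    list(w = best, rss = bestObj)
}

#' Estimate cell-type fractions by constrained projection
#'
#' For each sample, finds the non-negative, sum-to-one weights w that
#' minimize the squared residual between the sample's marker beta values
#' and the convex combination of the reference centroids
#' (\eqn{\sum_j (\beta_j - \sum_k w_k c_{jk})^2}). Markers missing in a
#' sample are dropped pairwise; a sample must cover at least
#' `minMarkerFrac` of the markers.
#'
#' @param x a [BetaSet-class], numeric matrix (probes x samples) or a
#'   single named numeric vector of beta values.
#' @param ref a [ReferenceProfiles-class].
#' @param minMarkerFrac minimum fraction of markers a sample must provide
#'   (default 0.5).
#' @return a [CellFractions-class] (weights sum to one within 1e-6).
#' @export
estimateFractions <- function(x, ref, minMarkerFrac = 0.5) {
    m <- if (is(x, "BetaSet")) betaValues(x)
         else if (is.matrix(x)) x
         else matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
    mk <- markerIds(ref)
    C <- centroids(ref)
    W <- matrix(NA_real_, ncol(m), ncol(C),
                dimnames = list(colnames(m), colnames(C)))
    rss <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        v <- m[match(mk, rownames(m)), j]
        ok <- !is.na(v)
        if (mean(ok) < minMarkerFrac)
            stop("sample '", colnames(m)[j], "' covers only ",
                 sprintf("%.0f%%", 100 * mean(ok)), " of the ",
                 length(mk), " markers (minimum ",
                 sprintf("%.0f%%", 100 * minMarkerFrac), ")")
        fit <- .solveSimplexLS(C[ok, , drop = FALSE], v[ok])
        W[j, ] <- fit$w
        rss[j] <- fit$rss
    }
    new("CellFractions", weights = W, residuals = rss)
}

#' Adjust beta values for estimated cell fractions
#'
#' Removes the linear effect of a cell-fraction covariate (by default the
#' adipose/fat fraction) from every probe: per probe, ordinary least
#' squares of beta on the covariate across samples, returning the residual
#' plus the fitted value at the mean covariate so adjusted values stay on
#' the beta scale. Values are clipped to \[0,1\] afterwards and clipping
#' events are counted (reported in the metadata and via a message).
#'
#' @param bs a [BetaSet-class].
#' @param fractions a [CellFractions-class] covering all samples of `bs`,
#'   or a named numeric covariate vector.
#' @param cellType which fraction column to adjust for (default `"FAT"`).
#' @return an adjusted [BetaSet-class]; `metadata()$n_clipped` counts
#'   clipped cells. A constant covariate yields the identity transform
#'   with a warning.
#' @export
adjustForFractions <- function(bs, fractions, cellType = "FAT") {
    f <- if (is(fractions, "CellFractions")) {
        w <- fractionWeights(fractions)
        if (!cellType %in% colnames(w))
            stop("cell type '", cellType, "' not in fractions")
        w[, cellType]
    } else fractions
    miss <- setdiff(sampleIds(bs), names(f))
    if (length(miss) > 0)
        stop("no estimated fraction for sample(s): ",
             paste(miss, collapse = ", "))
    f <- f[sampleIds(bs)]
    m <- betaValues(bs)
    if (stats::var(f) == 0) {
        warning("covariate is constant across samples; returning input unchanged")
        return(bs)
    }
    ## per-probe OLS slope with pairwise-complete cells, vectorized
    obs <- !is.na(m)
    fm <- matrix(f, nrow(m), ncol(m), byrow = TRUE)
    fm[!obs] <- NA
    fbar <- rowMeans(fm, na.rm = TRUE)
    mbar <- rowMeans(m, na.rm = TRUE)
    fc <- fm - fbar
    sxx <- rowSums(fc^2, na.rm = TRUE)
    sxy <- rowSums(fc * (m - mbar), na.rm = TRUE)
    slope <- ifelse(sxx > 0, sxy / sxx, 0)
    adj <- m - slope * fc  # residual + fitted value at the mean covariate
    nclip <- sum(adj < 0 | adj > 1, na.rm = TRUE)
    adj <- pmin(pmax(adj, 0), 1)
    if (nclip > 0)
        message("adjustForFractions: clipped ", nclip,
                " adjusted value(s) to [0,1]")
    out <- BetaSet(adj, sampleInfo = NULL)
    SummarizedExperiment::colData(out) <- colData(bs)
    SummarizedExperiment::rowData(out) <- rowData(bs)
    metadata(out)$n_clipped <- nclip
    metadata(out)$adjusted_for <- cellType
    out
}
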