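## Monte-Carlo permutation analyses on binary alteration (hit) matrices:
## stochasticity of per-probe alteration frequencies, inter-sample
## heterogeneity of hit patterns, and within-module coordination versus
## mutual exclusivity. Each null conserves the margins it is defined to
## conserve, asserted on every permutation.

## deterministic per-permutation seeds keyed by (seed, index), so runs are
## reproducible independently of how permutations are batched
.permSeed <- function(seed, b) {
    (as.numeric(seed) * 48271 + b * 1000003) %% 2147483647
}

.asHits <- function(hits) {
    h <- if (is(hits, "DeviationSet")) hitMatrix(hits) else as.matrix(hits)
    if (any(is.na(h))) stop("hit matrix contains NA; resolve missingness first")
    if (!all(h %in% c(0, 1))) stop("hit matrix must be binary")
    h
}

## mean pairwise Manhattan (Hamming) distance between binary columns, and
## mean pairwise fractional overlap (|intersection| / |union|)
.pairwiseBinaryStats <- function(h) {
    cp <- crossprod(h)                      # overlaps
    k <- colSums(h)
    D <- outer(k, k, "+") - 2 * cp          # Manhattan distances
    U <- outer(k, k, "+") - cp              # union sizes
    lo <- lower.tri(D)
    ov <- ifelse(U[lo] > 0, cp[lo] / U[lo], 0)
    list(meanDist = mean(D[lo]), meanOverlap = mean(ov))
}

#' Monte-Carlo test of stochasticity of alteration frequencies
#'
#' Asks whether any probe is altered across samples more often than
#' expected if the observed hits were scattered at random over the matrix.
#' Each permutation scrambles all entries of the binary matrix jointly
#' (preserving the total number of hits) and records the maximal per-probe
#' alteration frequency; the empirical p-value compares the observed
#' maximal frequency with this null with the +1 correction:
#' \eqn{p = (1 + \#\{null \ge obs\}) / (n_{perm} + 1)}.
#'
#' @param hits a [DeviationSet-class] or binary matrix (probes x samples).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `observedMax` (frequency), `nullMax` (vector),
#'   `pEmpirical`, `totalHits`, `degenerate` (TRUE for an all-zero or
#'   all-one matrix, in which case the test is not informative and
#'   `pEmpirical` is NA).
#' @export
stochasticityTest <- function(hits, nPerm = 1000, seed = 1) {
    h <- .asHits(hits)
    total <- sum(h)
    if (total == 0 || total == length(h))
        return(list(observedMax = if (total == 0) 0 else 1,
                    nullMax = rep(if (total == 0) 0 else 1, nPerm),
                    pEmpirical = NA_real_, totalHits = total,
                    degenerate = TRUE))
    obs <- max(rowMeans(h))
    np <- nrow(h); ns <- ncol(h)
    nullMax <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        set.seed(.permSeed(seed, b))
        pos <- sample.int(np * ns, total)
        rows <- (pos - 1L) %% np + 1L
        cnt <- tabulate(rows, nbins = np)
        stopifnot(sum(cnt) == total)  # conservation of total hit count
        nullMax[b] <- max(cnt) / ns
    }
    list(observedMax = obs, nullMax = nullMax,
         pEmpirical = (1 + sum(nullMax >= obs)) / (nPerm + 1),
         totalHits = total, degenerate = FALSE)
}

.heterogeneityOne <- function(h, nPerm, seed, offset) {
    obs <- .pairwiseBinaryStats(h)
    np <- nrow(h)
    nullDist <- numeric(nPerm); nullOv <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        set.seed(.permSeed(seed, offset + b))
        hp <- apply(h, 2L, function(col) col[sample.int(np)])
        stopifnot(identical(colSums(hp), colSums(h)))  # per-sample counts
        st <- .pairwiseBinaryStats(hp)
        nullDist[b] <- st$meanDist; nullOv[b] <- st$meanOverlap
    }
    sdN <- stats::sd(nullDist)
    list(observedDist = obs$meanDist, observedOverlap = obs$meanOverlap,
         nullMeanDist = mean(nullDist), nullSdDist = sdN,
         nullMeanOverlap = mean(nullOv),
         z = if (sdN > 0) (obs$meanDist - mean(nullDist)) / sdN else NA_real_,
         pLower = (1 + sum(nullDist <= obs$meanDist)) / (nPerm + 1),
         nullDist = nullDist)
}

#' Monte-Carlo heterogeneity of hit patterns within sample groups
#'
#' For each group, computes the mean pairwise Manhattan distance (equal to
#' the Hamming count between binary columns) and the mean pairwise
#' fractional overlap of hits between samples, and compares them with a
#' null in which each sample's hit vector is permuted over probes
#' independently. The null conserves every sample's hit count, which
#' adjusts for groups with inherently more deviations (tumours carry more
#' hits than normal-adjacent samples). A mean distance below the null
#' (small `pLower`) means samples share altered loci more than chance.
#'
#' @param hitsA binary matrix of the first group (probes x samples).
#' @param hitsB optional second group sharing the probe axis.
#' @param nPerm permutations per group (default 1000).
#' @param seed integer seed.
#' @return list with one result per group (`groupA`, and `groupB` when
#'   given): observed/null mean distance and overlap, z, empirical lower
#'   tail p, and the null distance distribution.
#' @export
heterogeneityTest <- function(hitsA, hitsB = NULL, nPerm = 1000, seed = 1) {
    hA <- .asHits(hitsA)
    if (ncol(hA) < 2) stop("each group needs at least 2 samples")
    out <- list(groupA = .heterogeneityOne(hA, nPerm, seed, 0L))
    if (!is.null(hitsB)) {
        hB <- .asHits(hitsB)
        if (nrow(hB) != nrow(hA))
            stop("groups must share the probe axis")
        if (ncol(hB) < 2) stop("each group needs at least 2 samples")
        out$groupB <- .heterogeneityOne(hB, nPerm, seed, nPerm)
    }
    out
}

#' Coordination versus mutual exclusivity of alterations in a module
#'
#' Given the binary hit matrix of a gene/probe module (rows) across
#' samples (columns), restricts to rows altered in at least
#' `floor(minHitFrac * n_samples)` samples (with 42 samples and the
#' default 0.1 this is 4) and computes the mean pairwise Manhattan
#' distance between the qualifying rows. The null permutes each row's
#' entries across samples independently (conserving per-row hit counts).
#' An observed mean distance below the null indicates coordinated
#' alteration of the module within the same samples; above the null,
#' mutual exclusivity.
#'
#' @param hitsModule binary matrix, module members x samples.
#' @param minHitFrac minimum alteration fraction for a row to qualify
#'   (default 0.1).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `observedDist`, `nullDist`, `nullMean`, `nullSd`,
#'   `pCoordination` (lower tail), `pExclusivity` (upper tail),
#'   `qualifyingRows`, `hitThreshold`.
#' @export
coordinationTest <- function(hitsModule, minHitFrac = 0.1, nPerm = 1000,
                             seed = 1) {
    h <- .asHits(hitsModule)
    ns <- ncol(h)
    thr <- floor(minHitFrac * ns)
    qual <- rowSums(h) >= thr & rowSums(h) > 0
    if (sum(qual) < 2)
        stop("fewer than 2 rows reach the qualification threshold of ",
             thr, " hits (minHitFrac = ", minHitFrac, ", ", ns, " samples)")
    hq <- h[qual, , drop = FALSE]
    obs <- .pairwiseBinaryStats(t(hq))$meanDist
    nullDist <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        set.seed(.permSeed(seed, b))
        hp <- t(apply(hq, 1L, function(row) row[sample.int(ns)]))
        stopifnot(identical(rowSums(hp), rowSums(hq)))  # per-row counts
        nullDist[b] <- .pairwiseBinaryStats(t(hp))$meanDist
    }
    list(observedDist = obs, nullDist = nullDist,
         nullMean = mean(nullDist), nullSd = stats::sd(nullDist),
         pCoordination = (1 + sum(nullDist <= obs)) / (nPerm + 1),
         pExclusivity = (1 + sum(nullDist >= obs)) / (nPerm + 1),
         qualifyingRows = rownames(hq), hitThreshold = thr)
}
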