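## Synthetic beta-value cohorts with the statistical structure the
## field-defect methods assume: a three-stratum baseline approximating the
## bimodal 450k landscape, outlier-contaminated hypervariable probes with
## beta jumps of 0.2-0.3, matched tumour progression, and cell-type
## mixtures. Every generator records its ground truth and is
## bit-reproducible given (parameters, seed).

.DEFAULT_STRATA <- list(means = c(low = 0.10, mid = 0.50, high = 0.85),
                        props = c(low = 0.35, mid = 0.25, high = 0.40))

## baseline per-probe means and dispersions; sdRange reflects typical
## inter-individual variability of normal-tissue 450k probes
.baseline <- function(nProbes, strata = .DEFAULT_STRATA,
                      muJitterSd = 0.02, sdRange = c(0.01, 0.03)) {
    stratum <- sample(names(strata$means), nProbes, replace = TRUE,
                      prob = strata$props)
    mu <- pmin(pmax(strata$means[stratum] +
                    stats::rnorm(nProbes, 0, muJitterSd), 0.02), 0.98)
    list(mu = unname(mu), sd = stats::runif(nProbes, sdRange[1], sdRange[2]),
         stratum = stratum)
}

.drawCohort <- function(base, nControl, nCase) {
    np <- length(base$mu)
    vals <- matrix(stats::rnorm(np * (nControl + nCase), base$mu, base$sd),
                   np, nControl + nCase)
    probes <- sprintf("cg%07d", seq_len(np))
    samples <- c(sprintf("N%03d", seq_len(nControl)),
                 sprintf("NADJ%03d", seq_len(nCase)))
    dimnames(vals) <- list(probes, samples)
    sheet <- data.frame(sample_id = samples,
                        group = rep(c("N", "NADJ"), c(nControl, nCase)),
                        stringsAsFactors = FALSE)
    list(vals = vals, sheet = sheet)
}

.clipCount <- function(vals) {
    n <- sum(vals < 0 | vals > 1)
    list(vals = pmin(pmax(vals, 0), 1), n = n)
}

#' Simulate a null two-group cohort
#'
#' Both groups are drawn per probe from the same normal-on-beta-scale
#' distribution (three baseline strata: low ~0.1, intermediate ~0.5,
#' high ~0.85, each with small per-probe dispersion), then clipped to
#' \[0,1\]. There is no group structure, so differential-variability and
#' differential-methylation statistics are calibrated under this null.
#'
#' @param nProbes,nControl,nCase cohort dimensions (each group >= 3).
#' @param seed integer seed.
#' @param sdRange range of per-probe baseline standard deviations.
#' @return list with `beta` (a [BetaSet-class], groups `N` and `NADJ`) and
#'   `truth` (a [S4Vectors::SimpleList] recording parameters and clipping).
#' @export
simulateNullCohort <- function(nProbes, nControl, nCase, seed = 1,
                               sdRange = c(0.01, 0.03)) {
    stopifnot(nControl >= 3, nCase >= 3)
    set.seed(seed)
    base <- .baseline(nProbes, sdRange = sdRange)
    coh <- .drawCohort(base, nControl, nCase)
    cl <- .clipCount(coh$vals)
    bs <- BetaSet(cl$vals, sampleInfo = coh$sheet)
    list(beta = bs,
         truth = SimpleList(plantedDvProbes = character(0),
                            outlierCells = data.frame(probe = character(0),
                                                      sample = character(0)),
                            baselineMean = base$mu, baselineSd = base$sd,
                            nClipped = cl$n, seed = seed))
}

#' Simulate a field-defect cohort with outlier contamination
#'
#' Starts from the null generator and plants `fracDvProbes` of the probes
#' as hypervariable field defects: in a random subset of
#' `round(outlierFrac * nCase)` case samples (at least one), each planted
#' probe receives an additive beta jump drawn uniformly from
#' `[jumpLow, jumpHigh]`, directed away from the baseline (upward when the
#' baseline mean is below 0.2, downward when above 0.6, a random direction
#' per probe otherwise), mirroring outlier samples whose methylation jumps
#' by 20-30% depending on the normal baseline. Values are clipped to
#' \[0,1\] and clipping is audited in the truth record.
#'
#' @param nProbes,nControl,nCase cohort dimensions.
#' @param fracDvProbes fraction of probes planted (default 0.05).
#' @param outlierFrac fraction of case samples jumping at a planted probe
#'   (default 0.1).
#' @param jumpLow,jumpHigh jump magnitude range on the beta scale
#'   (defaults 0.2 and 0.3).
#' @param seed integer seed.
#' @param sdRange range of per-probe baseline standard deviations.
#' @return list with `beta` (a [BetaSet-class]) and `truth`
#'   ([S4Vectors::SimpleList] with `plantedDvProbes`, `outlierCells`
#'   (probe/sample pairs), per-probe jump `direction`, baseline
#'   parameters, clip count and seed).
#' @export
simulateFieldDefect <- function(nProbes, nControl, nCase,
                                fracDvProbes = 0.05, outlierFrac = 0.1,
                                jumpLow = 0.2, jumpHigh = 0.3, seed = 1,
                                sdRange = c(0.01, 0.03)) {
    stopifnot(fracDvProbes > 0, fracDvProbes < 1,
              outlierFrac > 0, outlierFrac < 1)
    set.seed(seed)
    base <- .baseline(nProbes, sdRange = sdRange)
    coh <- .drawCohort(base, nControl, nCase)
    caseIdx <- nControl + seq_len(nCase)
    nPlant <- max(1L, round(fracDvProbes * nProbes))
    planted <- sort(sample.int(nProbes, nPlant))
    ## outliers per planted probe; degenerates to the null generator as
    ## outlierFrac -> 0
    k <- round(outlierFrac * nCase)
    dirn <- integer(nProbes)
    cells <- vector("list", nPlant)
    for (ii in seq_along(planted)) {
        i <- planted[ii]
        dirn[i] <- if (base$mu[i] < 0.2) 1L
                   else if (base$mu[i] > 0.6) -1L
                   else sample(c(-1L, 1L), 1L)
        hit <- sample.int(nCase, k)
        if (k > 0)
            coh$vals[i, caseIdx[hit]] <- coh$vals[i, caseIdx[hit]] +
                dirn[i] * stats::runif(k, jumpLow, jumpHigh)
        cells[[ii]] <- data.frame(
            probe = rep(rownames(coh$vals)[i], k),
            sample = colnames(coh$vals)[caseIdx[hit]],
            stringsAsFactors = FALSE)
    }
    cl <- .clipCount(coh$vals)
    bs <- BetaSet(cl$vals, sampleInfo = coh$sheet)
    list(beta = bs,
         truth = SimpleList(
             plantedDvProbes = rownames(coh$vals)[planted],
             outlierCells = do.call(rbind, cells),
             direction = stats::setNames(dirn[planted],
                                         rownames(coh$vals)[planted]),
             jumpRange = c(jumpLow, jumpHigh),
             outliersPerProbe = k,
             baselineMean = base$mu, baselineSd = base$sd,
             nClipped = cl$n, seed = seed))
}

#' Extend a field-defect cohort with matched progressing tumours
#'
#' Each of the first `nPairs` case (normal-adjacent) samples is given a
#' matched tumour that inherits its adjacent-normal profile plus an
#' additional directed shift of `tumourExtraShift` at every planted probe
#' (so tumours converge on the full field-defect repertoire, including
#' loci not yet altered in their matched normal-adjacent sample) and
#' technical noise of sd `tumourNoiseSd` elsewhere.
#'
#' @param base output of [simulateFieldDefect()].
#' @param nPairs number of matched pairs (at most the number of case
#'   samples).
#' @param tumourExtraShift additional beta shift at planted probes
#'   (default 0.15).
#' @param tumourNoiseSd technical noise sd for tumour profiles
#'   (default 0.01).
#' @param seed integer seed.
#' @return list with `beta` (a [BetaSet-class] with groups `N`, `NADJ`,
#'   `C` and `pair_id` links) and `truth` (adds `shiftedCells`,
#'   `tumourExtraShift`, `pairs` to the base truth).
#' @export
simulateProgressionCohort <- function(base, nPairs,
                                      tumourExtraShift = 0.15,
                                      tumourNoiseSd = 0.01, seed = 1) {
    set.seed(seed)
    bs <- base$beta; truth <- base$truth
    grp <- sampleGroups(bs)
    caseIds <- sampleIds(bs)[grp == "NADJ"]
    stopifnot(nPairs >= 1, nPairs <= length(caseIds))
    pairedIds <- caseIds[seq_len(nPairs)]
    m <- betaValues(bs)
    planted <- truth$plantedDvProbes
    dirn <- truth$direction[planted]
    tum <- m[, pairedIds, drop = FALSE] +
        matrix(stats::rnorm(nrow(m) * nPairs, 0, tumourNoiseSd),
               nrow(m), nPairs)
    tum[planted, ] <- tum[planted, ] + dirn * tumourExtraShift
    colnames(tum) <- sub("^NADJ", "C", pairedIds)
    all <- cbind(m, tum)
    nclip <- sum(all < 0 | all > 1)
    all <- pmin(pmax(all, 0), 1)
    pair <- stats::setNames(rep(NA_character_, ncol(all)), colnames(all))
    pair[pairedIds] <- paste0("P", seq_len(nPairs))
    pair[colnames(tum)] <- paste0("P", seq_len(nPairs))
    sheet <- data.frame(
        sample_id = colnames(all),
        group = c(grp, rep("C", nPairs)),
        pair_id = unname(pair),
        stringsAsFactors = FALSE)
    out <- BetaSet(all, sampleInfo = sheet)
    truth$shiftedCells <- expand.grid(probe = planted,
                                      sample = colnames(tum),
                                      stringsAsFactors = FALSE)
    truth$tumourExtraShift <- tumourExtraShift
    truth$pairs <- data.frame(pair_id = paste0("P", seq_len(nPairs)),
                              normal_id = pairedIds,
                              tumour_id = colnames(tum),
                              stringsAsFactors = FALSE)
    truth$nClippedProgression <- nclip
    list(beta = out, truth = truth)
}

#' Simulate mixture samples from reference centroids
#'
#' Samples are convex combinations of the reference centroids plus
#' truncated i.i.d. Gaussian noise; the true weights are returned.
#'
#' @param ref a [ReferenceProfiles-class].
#' @param nSamples number of mixture samples.
#' @param weightLaw `"uniform"` (flat Dirichlet over the simplex) or
#'   `"vertex"` (each sample sits at a random vertex).
#' @param noiseSd noise standard deviation on the beta scale.
#' @param seed integer seed.
#' @return list with `beta` (markers x samples matrix, clipped to
#'   \[0,1\]) and `weights` (samples x cell-types truth matrix).
#' @export
simulateMixtureCohort <- function(ref, nSamples,
                                  weightLaw = c("uniform", "vertex"),
                                  noiseSd = 0.05, seed = 1) {
    weightLaw <- match.arg(weightLaw)
    set.seed(seed)
    C <- centroids(ref)
    k <- ncol(C)
    W <- if (weightLaw == "vertex") {
        t(vapply(sample.int(k, nSamples, replace = TRUE),
                 function(j) as.numeric(seq_len(k) == j), numeric(k)))
    } else {
        e <- matrix(stats::rexp(nSamples * k), nSamples, k)
        e / rowSums(e)
    }
    colnames(W) <- colnames(C)
    rownames(W) <- sprintf("mix%03d", seq_len(nSamples))
    beta <- C %*% t(W)
    if (noiseSd > 0)
        beta <- beta + matrix(stats::rnorm(length(beta), 0, noiseSd),
                              nrow(beta), ncol(beta))
    beta <- pmin(pmax(beta, 0), 1)
    colnames(beta) <- rownames(W)
    list(beta = beta, weights = W)
}
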