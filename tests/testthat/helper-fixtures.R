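## fixtures built in code: small beta matrices, sample sheets, hit
## matrices and reference profiles used across the test files

makeBetaMatrix <- function(np = 10, ns = 6, seed = 1, naCells = 0) {
    set.seed(seed)
    m <- matrix(round(runif(np * ns), 6), np, ns,
                dimnames = list(sprintf("cg%05d", seq_len(np)),
                                sprintf("S%02d", seq_len(ns))))
    if (naCells > 0)
        m[sample.int(length(m), naCells)] <- NA_real_
    m
}

makeSheet <- function(ids, groups, pairs = NULL) {
    df <- data.frame(sample_id = ids, group = groups,
                     stringsAsFactors = FALSE)
    if (!is.null(pairs)) df$pair_id <- pairs
    df
}

makeHits <- function(np, ns, density = 0.1, seed = 1) {
    set.seed(seed)
    h <- matrix(rbinom(np * ns, 1, density), np, ns,
                dimnames = list(sprintf("p%03d", seq_len(np)),
                                sprintf("s%02d", seq_len(ns))))
    h
}

## two synthetic cell-type profiles separated strongly at the first
## nMarkers probes (all within the DHS list), weakly elsewhere
makeRefPair <- function(nProbes = 200, nMarkers = 60, seed = 2) {
    set.seed(seed)
    ids <- sprintf("cg%05d", seq_len(nProbes))
    a <- setNames(runif(nProbes, 0.05, 0.95), ids)
    b <- a
    b[seq_len(nMarkers)] <- ifelse(a[seq_len(nMarkers)] > 0.5,
                                   a[seq_len(nMarkers)] - 0.8,
                                   a[seq_len(nMarkers)] + 0.8)
    b <- pmin(pmax(b, 0), 1)
    list(a = a, b = b, dhs = ids[seq_len(nProbes / 2)], ids = ids)
}

## brute-force AUC by exhaustive pair counting (ties count 1/2)
bruteAUC <- function(pos, neg) {
    s <- 0
    for (p in pos) for (n in neg)
        s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
    s / (length(pos) * length(neg))
}

## exhaustive hypergeometric upper-tail p for a 2x2 enrichment table
bruteHyperTail <- function(a, setSize, N, nsel) {
    amax <- min(setSize, nsel)
    sum(vapply(a:amax, function(x) stats::dhyper(x, setSize, N - setSize,
                                                 nsel), 0))
}
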