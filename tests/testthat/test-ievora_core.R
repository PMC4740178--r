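test_that("two-group Bartlett statistic matches the direct formula and base R", {
    ## identical variances: statistic 0, p 1
    b0 <- bartlettTwoGroup(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
    expect_equal(b0$statistic, 0)
    expect_equal(b0$p.value, 1)

    ## frozen value from a hand evaluation of the Bartlett formula
    ## (pooled variance, sum (n_i-1) log s_i^2, correction factor C)
    b <- bartlettTwoGroup(c(0.10, 0.20, 0.30, 0.40),
                          c(0.10, 0.15, 0.20, 0.25, 0.30))
    expect_equal(b$statistic, 0.7241623253, tolerance = 1e-9)
    expect_equal(b$p.value, 0.3947819757, tolerance = 1e-9)

    ## degenerate variance is flagged, not assigned p = 0
    bd <- bartlettTwoGroup(c(0.1, 0.2, 0.3), c(0.4, 0.4, 0.4))
    expect_true(bd$degenerate)
    expect_true(is.na(bd$statistic))

    ## cross-check against the independent base-R implementation
    set.seed(5)
    for (i in 1:20) {
        x <- runif(sample(4:12, 1)); y <- runif(sample(4:12, 1))
        ours <- bartlettTwoGroup(x, y)
        ref <- bartlett.test(list(x, y))
        expect_equal(ours$statistic, unname(ref$statistic),
                     tolerance = 1e-10)
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    }
})

test_that("Welch t is signed case minus control and matches base R", {
    w0 <- welchT(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
    expect_equal(w0$statistic, 0)
    expect_equal(w0$p.value, 1)

    ## frozen hand evaluation: higher methylation in the case group gives
    ## a positive t
    w <- welchT(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
    expect_equal(w$statistic, 3.6742346142, tolerance = 1e-9)
    expect_equal(w$df, 4, tolerance = 1e-9)
    expect_equal(w$p.value, 0.02131164113, tolerance = 1e-9)

    ## antisymmetry
    wr <- welchT(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
    expect_equal(wr$statistic, -w$statistic)
    expect_equal(wr$p.value, w$p.value)

    set.seed(6)
    for (i in 1:10) {
        x <- runif(7); y <- runif(9)
        ours <- welchT(x, y)
        ref <- t.test(y, x)
        expect_equal(ours$statistic, unname(ref$statistic),
                     tolerance = 1e-10)
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
        oursP <- welchT(x, y, pooled = TRUE)
        refP <- t.test(y, x, var.equal = TRUE)
        expect_equal(oursP$statistic, unname(refP$statistic),
                     tolerance = 1e-10)
    }
})

test_that("FDR estimation follows step-up BH, handles edge cases, is order-invariant", {
    expect_equal(estimateFdr(c(0.01, 0.02, 0.04, 0.05)),
                 c(0.04, 0.04, 0.05, 0.05))
    expect_equal(estimateFdr(c(1, 1, 1)), c(1, 1, 1))
    expect_equal(estimateFdr(0.2, method = "storey"), 0.2)
    expect_error(estimateFdr(c(0.5, 1.2)), "\\[0,1\\]")

    set.seed(7)
    p <- runif(50)
    perm <- sample(50)
    expect_equal(estimateFdr(p)[perm], estimateFdr(p[perm]))
    q <- estimateFdr(p, method = "storey")
    expect_true(all(q <= 1) && all(q >= 0))
    expect_true(all(q <= estimateFdr(p) + 1e-12))  # pi0 shrinks BH
})

test_that("iEVORA recovers planted hypervariable probes and labels categories", {
    sim <- simulateFieldDefect(300, 50, 42, fracDvProbes = 0.02,
                               outlierFrac = 0.25, seed = 7)
    res <- runIEVORA(sim$beta)
    tab <- dvmcTable(res)
    planted <- sim$truth$plantedDvProbes
    expect_true(all(planted %in% tab$probe_id))
    expect_lte(sum(!tab$probe_id %in% planted), 1)

    ## planted probes are hypervariable in the case group and their
    ## methylation category follows the planted jump direction
    sel <- tab[tab$probe_id %in% planted, ]
    expect_true(all(sel$log2_var_ratio > 0))
    dirn <- sim$truth$direction[sel$probe_id]
    expect_identical(unname(sel$category),
                     unname(ifelse(dirn > 0, "dvUPdmUP", "dvUPdmDN")))

    ## ranking is by |t| descending with rank 1..n
    expect_identical(tab$rank, seq_len(nrow(tab)))
    expect_true(all(diff(abs(tab$t_stat)) <= 1e-12))

    ## retained rows satisfy both thresholds
    expect_true(all(tab$bartlett_qvalue < 0.001 & tab$t_pvalue < 0.05))

    expect_error(runIEVORA(sim$beta, caseGroup = "XX"), "absent")
})

test_that("single-extreme-outlier probes with non-significant t are excluded", {
    ## Bartlett alone would call these probes at tiny p; the t-filter
    ## regularizes the screen against single outliers
    set.seed(21)
    n1 <- 50; n2 <- 42
    m <- rbind(matrix(rnorm(100 * (n1 + n2), 0.30, 0.02), 100),
               matrix(rnorm(5 * (n1 + n2), 0.30, 0.01), 5))
    m[101:105, n1 + 1] <- 0.95  # one extreme outlier in the case group
    m <- pmin(pmax(m, 0), 1)
    dimnames(m) <- list(sprintf("cg%05d", 1:105),
                        sprintf("S%03d", seq_len(n1 + n2)))
    bs <- BetaSet(m, makeSheet(colnames(m),
                               rep(c("N", "NADJ"), c(n1, n2))))
    all <- runIEVORA(bs, dvFdr = 2, dmP = 1.01)  # no thresholds: full table
    atab <- dvmcTable(all)
    out <- atab[atab$probe_id %in% sprintf("cg%05d", 101:105), ]
    expect_true(all(out$bartlett_qvalue < 0.001))  # DV screen fires
    sel <- dvmcTable(runIEVORA(bs))
    expect_true(all(out$t_pvalue >= 0.05))
    expect_false(any(sprintf("cg%05d", 101:105) %in% sel$probe_id))
})

test_that("degenerate probes are reported in a side table, never tested", {
    m <- makeBetaMatrix(6, 8, seed = 3)
    m[1, ] <- 0.4                       # zero variance everywhere
    m[2, 1:3] <- NA                     # too few control values
    bs <- BetaSet(m, makeSheet(colnames(m), rep(c("N", "NADJ"), each = 4)))
    res <- runIEVORA(bs)
    exc <- excludedProbes(res)
    expect_setequal(exc$probe_id, c("cg00001", "cg00002"))
    expect_match(exc$reason[exc$probe_id == "cg00001"], "variance")
    expect_match(exc$reason[exc$probe_id == "cg00002"], "non-missing")
    expect_identical(res@nTested, 4L)
    ## empty selection is an empty table, not an error
    expect_identical(nrow(dvmcTable(res)), 0L)
})
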