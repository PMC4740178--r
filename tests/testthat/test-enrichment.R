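test_that("Fisher enrichment builds the 2x2 table, sample OR and hypergeometric tail", {
    ## universe 1000, selection 100, set of 15 overlapping in 10:
    ## table [[10, 90], [5, 895]] -> OR = 10*895/(90*5) = 19.888...
    universe <- sprintf("g%04d", 1:1000)
    selected <- universe[1:100]
    sets <- list(hit = c(universe[1:10], universe[101:105]),
                 away = sprintf("x%d", 1:5))
    expect_warning(res <- fisherEnrichment(selected, sets, universe),
                   "disjoint")
    expect_identical(nrow(res), 1L)
    expect_equal(res$odds_ratio, 10 * 895 / (90 * 5), tolerance = 1e-12)
    expect_identical(res$n_overlap, 10L)
    expect_equal(res$fisher_p, bruteHyperTail(10, 15, 1000, 100),
                 tolerance = 1e-12)
    expect_identical(res$overlap_ids, paste(universe[1:10], collapse = ","))

    ## perfect enrichment: selection identical to the set
    r2 <- fisherEnrichment(universe[1:20],
                           list(exact = universe[1:20],
                                other = universe[30:60]), universe)
    expect_identical(r2$n_overlap[r2$set_name == "exact"], 20L)
    expect_lt(r2$fisher_p[r2$set_name == "exact"],
              min(r2$fisher_p[r2$set_name == "other"]))
    expect_true(all(r2$bh_adjusted_p >= r2$fisher_p - 1e-15))

    expect_error(fisherEnrichment(c("zzz"), sets, universe),
                 "outside the universe.*zzz")
})

test_that("enrichment p-values agree with exhaustive tail sums on small margins", {
    set.seed(131)
    for (i in 1:25) {
        N <- sample(10:30, 1)
        nsel <- sample(2:(N - 2), 1)
        nset <- sample(2:(N - 2), 1)
        universe <- sprintf("u%02d", seq_len(N))
        selected <- sample(universe, nsel)
        aset <- sample(universe, nset)
        r <- fisherEnrichment(selected, list(s = aset), universe)
        expect_equal(r$fisher_p,
                     bruteHyperTail(r$n_overlap, nset, N, nsel),
                     tolerance = 1e-12)
        ## one-tailed over-representation agrees with fisher.test greater
        a <- r$n_overlap
        tab <- matrix(c(a, nsel - a, nset - a, N - nsel - nset + a), 2)
        expect_equal(r$fisher_p,
                     fisher.test(tab, alternative = "greater")$p.value,
                     tolerance = 1e-9)
    }
})

test_that("BH adjustment within an enrichment call is order-invariant", {
    universe <- sprintf("g%03d", 1:300)
    set.seed(141)
    sets <- lapply(1:6, function(i) sample(universe, 40))
    names(sets) <- paste0("set", 1:6)
    selected <- sample(universe, 50)
    r1 <- fisherEnrichment(selected, sets, universe)
    r2 <- fisherEnrichment(selected, rev(sets), universe)
    expect_equal(r1$bh_adjusted_p[match(r2$set_name, r1$set_name)],
                 r2$bh_adjusted_p)
})

test_that("expected overlap reproduces the printed cross-reactive audit numbers", {
    expect_identical(expectedOverlap(485512, 93382, 7318)$expected, 1407)
    expect_identical(expectedOverlap(485512, 93382, 3173)$expected, 610)
    expect_identical(expectedOverlap(485512, 0, 7318)$expected, 0)
    expect_error(expectedOverlap(0, 1, 1), "positive")
    expect_error(expectedOverlap(10, 20, 5), "exceed")

    ## monotone non-decreasing in each argument
    base <- expectedOverlap(1000, 200, 100)$expectedExact
    expect_gte(expectedOverlap(1000, 250, 100)$expectedExact, base)
    expect_gte(expectedOverlap(1000, 200, 150)$expectedExact, base)
})

.fakeDvmc <- function(categories, probeIds) {
    n <- length(probeIds)
    tab <- S4Vectors::DataFrame(
        probe_id = probeIds, t_stat = seq(n, 1) / n,
        t_pvalue = rep(0.01, n), log2_var_ratio = rep(1, n),
        bartlett_stat = rep(50, n), bartlett_pvalue = rep(1e-12, n),
        bartlett_qvalue = rep(1e-9, n), mean_control = rep(0.2, n),
        mean_case = rep(0.3, n), category = categories,
        rank = seq_len(n))
    new("DvmcResults", table = tab,
        excluded = S4Vectors::DataFrame(probe_id = character(0),
                                        reason = character(0)),
        params = list(dvFdr = 0.001, dmP = 0.05, fdrMethod = "bh"),
        nTested = n, nUniverse = n)
}

test_that("region bias test recovers planted TSS enrichment and hand odds ratios", {
    ## contingency [[20, 80], [80, 20]]: OR = 20*20/(80*80) = 1/16
    probes <- sprintf("cg%03d", 1:200)
    dv <- .fakeDvmc(rep(c("dvUPdmUP", "dvDNdmUP"), each = 100), probes)
    ann <- S4Vectors::DataFrame(
        probe_id = probes, chrom = "chr1",
        position = seq_len(200),
        region_class = c(rep("TSS1500", 20), rep("Body", 80),
                         rep("TSS1500", 80), rep("Body", 20)))
    r <- regionBiasTest(dv, ann, "dvUPdmUP", "dvDNdmUP", "TSS1500")
    expect_equal(r$oddsRatio, 1 / 16, tolerance = 1e-12)
    ## symmetric complement: swapping the region group inverts the OR
    rc <- regionBiasTest(dv, ann, "dvUPdmUP", "dvDNdmUP", "Body")
    expect_equal(rc$oddsRatio, 16, tolerance = 1e-12)
    expect_equal(r$p, rc$p, tolerance = 1e-12)
    expect_equal(r$p, fisher.test(r$table)$p.value, tolerance = 1e-12)

    ## planted strong enrichment is recovered with a large OR
    ann2 <- ann
    ann2$region_class <- c(rep("TSS1500", 90), rep("Body", 10),
                           rep("TSS1500", 15), rep("Body", 85))
    r2 <- regionBiasTest(dv, ann2, "dvUPdmUP", "dvDNdmUP", "TSS1500")
    expect_gt(r2$oddsRatio, 5)
    expect_lt(r2$p, 1e-10)

    expect_error(regionBiasTest(dv, ann, "dvUPdmUP", "dvDNdmUP",
                                "Promoter2k"), "unknown region")
})
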