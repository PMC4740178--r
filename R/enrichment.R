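## Set-based enrichment of DVMC lists (TFBS / pathway / gene-region
## style): one-tailed Fisher exact tests with Benjamini-Hochberg
## correction, and expected-overlap arithmetic for flagged-probe audits.

#' One-tailed Fisher enrichment of a selection against annotation sets
#'
#' For each named set, builds the 2x2 table of membership in the selection
#' versus membership in the set over the universe, and tests
#' over-representation with the one-tailed hypergeometric (Fisher) tail.
#' The odds ratio is the sample odds ratio ad/bc, with the Haldane 0.5
#' correction added to all cells only when a zero cell occurs. P-values
#' are Benjamini-Hochberg adjusted across all sets tested in the call.
#' Sets are intersected with the universe first; sets disjoint from the
#' universe are skipped with a warning.
#'
#' @param selected character vector, must be a subset of `universe`.
#' @param annotationSets named list of character vectors.
#' @param universe character vector of all tested probes/genes.
#' @return `DataFrame` with set_name, n_set, n_overlap, odds_ratio,
#'   fisher_p, bh_adjusted_p and a comma-separated `overlap_ids` column,
#'   ordered as the input sets (skipped sets omitted).
#' @export
fisherEnrichment <- function(selected, annotationSets, universe) {
    bad <- setdiff(selected, universe)
    if (length(bad) > 0)
        stop("selected ids outside the universe: ",
             paste(utils::head(bad, 5), collapse = ", "),
             if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
    if (is.null(names(annotationSets)))
        stop("annotationSets must be a named list")
    N <- length(unique(universe))
    nsel <- length(unique(selected))
    rows <- lapply(names(annotationSets), function(nm) {
        s <- intersect(annotationSets[[nm]], universe)
        if (length(s) == 0) {
            warning("set '", nm, "' is disjoint from the universe; skipped")
            return(NULL)
        }
        ov <- intersect(selected, s)
        a <- length(ov)                 # selected & in set
        b <- nsel - a                   # selected & out of set
        c <- length(s) - a              # unselected & in set
        d <- N - nsel - c
        if (any(c(a, b, c, d) == 0)) {
            or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
        } else or <- a * d / (b * c)
        p <- stats::phyper(a - 1, length(s), N - length(s), nsel,
                           lower.tail = FALSE)
        data.frame(set_name = nm, n_set = length(s), n_overlap = a,
                   odds_ratio = or, fisher_p = p,
                   overlap_ids = paste(sort(ov), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0) stop("no testable set")
    out <- do.call(rbind, rows)
    out$bh_adjusted_p <- stats::p.adjust(out$fisher_p, method = "BH")
    out <- out[, c("set_name", "n_set", "n_overlap", "odds_ratio",
                   "fisher_p", "bh_adjusted_p", "overlap_ids")]
    as(out, "DataFrame")
}

#' Expected overlap of a selection with a flagged probe set
#'
#' The number of selected probes expected to be flagged by random chance:
#' `floor(flaggedN / universeN * selectedN)`. Used e.g. to audit how many
#' DVMCs would overlap cross-reactive/polymorphic probes if selection were
#' random with respect to the flag.
#'
#' @param universeN size of the probe universe.
#' @param flaggedN number of flagged probes in the universe.
#' @param selectedN size of the selection.
#' @return list with `expected` (floored integer) and `expectedExact`
#'   (unrounded).
#' @examples
#' expectedOverlap(485512, 93382, 7318)$expected  # 1407
#' @export
expectedOverlap <- function(universeN, flaggedN, selectedN) {
    if (universeN <= 0) stop("universe size must be positive")
    if (flaggedN > universeN || selectedN > universeN)
        stop("flaggedN and selectedN cannot exceed universeN")
    if (flaggedN < 0 || selectedN < 0)
        stop("counts must be non-negative")
    ex <- flaggedN / universeN * selectedN
    list(expected = floor(ex), expectedExact = ex)
}

.REGION_VOCAB <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                   "3'UTR", "intergenic")

#' Gene-region bias between two DVMC category groups
#'
#' Tests whether probes of one category group map to a set of gene regions
#' (e.g. the TSS-proximal classes) more often than probes of another
#' category group, by a Fisher exact test on the 2x2 table of category
#' group x region membership.
#'
#' @param dvmc a [DvmcResults-class].
#' @param annotation probe annotation with `probe_id` and `region_class`.
#' @param categoriesA,categoriesB DVMC category labels forming the two
#'   groups (e.g. `"dvUPdmUP"` vs `"dvDNdmUP"`).
#' @param regions region classes forming the region group; must belong to
#'   the annotation vocabulary.
#' @param alternative passed to [stats::fisher.test()].
#' @return list with `oddsRatio` (sample odds ratio, Haldane-corrected on
#'   zero cells), `p`, and the 2x2 `table`.
#' @export
regionBiasTest <- function(dvmc, annotation, categoriesA, categoriesB,
                           regions, alternative = "two.sided") {
    vocab <- union(.REGION_VOCAB, unique(annotation$region_class))
    bad <- setdiff(regions, vocab)
    if (length(bad) > 0)
        stop("unknown region label(s): ", paste(bad, collapse = ", "))
    tab <- dvmcTable(dvmc)
    reg <- annotation$region_class[match(tab$probe_id, annotation$probe_id)]
    inA <- tab$category %in% categoriesA
    inB <- tab$category %in% categoriesB
    if (!any(inA) || !any(inB))
        stop("both category groups must be non-empty after annotation join")
    inReg <- reg %in% regions
    m <- matrix(c(sum(inA & inReg), sum(inA & !inReg),
                  sum(inB & inReg), sum(inB & !inReg)),
                2, 2, byrow = TRUE,
                dimnames = list(c("groupA", "groupB"),
                                c("in_region", "out_region")))
    p <- stats::fisher.test(m, alternative = alternative)$p.value
    if (any(m == 0)) {
        or <- (m[1, 1] + 0.5) * (m[2, 2] + 0.5) /
            ((m[1, 2] + 0.5) * (m[2, 1] + 0.5))
    } else or <- m[1, 1] * m[2, 2] / (m[1, 2] * m[2, 1])
    list(oddsRatio = or, p = p, table = m)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    if (!requireNamespace("fgsea", quietly = TRUE))
        stop("fgsea is required to parse GMT files")
    fgsea::gmtPathways(path)
}
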