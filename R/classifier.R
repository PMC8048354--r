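## Expression-class criteria and induced-gene set algebra. The inequality
## directions are deliberate and pinned by tests: expressed nFPKM > 1;
## preferential additionally own >= 10 x other; specific additionally
## other <= 1, own > 100 and own > 100 x other. The nested classes make a
## gene at most "specific" in one tissue.

.classifyOne <- function(own, oth) {
    expressed <- own > 1
    preferential <- expressed & own >= 10 * oth
    specific <- preferential & oth <= 1 & own > 100 & own > 100 * oth
    ifelse(specific, "specific",
    ifelse(preferential, "preferential",
    ifelse(expressed, "expressed", "none")))
}

#' Classify sex-specific expression from nFPKM
#'
#' Applies the expressed / preferential / specific criteria to each gene's
#' stigma and pollen nFPKM, mirror-symmetrically for the two tissues. The
#' classes are nested (specific implies preferential implies expressed) and
#' no gene can be specific for both tissues.
#'
#' @param nfpkmStigma,nfpkmPollen non-negative numeric vectors (same genes).
#' @param geneIds optional gene ids (default from names).
#' @return data.frame `gene_id`, `stigma_class`, `pollen_class`,
#'   `rank_key_stigma`, `rank_key_pollen` (the called tissue's nFPKM, for
#'   sorting specific-gene lists).
#' @examples
#' classifyExpression(c(150, 50, 150), c(0.5, 4, 1.4))
#' @export
classifyExpression <- function(nfpkmStigma, nfpkmPollen,
                               geneIds = names(nfpkmStigma)) {
    stopifnot(length(nfpkmStigma) == length(nfpkmPollen))
    if (any(nfpkmStigma < 0 | nfpkmPollen < 0))
        stop("nFPKM values must be non-negative")
    if (is.null(geneIds)) geneIds <- as.character(seq_along(nfpkmStigma))
    data.frame(gene_id = geneIds,
               stigma_class = .classifyOne(nfpkmStigma, nfpkmPollen),
               pollen_class = .classifyOne(nfpkmPollen, nfpkmStigma),
               rank_key_stigma = unname(nfpkmStigma),
               rank_key_pollen = unname(nfpkmPollen),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes specific to one tissue, ranked by expression
#'
#' @param calls output of [classifyExpression()].
#' @param tissue `"stigma"` or `"pollen"`.
#' @return character vector of gene ids, sorted by the tissue's nFPKM
#'   descending.
#' @export
specificGenes <- function(calls, tissue = c("stigma", "pollen")) {
    tissue <- match.arg(tissue)
    cls <- calls[[paste0(tissue, "_class")]]
    key <- calls[[paste0("rank_key_", tissue)]]
    sel <- cls == "specific"
    calls$gene_id[sel][order(key[sel], decreasing = TRUE)]
}

#' Upregulated gene set from a differential test
#'
#' @param de data.frame from [nbWaldTest()].
#' @param fcThreshold linear fold-change threshold (strict `>`).
#' @param padjThreshold adjusted-p threshold (strict `<`).
#' @return character vector of gene ids.
#' @export
upregulatedSet <- function(de, fcThreshold = 2, padjThreshold = 0.1) {
    sel <- !is.na(de$fold_change) & de$fold_change > fcThreshold &
        de$padj < padjThreshold
    de$gene_id[sel]
}

#' Partition four upregulated sets into Venn regions
#'
#' Computes all 15 region memberships of the 4-set Venn over
#' `(C10, C60, I10, I60)` by per-gene membership signature, plus the derived
#' exclusive-compatible union `(C10 u C60) \ (I10 u I60)` and its
#' incompatible mirror. When `nExpressed` is supplied, per-set totals are
#' also reported as percentages of the expressed-gene universe.
#'
#' @param C10,C60,I10,I60 character vectors of upregulated gene ids.
#' @param nExpressed optional size of the expressed-gene universe.
#' @return list with `regions` (data.frame: region signature such as
#'   `"C10&C60"`, count, genes), `exclusiveCompatible`,
#'   `exclusiveIncompatible` (gene vectors), `setTotals` and (if
#'   `nExpressed`) `setPct` (percent of expressed genes, one decimal).
#' @export
vennPartition <- function(C10, C60, I10, I60, nExpressed = NULL) {
    sets <- list(C10 = unique(C10), C60 = unique(C60),
                 I10 = unique(I10), I60 = unique(I60))
    universe <- sort(unique(unlist(sets)))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                                 dimnames = list(NULL, names(sets)))
    sig <- apply(member, 1L, function(m)
        paste(names(sets)[m], collapse = "&"))
    regions <- data.frame(region = sort(unique(sig)), stringsAsFactors = FALSE)
    regions$count <- vapply(regions$region, function(r) sum(sig == r), integer(1))
    regions$genes <- vapply(regions$region, function(r)
        paste(universe[sig == r], collapse = ","), character(1))
    rownames(regions) <- NULL

    inC <- member[, "C10"] | member[, "C60"]
    inI <- member[, "I10"] | member[, "I60"]
    out <- list(regions = regions,
                exclusiveCompatible = universe[inC & !inI],
                exclusiveIncompatible = universe[inI & !inC],
                setTotals = vapply(sets, length, integer(1)),
                union = universe)
    if (!is.null(nExpressed))
        out$setPct <- round(100 * out$setTotals / nExpressed, 1)
    out
}

#' Selectively induced genes, ranked by between-treatment fold-change ratio
#'
#' Restricts to a Venn-exclusive gene set, keeps genes whose
#' compatible-vs-incompatible contrast (e.g. C60 vs I60) passes the fold
#' change and adjusted-p thresholds, sorts by that fold change descending
#' and truncates to the top `topN`.
#'
#' @param exclusiveSet character vector (e.g. `exclusiveCompatible` from
#'   [vennPartition()]).
#' @param deRatio data.frame from [nbWaldTest()] for the between-treatment
#'   contrast, fold change oriented so larger means more selective.
#' @param fcRatioThreshold,padjThreshold selection thresholds (strict).
#' @param topN maximum genes returned.
#' @return data.frame `gene_id`, `fold_change`, `padj`, sorted descending by
#'   fold change; may be empty.
#' @export
selectInduced <- function(exclusiveSet, deRatio, fcRatioThreshold = 2,
                          padjThreshold = 0.1, topN = 10L) {
    d <- deRatio[deRatio$gene_id %in% exclusiveSet &
                 !is.na(deRatio$fold_change) &
                 deRatio$fold_change > fcRatioThreshold &
                 deRatio$padj < padjThreshold, , drop = FALSE]
    d <- d[order(d$fold_change, decreasing = TRUE), , drop = FALSE]
    d <- head(d, topN)
    data.frame(gene_id = d$gene_id, fold_change = d$fold_change,
               padj = d$padj, stringsAsFactors = FALSE, row.names = NULL)
}
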