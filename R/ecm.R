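## Expression Correlation Method: sex-specificity for SNP-less genes is
## predicted from the specificity labels of the top-ranked SNP-bearing
## co-expression neighbors. Thresholds are strict (> 35 stigma / > 25
## pollen of the top 50), so no target can ever receive both calls
## (36 + 26 = 62 > 50).

#' Genes eligible for specificity prediction
#'
#' Only highly expressed genes are predictable: the stigma+pollen nFPKM sum
#' at baseline must reach `minTotalNfpkm`.
#'
#' @param nfpkmStigma,nfpkmPollen named numeric vectors at the baseline
#'   condition.
#' @param minTotalNfpkm eligibility threshold (inclusive `>=`).
#' @return character vector of eligible gene ids.
#' @examples
#' eligibleTargets(c(a = 300, b = 349), c(a = 60, b = 0))  # "a"
#' @export
eligibleTargets <- function(nfpkmStigma, nfpkmPollen, minTotalNfpkm = 350) {
    stopifnot(identical(names(nfpkmStigma), names(nfpkmPollen)))
    names(nfpkmStigma)[nfpkmStigma + nfpkmPollen >= minTotalNfpkm]
}

#' Order and deduplicate one mutual-rank neighbor list
#'
#' Strict ordering by mutual-rank score ascending with lexicographic
#' neighbor-id tie-break; self-neighbors removed.
#'
#' @param ranks data.frame `target`, `neighbor`, `rank` for one target.
#' @param target the target gene id.
#' @return character vector of neighbor ids, most correlated first.
#' @keywords internal
.orderedNeighbors <- function(ranks, target) {
    r <- ranks[ranks$target == target & ranks$neighbor != target, , drop = FALSE]
    r <- r[order(r$rank, r$neighbor), , drop = FALSE]
    r$neighbor[!duplicated(r$neighbor)]
}

#' Predict sex-specificity of one target gene
#'
#' Looks up the target's neighbor list in an ordered sequence of
#' mutual-rank tables (first table holding a record wins, modelling a
#' primary microarray compendium with an RNA-seq fallback), filters
#' neighbors to SNP-bearing genes, truncates to the top `k`, counts
#' stigma- and pollen-specific labels among them and applies the strict
#' thresholds.
#'
#' @param target gene id.
#' @param rankTables a data.frame `target`/`neighbor`/`rank`, or a list of
#'   such tables tried in order.
#' @param labels named character vector: baseline specificity label per
#'   SNP-bearing gene, values `"stigma"`, `"pollen"` or `"none"`. Its names
#'   define the SNP-bearing gene universe used for filtering.
#' @param k neighbors retained after SNP filtering.
#' @param stigmaThreshold,pollenThreshold strict call thresholds.
#' @param truncateBeforeFilter if `TRUE`, truncate to the top `k` neighbors
#'   before filtering to SNP-bearing genes instead of after (the default
#'   filters first, reading the selection rule literally).
#' @return one-row data.frame `gene_id`, `eligible` (record found),
#'   `n_stigma`, `n_pollen`, `call` (`"stigma"`, `"pollen"` or `"none"`),
#'   `reason`.
#' @export
predictSpecificity <- function(target, rankTables, labels, k = 50L,
                               stigmaThreshold = 35L, pollenThreshold = 25L,
                               truncateBeforeFilter = FALSE) {
    if (is.data.frame(rankTables)) rankTables <- list(rankTables)
    nb <- NULL
    for (tab in rankTables) {
        if (target %in% tab$target) {
            nb <- .orderedNeighbors(tab, target)
            break
        }
    }
    if (is.null(nb))
        return(data.frame(gene_id = target, eligible = FALSE,
                          n_stigma = 0L, n_pollen = 0L, call = "none",
                          reason = "no record", stringsAsFactors = FALSE))
    if (truncateBeforeFilter) {
        nb <- head(nb, k)
        nb <- nb[nb %in% names(labels)]
    } else {
        nb <- nb[nb %in% names(labels)]
        nb <- head(nb, k)
    }
    nS <- sum(labels[nb] == "stigma")
    nP <- sum(labels[nb] == "pollen")
    call <- if (nS > stigmaThreshold) "stigma"
            else if (nP > pollenThreshold) "pollen" else "none"
    data.frame(gene_id = target, eligible = TRUE,
               n_stigma = nS, n_pollen = nP, call = call, reason = "",
               stringsAsFactors = FALSE)
}

#' Predict specificity for a set of targets
#'
#' @param targets character vector of gene ids (typically
#'   [eligibleTargets()]).
#' @param ... passed to [predictSpecificity()].
#' @inheritParams predictSpecificity
#' @return data.frame, one row per target.
#' @export
predictSpecificityAll <- function(targets, rankTables, labels, ...) {
    out <- lapply(targets, predictSpecificity, rankTables = rankTables,
                  labels = labels, ...)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Evaluate ECM predictions against truth
#'
#' Confusion summary over targets with a known specificity label: per class,
#' counts of correct, wrong and unpredicted calls, the percentage correct
#' among predicted calls, and overall totals.
#'
#' @param predictions data.frame from [predictSpecificityAll()].
#' @param truthLabels named character vector (`"stigma"`, `"pollen"`,
#'   other values are treated as unlabeled and ignored).
#' @return list with `byClass` (data.frame: class, n, correct, wrong,
#'   unpredicted, pct_correct), `nWrong`, `nUnpredicted`, `pctCorrect`
#'   (overall, among predicted labeled targets).
#' @export
evaluateEcm <- function(predictions, truthLabels) {
    keep <- predictions$gene_id %in%
        names(truthLabels)[truthLabels %in% c("stigma", "pollen")]
    p <- predictions[keep, , drop = FALSE]
    tl <- truthLabels[p$gene_id]
    rows <- lapply(c("stigma", "pollen"), function(cl) {
        sel <- tl == cl
        pred <- p$call[sel]
        predicted <- pred != "none"
        data.frame(class = cl, n = sum(sel),
                   correct = sum(pred == cl),
                   wrong = sum(predicted & pred != cl),
                   unpredicted = sum(!predicted),
                   pct_correct = if (any(predicted))
                       round(100 * sum(pred == cl) / sum(predicted), 1)
                       else NA_real_,
                   stringsAsFactors = FALSE)
    })
    byClass <- do.call(rbind, rows)
    predicted <- p$call != "none"
    list(byClass = byClass,
         nWrong = sum(predicted & p$call != tl),
         nUnpredicted = sum(!predicted),
         pctCorrect = if (any(predicted))
             round(100 * sum(p$call == tl) / sum(predicted), 1)
             else NA_real_)
}
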