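## FPKM / nFPKM and the self-contained differential-expression stand-in:
## median-of-ratios size factors and a per-gene negative-binomial Wald test
## with method-of-moments dispersion. Downstream selection rules consume
## only the linear fold change and the BH-adjusted p-value.

#' Fragments per kilobase per million assigned fragments
#'
#' `FPKM = count / (effectiveLength / 1e3) / (totalAssigned / 1e6)`.
#'
#' @param expectedCounts numeric vector of (possibly fractional) fragment
#'   counts.
#' @param effectiveLengths per-transcript effective lengths (>= 1).
#' @param totalAssigned total assigned fragments in the sample (> 0).
#' @return numeric FPKM vector.
#' @examples
#' computeFpkm(10, 1000, 1e6)   # 10
#' @export
computeFpkm <- function(expectedCounts, effectiveLengths, totalAssigned) {
    if (totalAssigned <= 0) stop("totalAssigned must be positive")
    if (any(effectiveLengths < 1)) stop("effective lengths must be >= 1")
    expectedCounts / (effectiveLengths / 1e3) / (totalAssigned / 1e6)
}

#' Tissue-proportion-normalized FPKM
#'
#' Divides the tissue's FPKM by the estimated proportion of fragments
#' derived from that tissue at the condition, making stigma and pollen
#' values directly comparable (an FPKM of 69 at a proportion of 0.69 and an
#' FPKM of 31 at 0.31 both become an nFPKM of 100).
#'
#' @param fpkm numeric FPKM vector for one tissue.
#' @param tissueProportion the tissue's fragment proportion, in (0, 1].
#' @return numeric nFPKM vector.
#' @export
normalizeFpkm <- function(fpkm, tissueProportion) {
    if (length(tissueProportion) != 1L || tissueProportion <= 0 ||
        tissueProportion > 1)
        stop("tissueProportion must be a single value in (0, 1]")
    fpkm / tissueProportion
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across genes of the ratio of its count to the
#' per-gene geometric mean; genes with a zero count in any sample are
#' excluded from the reference, the standard count-normalization estimator
#' for RNA-seq.
#'
#' @param countMatrix genes x samples numeric matrix (>= 2 samples).
#' @return numeric vector of per-sample factors.
#' @export
medianRatioSizeFactors <- function(countMatrix) {
    countMatrix <- as.matrix(countMatrix)
    if (ncol(countMatrix) < 2L) stop("need at least 2 samples")
    logGeo <- rowMeans(log(countMatrix))
    use <- is.finite(logGeo)
    if (!any(use))
        stop("no gene has a positive count in every sample")
    apply(countMatrix, 2L, function(k)
        exp(median((log(k) - logGeo)[use & k > 0])))
}

#' Negative-binomial Wald test between two groups
#'
#' Per-gene test on size-factor-normalized counts: group means, a pooled
#' method-of-moments NB dispersion `max(0, (var - mu) / mu^2)`, and a Wald
#' statistic on the log fold change with delta-method variance
#' `(1/mu + alpha) / n` per group against a normal reference. With only a
#' few replicates, gene-wise moment dispersions are extremely noisy and
#' frequently truncate at zero, which makes the raw Wald statistic
#' anti-conservative; each gene's dispersion is therefore floored at an
#' upper quantile (`dispersionFloorQuantile`) of the gene-wise estimates,
#' a simple moderation toward the ensemble in the spirit of common-dispersion
#' shrinkage. P-values are BH-adjusted; fold changes are reported on the
#' linear scale, computed with a 0.5 pseudocount on zero means so ratios
#' stay finite. All-zero genes are flagged and given p = 1.
#'
#' @param countsA,countsB genes x replicates matrices (same genes; >= 2
#'   replicates each).
#' @param sizeFactors per-sample factors for `cbind(countsA, countsB)`;
#'   default estimated by [medianRatioSizeFactors()].
#' @param dispersionFloorQuantile ensemble quantile used as the per-gene
#'   dispersion floor.
#' @return data.frame `gene_id`, `baseMeanA`, `baseMeanB`, `fold_change`
#'   (linear, B over A), `log2_fold_change`, `p_value`, `padj`, `all_zero`.
#' @export
nbWaldTest <- function(countsA, countsB,
                       sizeFactors = medianRatioSizeFactors(cbind(countsA, countsB)),
                       dispersionFloorQuantile = 0.75) {
    countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
    if (nrow(countsA) != nrow(countsB)) stop("gene universes differ")
    if (ncol(countsA) < 2L || ncol(countsB) < 2L)
        stop("need at least 2 replicates per group")
    nA <- ncol(countsA); nB <- ncol(countsB)
    sf <- sizeFactors
    normA <- sweep(countsA, 2L, sf[seq_len(nA)], "/")
    normB <- sweep(countsB, 2L, sf[nA + seq_len(nB)], "/")

    muA <- rowMeans(normA); muB <- rowMeans(normB)
    varA <- apply(normA, 1L, var); varB <- apply(normB, 1L, var)
    # pooled within-group variance, moments dispersion on the common scale
    muPool <- (nA * muA + nB * muB) / (nA + nB)
    varPool <- ((nA - 1) * varA + (nB - 1) * varB) / (nA + nB - 2)
    alpha <- pmax(0, (varPool - muPool) / muPool^2)
    alpha[!is.finite(alpha)] <- 0
    expressed <- muPool > 0
    if (any(expressed)) {
        floorAlpha <- quantile(alpha[expressed], dispersionFloorQuantile,
                               na.rm = TRUE, names = FALSE)
        alpha <- pmax(alpha, floorAlpha)
    }

    pcA <- ifelse(muA == 0, 0.5, 0); pcB <- ifelse(muB == 0, 0.5, 0)
    lfcNat <- log(muB + pcB) - log(muA + pcA)
    se <- sqrt((1 / pmax(muA, 1e-8) + alpha) / nA +
               (1 / pmax(muB, 1e-8) + alpha) / nB)
    stat <- lfcNat / se
    p <- 2 * pnorm(-abs(stat))

    allZero <- muA == 0 & muB == 0
    p[allZero] <- 1
    lfcNat[allZero] <- NA_real_
    padj <- p.adjust(p, method = "BH")

    gid <- rownames(countsA)
    if (is.null(gid)) gid <- as.character(seq_len(nrow(countsA)))
    data.frame(gene_id = gid, baseMeanA = muA, baseMeanB = muB,
               fold_change = exp(lfcNat),
               log2_fold_change = lfcNat / log(2),
               p_value = p, padj = padj, all_zero = allZero,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble an expression table
#'
#' Bundles per-gene expected counts, FPKM and nFPKM across condition x
#' tissue combinations into a [SummarizedExperiment::SummarizedExperiment]
#' whose columns are samples (`colData`: `condition`, `tissue`,
#' `proportion`). The nFPKM assay equals FPKM divided by the column's tissue
#' proportion, by construction.
#'
#' @param counts,fpkm genes x samples matrices (same dimnames).
#' @param condition,tissue per-column labels.
#' @param proportion per-column tissue fragment proportion in (0, 1).
#' @return a `SummarizedExperiment` with assays `counts`, `fpkm`, `nfpkm`.
#' @export
buildExpressionTable <- function(counts, fpkm, condition, tissue, proportion) {
    stopifnot(all(dim(counts) == dim(fpkm)),
              length(condition) == ncol(counts),
              length(tissue) == ncol(counts),
              length(proportion) == ncol(counts))
    if (any(proportion <= 0 | proportion >= 1))
        stop("tissue proportions must lie in (0, 1)")
    nfpkm <- sweep(fpkm, 2L, proportion, "/")
    SummarizedExperiment(
        assays = list(counts = counts, fpkm = fpkm, nfpkm = nfpkm),
        colData = DataFrame(condition = condition, tissue = tissue,
                            proportion = proportion))
}

#' nFPKM vectors for one condition
#'
#' @param se expression table from [buildExpressionTable()].
#' @param condition condition label.
#' @return list with named numeric vectors `stigma` and `pollen`.
#' @export
conditionNfpkm <- function(se, condition) {
    cd <- colData(se)
    pick <- function(tis) {
        j <- which(cd$condition == condition & cd$tissue == tis)
        if (length(j) != 1L)
            stop("expected exactly one ", tis, " column for ", condition)
        setNames(assays(se)$nfpkm[, j], rownames(se))
    }
    list(stigma = pick("stigma"), pollen = pick("pollen"))
}
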