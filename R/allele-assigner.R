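## EM assignment of mixed-origin fragments to the merged maternal+paternal
## transcript universe. The matcher enumerates gapless end-to-end placements
## (exact up to the mismatch budget); the EM shares each fragment across its
## compatible transcripts in proportion to abundance and mismatch likelihood,
## so reads over SNPs pull towards their allele and SNP-less reads split
## evenly - the behavior that lets the pipeline use every sequenced read.

#' Merge maternal and paternal transcriptomes
#'
#' Concatenates the two transcript sets into the single universe the
#' estimator works on, tagging names with `_mat` / `_pat` suffixes.
#'
#' @param maternalTx,paternalTx named [Biostrings::DNAStringSet] over the
#'   same gene universe.
#' @return named [Biostrings::DNAStringSet] of length `2 * n_genes`.
#' @export
mergeTranscriptomes <- function(maternalTx, paternalTx) {
    stopifnot(identical(sort(names(maternalTx)), sort(names(paternalTx))))
    m <- maternalTx; p <- paternalTx
    names(m) <- paste0(names(m), "_mat")
    names(p) <- paste0(names(p), "_pat")
    c(m, p)
}

#' Accession of origin per merged transcript name
#'
#' @param txNames names produced by [mergeTranscriptomes()].
#' @return named character vector, `"maternal"` or `"paternal"`.
#' @export
transcriptOrigin <- function(txNames) {
    out <- ifelse(grepl("_mat$", txNames), "maternal",
           ifelse(grepl("_pat$", txNames), "paternal", NA_character_))
    if (anyNA(out)) stop("transcript names must carry _mat/_pat suffixes")
    setNames(out, txNames)
}

#' Gene id per merged transcript name
#' @param txNames names produced by [mergeTranscriptomes()].
#' @return named character vector of gene ids.
#' @export
transcriptGene <- function(txNames) {
    setNames(sub("_(mat|pat)$", "", txNames), txNames)
}

#' Build the fragment-by-transcript compatibility matrix
#'
#' Places every fragment end-to-end (gapless) on every transcript reachable
#' with at most `maxMismatches` mismatches summed over both mates; mate 2 is
#' reverse-complemented and must align downstream of mate 1 on the same
#' transcript. Seeding uses a pigeonhole split of each mate into
#' `maxMismatches + 1` exact k-mer seeds, so the result equals a brute-force
#' scan over all offsets. Fragments with no compatible transcript are
#' recorded as unassigned.
#'
#' @param mate1,mate2 named character vectors (or `DNAStringSet`) of read
#'   sequences; pass `mate2 = NULL` for single-end mode.
#' @param transcripts named [Biostrings::DNAStringSet] (the merged
#'   universe).
#' @param maxMismatches mismatch budget per fragment (both mates combined).
#' @return a [CompatMatrix-class].
#' @export
buildCompatibility <- function(mate1, mate2, transcripts, maxMismatches = 4L) {
    m1 <- as.character(mate1)
    m2 <- if (is.null(mate2)) character() else as.character(mate2)
    txSeq <- as.character(transcripts)
    if (!length(txSeq)) stop("empty transcript set")
    ent <- .cpp_build_compat(unname(txSeq), unname(m1), unname(m2),
                             as.integer(maxMismatches))
    ent <- as.data.frame(ent)
    ent <- ent[order(ent$fragment, ent$tx), , drop = FALSE]
    rownames(ent) <- NULL
    L1 <- nchar(m1)[ent$fragment]
    ent$alen <- if (length(m2)) L1 + nchar(m2)[ent$fragment] else L1
    unas <- setdiff(seq_along(m1), unique(ent$fragment))
    new("CompatMatrix", entries = ent, txNames = names(txSeq),
        txLengths = nchar(unname(txSeq)), nFragments = length(m1),
        unassigned = as.integer(unas), maxMismatches = as.integer(maxMismatches))
}

#' Estimate allele-specific abundances by EM with a Dirichlet prior
#'
#' Finite-mixture model: a fragment from transcript `t` with `m` mismatches
#' over `L` aligned bases has likelihood `theta_t * e^m * (1-e)^(L-m)`.
#' The E-step computes fragment responsibilities proportional to that
#' product; the M-step updates `theta_t` proportional to the responsibility
#' sum plus the symmetric Dirichlet pseudocount (posterior-mean flavor, so a
#' pseudocount of 1 is the uniform-prior Bayesian mean). The maximized
#' objective (data log-likelihood plus Dirichlet log-prior) is non-decreasing
#' and its relative change drives convergence. Expected counts are
#' responsibility sums; FPKM uses effective lengths
#' `max(1, length - fragmentLength + 1)`.
#'
#' @param compat a [CompatMatrix-class].
#' @param errorRate assumed per-base mismatch probability.
#' @param priorPseudocount symmetric Dirichlet pseudocount (>= 0).
#' @param tol relative objective-change convergence threshold.
#' @param maxIter iteration cap; non-convergence returns with
#'   `converged = FALSE` and a warning.
#' @param fragmentLength nominal fragment length for effective lengths.
#' @return an [AbundanceEstimate-class].
#' @export
estimateAbundance <- function(compat, errorRate = 0.01, priorPseudocount = 1,
                              tol = 1e-8, maxIter = 1000L,
                              fragmentLength = 250) {
    e <- compat@entries
    if (!nrow(e)) stop("compatibility matrix has no entries")
    nT <- length(compat@txNames)
    fragIdx <- match(e$fragment, sort(unique(e$fragment)))
    nF <- max(fragIdx)

    logw <- e$mismatch * log(errorRate) +
        (e$alen - e$mismatch) * log1p(-errorRate)
    # per-fragment scaling keeps weights in floating range
    perFragScale <- as.vector(tapply(logw, fragIdx, max))
    w <- exp(logw - perFragScale[fragIdx])

    theta <- rep(1 / nT, nT)
    a <- priorPseudocount
    priorTerm <- function(th) if (a > 0) a * sum(log(th)) else 0
    countSums <- function(resp) {
        Nt <- numeric(nT)
        agg <- rowsum(resp, e$tx)
        Nt[as.integer(rownames(agg))] <- agg
        Nt
    }
    trace <- numeric()
    prev <- -Inf
    converged <- FALSE
    iter <- 0L
    ll <- NA_real_
    while (iter < maxIter) {
        iter <- iter + 1L
        s <- theta[e$tx] * w
        denom <- as.vector(rowsum(s, fragIdx))
        ll <- sum(log(denom)) + sum(perFragScale)
        obj <- ll + priorTerm(theta)
        trace <- c(trace, obj)
        if (is.finite(prev) &&
            abs(obj - prev) <= tol * (abs(prev) + .Machine$double.eps)) {
            converged <- TRUE
            break
        }
        prev <- obj
        r <- s / denom[fragIdx]
        theta <- (countSums(r) + a) / (nF + a * nT)
    }
    if (!converged)
        warning("EM did not converge in ", maxIter, " iterations")

    # expected counts at the returned theta
    s <- theta[e$tx] * w
    denom <- as.vector(rowsum(s, fragIdx))
    Nt <- countSums(s / denom[fragIdx])
    ll <- sum(log(denom)) + sum(perFragScale)

    effLen <- pmax(1, compat@txLengths - fragmentLength + 1)
    fpkm <- computeFpkm(Nt, effLen, nF)
    nm <- compat@txNames
    new("AbundanceEstimate",
        theta = setNames(theta, nm), expectedCounts = setNames(Nt, nm),
        effectiveLengths = setNames(effLen, nm), fpkm = setNames(fpkm, nm),
        logPosteriorTrace = trace, logLikelihood = ll,
        iterations = iter, converged = converged, nFragments = nF)
}

#' Per-fragment posterior responsibilities
#'
#' Responsibility of each compatible transcript for each fragment at the
#' estimate's converged abundances; rows of one fragment sum to 1.
#'
#' @param compat the [CompatMatrix-class] used for estimation.
#' @param estimate the fitted [AbundanceEstimate-class].
#' @param errorRate the error rate used for estimation.
#' @return data.frame `fragment`, `tx`, `responsibility`.
#' @export
fragmentResponsibilities <- function(compat, estimate, errorRate = 0.01) {
    e <- compat@entries
    fragIdx <- match(e$fragment, sort(unique(e$fragment)))
    logw <- e$mismatch * log(errorRate) +
        (e$alen - e$mismatch) * log1p(-errorRate)
    w <- exp(logw - as.vector(tapply(logw, fragIdx, max))[fragIdx])
    s <- unname(estimate@theta)[e$tx] * w
    denom <- as.vector(rowsum(s, fragIdx))
    data.frame(fragment = e$fragment, tx = e$tx,
               responsibility = s / denom[fragIdx])
}

#' Tissue (accession) proportions from an abundance estimate
#'
#' @param estimate an [AbundanceEstimate-class] over the merged universe.
#' @param originLabels named character vector mapping transcript name to
#'   `"maternal"` / `"paternal"` (default derived from name suffixes).
#' @return named numeric `c(maternal = , paternal = )`, summing to 1.
#' @export
tissueProportions <- function(estimate,
                              originLabels = transcriptOrigin(names(estimate@expectedCounts))) {
    cnt <- estimate@expectedCounts
    if (!all(names(cnt) %in% names(originLabels)))
        stop("every transcript must carry an origin label")
    tot <- sum(cnt)
    mat <- sum(cnt[originLabels[names(cnt)] == "maternal"])
    c(maternal = mat / tot, paternal = (tot - mat) / tot)
}

#' Aggregate expected counts to gene x accession
#'
#' @param estimate an [AbundanceEstimate-class] over the merged universe.
#' @return data.frame `gene_id`, `maternal_count`, `paternal_count`,
#'   `maternal_fpkm`, `paternal_fpkm`.
#' @export
geneAccessionCounts <- function(estimate) {
    nm <- names(estimate@expectedCounts)
    gene <- transcriptGene(nm)
    origin <- transcriptOrigin(nm)
    ids <- sort(unique(gene))
    pick <- function(v, acc) {
        sel <- origin == acc
        setNames(v[sel], gene[sel])[ids]
    }
    data.frame(gene_id = ids,
               maternal_count = unname(pick(estimate@expectedCounts, "maternal")),
               paternal_count = unname(pick(estimate@expectedCounts, "paternal")),
               maternal_fpkm = unname(pick(estimate@fpkm, "maternal")),
               paternal_fpkm = unname(pick(estimate@fpkm, "paternal")),
               stringsAsFactors = FALSE)
}
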