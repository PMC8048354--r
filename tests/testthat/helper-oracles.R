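# Independent oracles and small fixture builders used across test files.
# Oracles are deliberately naive (exhaustive scans, direct formulas) and
# share no code with the implementation paths they check.

tinyConfig <- function(...) {
    args <- list(nChromosomes = 1L, chromosomeLength = 60000L, nGenes = 10L,
                 nReads = 2000L, rngSeed = 42L)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(simConfig, args)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

revcompChr <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

mismAt <- function(txt, q, o) {
    # mismatches of q aligned at 1-based offset o; N never matches
    a <- strsplit(substr(txt, o, o + nchar(q) - 1L), "")[[1]]
    b <- strsplit(q, "")[[1]]
    sum(a != b | !(b %in% c("A", "C", "G", "T")) | !(a %in% c("A", "C", "G", "T")))
}

# exhaustive offset-by-offset paired placement scan; mirrors the matcher's
# contract (mate2 reverse-complemented, downstream of mate1, best kept)
bruteCompat <- function(txSeqs, m1, m2, maxMis) {
    rows <- list()
    for (f in seq_along(m1)) {
        r2 <- if (is.null(m2)) NULL else revcompChr(m2[f])
        for (t in seq_along(txSeqs)) {
            txt <- txSeqs[t]
            best <- maxMis + 1L
            for (o1 in seq_len(max(0L, nchar(txt) - nchar(m1[f]) + 1L))) {
                mm1 <- mismAt(txt, m1[f], o1)
                if (mm1 > maxMis) next
                if (is.null(r2)) {
                    best <- min(best, mm1)
                } else {
                    o2max <- nchar(txt) - nchar(r2) + 1L
                    if (o2max >= o1)
                        for (o2 in o1:o2max)
                            best <- min(best, mm1 + mismAt(txt, r2, o2))
                }
            }
            if (best <= maxMis)
                rows[[length(rows) + 1L]] <- data.frame(fragment = f, tx = t,
                                                        mismatch = best)
        }
    }
    if (!length(rows))
        return(data.frame(fragment = integer(), tx = integer(),
                          mismatch = integer()))
    out <- do.call(rbind, rows)
    out[order(out$fragment, out$tx), ]
}

# exhaustive finite-mixture evaluation: marginal posterior responsibility of
# each transcript per fragment, enumerating all |T|^|F| assignment vectors
bruteResponsibilities <- function(entries, theta, errorRate) {
    frags <- sort(unique(entries$fragment))
    lik <- function(row) theta[row$tx] * errorRate^row$mismatch *
        (1 - errorRate)^(row$alen - row$mismatch)
    perFrag <- lapply(frags, function(f) entries[entries$fragment == f, ,
                                                 drop = FALSE])
    choices <- lapply(perFrag, function(d) seq_len(nrow(d)))
    grid <- expand.grid(choices)
    weights <- apply(grid, 1L, function(idx) {
        prod(vapply(seq_along(frags), function(i)
            lik(perFrag[[i]][idx[i], , drop = FALSE]), numeric(1)))
    })
    weights <- weights / sum(weights)
    out <- list()
    for (i in seq_along(frags)) {
        d <- perFrag[[i]]
        marg <- vapply(seq_len(nrow(d)), function(j)
            sum(weights[grid[[i]] == j]), numeric(1))
        out[[i]] <- data.frame(fragment = frags[i], tx = d$tx,
                               responsibility = marg)
    }
    do.call(rbind, out)
}

# direct Benjamini-Hochberg from the definition (step-up, cumulative min)
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
}

# full synthetic dataset at small scale, reused by several files
makeDataset <- function(cfg = tinyConfig()) {
    ref <- generateReference(cfg)
    pair <- generateAccessionPair(ref$genome, ref$geneModels, cfg)
    truth <- generateExpressionTruth(ref$geneModels, pair$snplessGenes, cfg)
    mt <- extractTranscripts(pair$maternalGenome, ref$geneModels)
    pt <- extractTranscripts(pair$paternalGenome, ref$geneModels)
    list(cfg = cfg, ref = ref, pair = pair, truth = truth,
         maternalTx = mt, paternalTx = pt,
         merged = mergeTranscriptomes(mt, pt))
}

# hand-built truth object (only the fields generateMutualRankTable and the
# ECM path consume), for label-structure tests that need many genes
fakeTruth <- function(n, labels, snpless) {
    ids <- sprintf("g%04d", seq_len(n))
    list(genes = data.frame(gene_id = ids, label = labels,
                            snpless = snpless, stringsAsFactors = FALSE))
}
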