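## Synthetic two-accession data with recorded ground truth. Every generator
## derives its RNG stream from config@rngSeed (plus a small fixed offset per
## stage) so the full input set is bit-reproducible.

.seedOffset <- c(reference = 0L, pair = 1L, truth = 2L, reads = 3L, ranks = 4L)

.geneId <- function(i) sprintf("g%04d", i)

#' Generate a reference genome and gene models
#'
#' Draws uniform-random chromosome sequences and places non-overlapping gene
#' models (one transcript each) with random strand and exon structure. Exon
#' lengths are drawn in 150-400 bp and inflated where needed so every
#' transcript is at least `fragmentLengthMean + 4 * fragmentLengthSd` long,
#' keeping all genes sequenceable at the configured fragment layout.
#'
#' @param config a [SimConfig-class].
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `geneModels` (exon-level [GenomicRanges::GRanges] with `gene_id`,
#'   `exon_rank` metadata).
#' @examples
#' ref <- generateReference(simConfig(nGenes = 5L))
#' ref$geneModels
#' @export
generateReference <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (config@nGenes < 1L) stop("nGenes must be at least 1")
    set.seed(config@rngSeed + .seedOffset[["reference"]])

    chromNames <- paste0("chr", seq_len(config@nChromosomes))
    genome <- DNAStringSet(vapply(chromNames, function(cn) {
        paste(sample(c("A", "C", "G", "T"), config@chromosomeLength,
                     replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- chromNames

    minTx <- ceiling(config@fragmentLengthMean + 4 * config@fragmentLengthSd)
    chromOf <- rep(seq_len(config@nChromosomes), length.out = config@nGenes)

    rows <- vector("list", config@nGenes)
    for (ci in seq_len(config@nChromosomes)) {
        gidx <- which(chromOf == ci)
        if (!length(gidx)) next
        structs <- lapply(gidx, function(g) {
            nEx <- sample(seq(config@exonsPerGene[1], config@exonsPerGene[2]), 1L)
            exLen <- sample(150:400, nEx, replace = TRUE)
            deficit <- minTx - sum(exLen)
            if (deficit > 0) exLen[nEx] <- exLen[nEx] + deficit
            inLen <- if (nEx > 1L) sample(60:200, nEx - 1L, replace = TRUE) else integer()
            list(exLen = exLen, inLen = inLen, span = sum(exLen) + sum(inLen))
        })
        spans <- vapply(structs, `[[`, numeric(1), "span")
        leftover <- config@chromosomeLength - sum(spans)
        if (leftover < length(gidx) + 1L)
            stop("cannot place ", length(gidx), " genes on a ",
                 config@chromosomeLength, " bp chromosome without overlap")
        gaps <- as.vector(rmultinom(1L, size = leftover - (length(gidx) + 1L),
                                    prob = rep(1, length(gidx) + 1L))) + 1L
        pos <- 1L
        for (j in seq_along(gidx)) {
            pos <- pos + gaps[j]
            st <- structs[[j]]
            exStart <- pos + cumsum(c(0L, st$exLen[-length(st$exLen)] +
                                          st$inLen))
            rows[[gidx[j]]] <- data.frame(
                chrom = paste0("chr", ci),
                start = exStart, end = exStart + st$exLen - 1L,
                gene_id = .geneId(gidx[j]),
                exon_rank = seq_along(st$exLen))
            pos <- pos + st$span
        }
    }
    tab <- do.call(rbind, rows)
    strandOf <- sample(c("+", "-"), config@nGenes, replace = TRUE)
    gm <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                  strand = strandOf[match(tab$gene_id, .geneId(seq_len(config@nGenes)))],
                  gene_id = tab$gene_id, exon_rank = tab$exon_rank)
    list(genome = genome, geneModels = gm)
}

#' Generate an accession pair differing by SNPs
#'
#' Scatters biallelic SNPs over the genome at `snpRate`, keeps a configured
#' fraction of genes free of transcript SNPs (masking their exons) and forces
#' at least one exonic SNP into every other gene, so the SNP-less gene set is
#' exact by construction. SNPs are attributed to the maternal or paternal
#' line (relative to the common reference) at `maternalSnpFraction`.
#'
#' @param genome,geneModels output of [generateReference()].
#' @param config a [SimConfig-class].
#' @return list with `vcfMaternal` / `vcfPaternal` (variant record
#'   data.frames, see [filterVariants()]), `maternalGenome`,
#'   `paternalGenome` ([Biostrings::DNAStringSet]) and `snplessGenes`
#'   (character).
#' @export
generateAccessionPair <- function(genome, geneModels, config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@rngSeed + .seedOffset[["pair"]])

    geneIds <- unique(mcols(geneModels)$gene_id)
    nSnpless <- round(config@snplessGeneFraction * length(geneIds))
    snplessGenes <- sort(sample(geneIds, nSnpless))

    exonsBySnpless <- geneModels[mcols(geneModels)$gene_id %in% snplessGenes]
    allExons <- geneModels

    recs <- list()
    for (cn in names(genome)) {
        len <- length(genome[[cn]])
        pos <- which(runif(len) < config@snpRate)
        if (length(pos)) {
            masked <- exonsBySnpless[as.character(seqnames(exonsBySnpless)) == cn]
            if (length(masked)) {
                inMasked <- rep(FALSE, length(pos))
                for (i in seq_along(masked))
                    inMasked <- inMasked | (pos >= start(masked)[i] & pos <= end(masked)[i])
                pos <- pos[!inMasked]
            }
        }
        # force one exonic SNP into SNP-bearing genes missed by the scatter
        exHere <- allExons[as.character(seqnames(allExons)) == cn &
                           !(mcols(allExons)$gene_id %in% snplessGenes)]
        if (length(exHere)) {
            for (g in unique(mcols(exHere)$gene_id)) {
                ex <- exHere[mcols(exHere)$gene_id == g]
                hit <- any(vapply(seq_along(ex), function(i)
                    any(pos >= start(ex)[i] & pos <= end(ex)[i]), logical(1)))
                if (!hit) {
                    i <- sample(length(ex), 1L)
                    pos <- c(pos, sample(start(ex)[i]:end(ex)[i], 1L))
                }
            }
        }
        pos <- sort(unique(pos))
        if (!length(pos)) next
        ref <- as.character(Biostrings::extractAt(genome[[cn]], IRanges(pos, pos)))
        alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      character(1), USE.NAMES = FALSE)
        recs[[cn]] <- data.frame(chrom = cn, pos = pos, ref = ref, alt = alt,
                                 stringsAsFactors = FALSE)
    }
    vcf <- do.call(rbind, recs)
    rownames(vcf) <- NULL
    vcf$depth <- rpois(nrow(vcf), 30) + 10L
    vcf$genotype <- "1/1"
    vcf$is_snp <- TRUE
    toMaternal <- runif(nrow(vcf)) < config@maternalSnpFraction
    vcfMaternal <- vcf[toMaternal, , drop = FALSE]
    vcfPaternal <- vcf[!toMaternal, , drop = FALSE]

    list(vcfMaternal = vcfMaternal, vcfPaternal = vcfPaternal,
         maternalGenome = applySnps(genome, vcfMaternal),
         paternalGenome = applySnps(genome, vcfPaternal),
         snplessGenes = snplessGenes)
}

.responseProfiles <- c("C10,C60", "C60", "I10,I60", "I60", "C10,C60,I10,I60")

#' Generate expression ground truth
#'
#' Assigns each gene a tissue pattern (stigma-specific, pollen-specific or
#' shared), draws log-normal expression levels per tissue (the silent tissue
#' of a specific gene is set to 0), flags pollination-responsive genes with
#' fixed condition profiles, and records the implied true nFPKM and
#' specificity class labels at baseline.
#'
#' @param geneModels exon [GenomicRanges::GRanges] from [generateReference()].
#' @param snplessGenes character vector from [generateAccessionPair()].
#' @param config a [SimConfig-class].
#' @return list with `genes` (per-gene data.frame: label, levels, true nFPKM
#'   and implied class), `induced` (gene x tissue x condition flags, long
#'   format) and `txLengths` (named integer).
#' @export
generateExpressionTruth <- function(geneModels, snplessGenes, config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@rngSeed + .seedOffset[["truth"]])

    exLen <- GenomicRanges::width(geneModels)
    txLen <- tapply(exLen, mcols(geneModels)$gene_id, sum)
    geneIds <- names(txLen)
    n <- length(geneIds)

    # Tissue labels are drawn among SNP-bearing genes only, and SNP-less
    # genes get one balanced level for both tissues: the estimator must
    # split SNP-less reads evenly, so the mixing proportion is identifiable
    # only when SNP-less expression is tissue-balanced. Sex-specific
    # SNP-less genes in real data are exactly the cases handed to the
    # co-expression predictor instead.
    isSnpless <- geneIds %in% snplessGenes
    nS <- round(config@stigmaSpecificFraction * n)
    nP <- round(config@pollenSpecificFraction * n)
    bearing <- which(!isSnpless)
    if (nS + nP > length(bearing))
        stop("specific fractions exceed the SNP-bearing gene pool")
    label <- rep("shared", n)
    pick <- sample(bearing, nS + nP)
    label[pick[seq_len(nS)]] <- "stigma"
    label[pick[nS + seq_len(nP)]] <- "pollen"

    levelStigma <- rlnorm(n, config@levelMeanlog, config@levelSdlog)
    levelPollen <- rlnorm(n, config@levelMeanlog, config@levelSdlog)
    levelStigma[isSnpless] <- levelStigma[isSnpless] * config@snplessLevelScale
    levelPollen[isSnpless] <- levelStigma[isSnpless]
    levelStigma[label == "pollen"] <- 0
    levelPollen[label == "stigma"] <- 0

    effLen <- pmax(1, as.numeric(txLen) - config@fragmentLengthMean + 1)
    pS <- levelStigma / sum(levelStigma)
    pP <- levelPollen / sum(levelPollen)
    nfpkmS <- 1e9 * pS / effLen
    nfpkmP <- 1e9 * pP / effLen

    # implied baseline class per tissue (the generator's own arithmetic; the
    # classifier module must recover exactly these labels on noise-free input)
    classOf <- function(own, oth) {
        ifelse(own > 1 & own >= 10 * oth & oth <= 1 & own > 100 & own > 100 * oth,
               "specific",
        ifelse(own > 1 & own >= 10 * oth, "preferential",
        ifelse(own > 1, "expressed", "none")))
    }
    genes <- data.frame(
        gene_id = geneIds, label = label,
        snpless = geneIds %in% snplessGenes,
        levelStigma = levelStigma, levelPollen = levelPollen,
        trueNfpkmStigma = nfpkmS, trueNfpkmPollen = nfpkmP,
        classStigma = classOf(nfpkmS, nfpkmP),
        classPollen = classOf(nfpkmP, nfpkmS),
        stringsAsFactors = FALSE)

    induced <- list()
    for (tis in c("stigma", "pollen")) {
        lev <- if (tis == "stigma") levelStigma else levelPollen
        pool <- geneIds[lev > 0 & !(geneIds %in% snplessGenes)]
        nResp <- min(config@nResponseGenes, length(pool))
        respGenes <- sample(pool, nResp)
        prof <- rep(.responseProfiles, length.out = nResp)
        for (i in seq_len(nResp)) {
            conds <- strsplit(prof[i], ",")[[1]]
            induced[[length(induced) + 1L]] <- data.frame(
                gene_id = respGenes[i], tissue = tis, condition = conds,
                foldChange = config@responseFoldChange,
                stringsAsFactors = FALSE)
        }
    }
    induced <- if (length(induced)) do.call(rbind, induced) else
        data.frame(gene_id = character(), tissue = character(),
                   condition = character(), foldChange = numeric())

    list(genes = genes, induced = induced,
         txLengths = setNames(as.integer(txLen), geneIds))
}

#' Expression levels under a condition
#'
#' Applies the induced-gene fold changes of `truth` to the baseline levels.
#'
#' @param truth output of [generateExpressionTruth()].
#' @param condition condition label (e.g. `"C60"`).
#' @return list with named numeric vectors `stigma` and `pollen`.
#' @export
conditionLevels <- function(truth, condition) {
    g <- truth$genes
    lev <- list(stigma = setNames(g$levelStigma, g$gene_id),
                pollen = setNames(g$levelPollen, g$gene_id))
    ind <- truth$induced[truth$induced$condition == condition, , drop = FALSE]
    for (i in seq_len(nrow(ind)))
        lev[[ind$tissue[i]]][ind$gene_id[i]] <-
            lev[[ind$tissue[i]]][ind$gene_id[i]] * ind$foldChange[i]
    lev
}

## substitute sequencing errors in place, vectorized over the few hit reads
.injectErrors <- function(reads, rate) {
    if (rate <= 0 || !length(reads)) return(reads)
    L <- nchar(reads)
    nErr <- rbinom(length(reads), L, rate)
    hit <- which(nErr > 0)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        s <- strsplit(reads[i], "")[[1]]
        at <- sample(L[i], nErr[i])
        for (p in at) s[p] <- sample(setdiff(bases, s[p]), 1L)
        reads[i] <- paste(s, collapse = "")
    }
    reads
}

#' Simulate mixed-tissue paired-end reads
#'
#' Draws each fragment's accession of origin first (Bernoulli at
#' `maternalFraction`), then a transcript within that accession with
#' probability proportional to its expression level under `condition`, then a
#' fragment position and length (normal, clipped to the transcript). Mate 1
#' is the fragment 5' end, mate 2 the reverse complement of its 3' end;
#' per-base substitution errors are applied at `sequencingErrorRate`.
#' Expressed transcripts shorter than the nominal fragment length are skipped
#' with a warning.
#'
#' @param maternalTx,paternalTx named [Biostrings::DNAStringSet] of spliced
#'   transcripts (same gene universe).
#' @param truth output of [generateExpressionTruth()].
#' @param config a [SimConfig-class].
#' @param condition condition label whose expression levels apply.
#' @param seed RNG seed for this sample (so replicates differ); defaults to
#'   the config seed plus a fixed offset.
#' @return list with `mate1`, `mate2` (named character vectors),
#'   `truthLog` (per-fragment source data.frame) and `skippedGenes`.
#' @export
simulateReads <- function(maternalTx, paternalTx, truth, config,
                          condition = "C0",
                          seed = config@rngSeed + .seedOffset[["reads"]]) {
    stopifnot(is(config, "SimConfig"))
    set.seed(seed)
    lev <- conditionLevels(truth, condition)

    txSets <- list(maternal = as.character(maternalTx),
                   paternal = as.character(paternalTx))
    levSets <- list(maternal = lev$stigma[names(maternalTx)],
                    paternal = lev$pollen[names(paternalTx)])

    skipped <- character()
    for (acc in names(txSets)) {
        short <- names(txSets[[acc]])[nchar(txSets[[acc]]) < config@fragmentLengthMean &
                                      levSets[[acc]] > 0]
        if (length(short)) {
            skipped <- union(skipped, short)
            levSets[[acc]][short] <- 0
        }
    }
    if (length(skipped))
        warning("skipping ", length(skipped),
                " expressed gene(s) shorter than the nominal fragment length: ",
                paste(head(skipped, 5), collapse = ", "))

    nM <- rbinom(1L, config@nReads, config@maternalFraction)
    counts <- c(maternal = nM, paternal = config@nReads - nM)

    m1 <- m2 <- character(config@nReads)
    logRows <- vector("list", 2L)
    ofs <- 0L
    for (acc in names(txSets)) {
        nAcc <- counts[[acc]]
        if (nAcc == 0L) { logRows[[acc]] <- NULL; next }
        p <- levSets[[acc]]
        p[is.na(p)] <- 0
        if (sum(p) <= 0) stop("no expressed transcripts for accession ", acc)
        txi <- sample(length(p), nAcc, replace = TRUE, prob = p)
        txSeq <- txSets[[acc]]
        txLen <- nchar(txSeq)
        fragLen <- pmin(pmax(round(rnorm(nAcc, config@fragmentLengthMean,
                                         config@fragmentLengthSd)),
                             config@readLength), txLen[txi])
        startP <- floor(runif(nAcc) * (txLen[txi] - fragLen + 1)) + 1L
        frag <- substr(rep(txSeq[txi], 1L), startP, startP + fragLen - 1L)
        r1 <- substr(frag, 1L, config@readLength)
        r2 <- as.character(reverseComplement(DNAStringSet(
            substr(frag, fragLen - config@readLength + 1L, fragLen))))
        idx <- ofs + seq_len(nAcc)
        m1[idx] <- .injectErrors(r1, config@sequencingErrorRate)
        m2[idx] <- .injectErrors(r2, config@sequencingErrorRate)
        logRows[[acc]] <- data.frame(
            fragment_id = sprintf("frag_%06d", idx),
            accession = acc, gene_id = names(txSeq)[txi],
            start = startP, fragment_length = fragLen,
            stringsAsFactors = FALSE)
        ofs <- ofs + nAcc
    }
    ids <- sprintf("frag_%06d", seq_len(config@nReads))
    names(m1) <- names(m2) <- ids
    truthLog <- do.call(rbind, logRows)
    rownames(truthLog) <- NULL
    list(mate1 = m1, mate2 = m2, truthLog = truthLog, skippedGenes = skipped)
}

#' Write a simulated sample as paired FASTQ
#'
#' @param reads output of [simulateReads()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with `/1`, `/2` read-name suffixes and constant
#'   quality.
#' @return the two file paths, invisibly.
#' @export
writeFastqPair <- function(reads, prefix) {
    paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    for (m in 1:2) {
        seqs <- if (m == 1) reads$mate1 else reads$mate2
        con <- file(paths[m], "w")
        writeLines(paste0("@", names(seqs), "/", m, "\n", seqs, "\n+\n",
                          vapply(nchar(seqs), function(l)
                              paste(rep("I", l), collapse = ""), character(1))),
                   con)
        close(con)
    }
    invisible(paths)
}

#' Read a paired FASTQ sample back into mate vectors
#'
#' @param prefix path prefix as used by [writeFastqPair()].
#' @return list with `mate1` and `mate2` named character vectors.
#' @export
readFastqPair <- function(prefix) {
    rd <- function(path, m) {
        x <- readDNAStringSet(path, format = "fastq")
        out <- as.character(x)
        names(out) <- sub(paste0("/", m, "$"), "", names(x))
        out
    }
    list(mate1 = rd(paste0(prefix, "_1.fastq"), 1),
         mate2 = rd(paste0(prefix, "_2.fastq"), 2))
}

#' Generate a co-expression mutual-rank table
#'
#' For each gene, emits an ordered neighbor list in which SNP-bearing genes
#' sharing the target's tissue label are enriched at top ranks. With
#' `corruption = 0` every neighbor shares the target's label; with
#' `corruption = 1` neighbors are drawn uniformly, independent of the target.
#' Neighbor lists need not be mutual.
#'
#' @param truth output of [generateExpressionTruth()].
#' @param config a [SimConfig-class].
#' @param nNeighbors neighbors per target.
#' @param corruption probability that a neighbor slot is drawn uniformly at
#'   random instead of from the label-matched SNP-bearing pool.
#' @param seed RNG seed.
#' @return data.frame with columns `target`, `neighbor`, `rank` (ascending =
#'   more correlated).
#' @export
generateMutualRankTable <- function(truth, config, nNeighbors = 100L,
                                    corruption = 0,
                                    seed = config@rngSeed + .seedOffset[["ranks"]]) {
    set.seed(seed)
    g <- truth$genes
    pools <- split(g$gene_id[!g$snpless], g$label[!g$snpless])
    out <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
        target <- g$gene_id[i]
        same <- setdiff(pools[[g$label[i]]], target)
        nCorrupt <- rbinom(1L, nNeighbors, corruption)
        nSame <- min(nNeighbors - nCorrupt, length(same))
        nb <- if (nSame > 0) sample(same, nSame) else character()
        nCorrupt <- nNeighbors - length(nb)
        if (nCorrupt > 0) {
            others <- setdiff(g$gene_id, c(target, nb))
            nb <- c(nb, sample(others, min(nCorrupt, length(others))))
        }
        # corrupted slots are interleaved so rank carries no label signal
        # beyond the intended enrichment
        if (corruption > 0) nb <- sample(nb)
        out[[i]] <- data.frame(target = target, neighbor = nb,
                               rank = seq_along(nb), stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
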