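# Synthetic-data generators: determinism, count conservation, binomial SNP
# density, forced SNP-less genes, read-simulation fidelity, mutual-rank
# neighbor structure.

test_that("generators are bit-reproducible under a fixed seed", {
    cfg <- tinyConfig()
    a <- generateReference(cfg)
    b <- generateReference(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(as.data.frame(a$geneModels), as.data.frame(b$geneModels))

    fa <- tempfile(fileext = ".gff3"); fb <- tempfile(fileext = ".gff3")
    writeGeneModelsGff3(a$geneModels, fa)
    writeGeneModelsGff3(b$geneModels, fb)
    expect_identical(readLines(fa), readLines(fb))

    pa <- generateAccessionPair(a$genome, a$geneModels, cfg)
    pb <- generateAccessionPair(b$genome, b$geneModels, cfg)
    expect_identical(pa$vcfPaternal, pb$vcfPaternal)
    expect_identical(as.character(pa$maternalGenome),
                     as.character(pb$maternalGenome))

    ta <- generateExpressionTruth(a$geneModels, pa$snplessGenes, cfg)
    mt <- extractTranscripts(pa$maternalGenome, a$geneModels)
    pt <- extractTranscripts(pa$paternalGenome, a$geneModels)
    ra <- suppressWarnings(simulateReads(mt, pt, ta, cfg))
    rb <- suppressWarnings(simulateReads(mt, pt, ta, cfg))
    expect_identical(ra$mate1, rb$mate1)
    expect_identical(ra$truthLog, rb$truthLog)
})

test_that("degenerate configurations are rejected", {
    expect_error(simConfig(nGenes = 0L), "positive")
    expect_error(simConfig(maternalFraction = 1), "maternalFraction")
    expect_error(simConfig(snpRate = 0.2), "snpRate")
    # genes that cannot be placed without overlap
    cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 5000L,
                     nGenes = 20L, fragmentLengthMean = 250)
    expect_error(generateReference(cfg), "without overlap")
})

test_that("requested gene count is conserved in the models and on disk", {
    cfg <- simConfig(nGenes = 50L, chromosomeLength = 200000L, rngSeed = 11L)
    ref <- generateReference(cfg)
    expect_identical(length(unique(GenomicRanges::mcols(ref$geneModels)$gene_id)),
                     50L)
    f <- tempfile(fileext = ".gff3")
    writeGeneModelsGff3(ref$geneModels, f)
    back <- readGeneModelsGff3(f)
    expect_identical(length(unique(GenomicRanges::mcols(back)$gene_id)), 50L)
    # non-overlap within each chromosome
    for (cn in unique(as.character(GenomicRanges::seqnames(ref$geneModels)))) {
        ex <- ref$geneModels[as.character(GenomicRanges::seqnames(ref$geneModels)) == cn]
        ex <- ex[order(GenomicRanges::start(ex))]
        expect_true(all(diff(GenomicRanges::start(ex)) > 0))
        expect_true(all(GenomicRanges::start(ex)[-1] >
                        GenomicRanges::end(ex)[-length(ex)]))
    }
})

test_that("SNP count follows the configured binomial density", {
    cfg <- simConfig(nChromosomes = 2L, chromosomeLength = 500000L,
                     nGenes = 5L, snpRate = 0.001, snplessGeneFraction = 0,
                     rngSeed = 9L)
    ref <- generateReference(cfg)
    pair <- generateAccessionPair(ref$genome, ref$geneModels, cfg)
    n <- nrow(pair$vcfMaternal) + nrow(pair$vcfPaternal)
    L <- 2 * 500000
    expected <- L * 0.001
    tol <- 3 * sqrt(L * 0.001 * 0.999) + 5   # +5 forced exonic SNPs at most
    expect_lt(abs(n - expected), tol)
    # biallelic SNPs only
    all <- rbind(pair$vcfMaternal, pair$vcfPaternal)
    expect_true(all(nchar(all$ref) == 1L & nchar(all$alt) == 1L))
    expect_true(all(all$ref != all$alt))
})

test_that("SNP-less gene fraction is exact by construction", {
    cfg <- simConfig(nGenes = 100L, snplessGeneFraction = 0.2, rngSeed = 4L)
    ref <- generateReference(cfg)
    pair <- generateAccessionPair(ref$genome, ref$geneModels, cfg)
    expect_identical(length(pair$snplessGenes), 20L)
    mt <- extractTranscripts(pair$maternalGenome, ref$geneModels)
    pt <- extractTranscripts(pair$paternalGenome, ref$geneModels)
    tp <- buildTranscriptPairs(mt, pt)
    zero <- tp$pairs$gene_id[tp$pairs$n_snps_tx == 0L]
    expect_setequal(zero, pair$snplessGenes)
    expect_equal(tp$summary$snp_bearing_pct, 80)
})

test_that("read simulation respects the mixing proportion and is error-faithful", {
    d <- makeDataset(tinyConfig(maternalFraction = 0.5, nReads = 10000L,
                                sequencingErrorRate = 0))
    reads <- simulateReads(d$maternalTx, d$paternalTx, d$truth, d$cfg)
    share <- mean(reads$truthLog$accession == "maternal")
    expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 10000))
    expect_identical(nrow(reads$truthLog), 10000L)
    expect_identical(length(reads$mate1), 10000L)
    expect_identical(length(reads$mate2), 10000L)

    # with zero sequencing error every mate substring-matches its source
    txs <- list(maternal = as.character(d$maternalTx),
                paternal = as.character(d$paternalTx))
    idx <- sample(nrow(reads$truthLog), 200L)
    for (i in idx) {
        src <- txs[[reads$truthLog$accession[i]]][[reads$truthLog$gene_id[i]]]
        fid <- reads$truthLog$fragment_id[i]
        expect_true(grepl(reads$mate1[[fid]], src, fixed = TRUE))
        expect_true(grepl(revcompChr(reads$mate2[[fid]]), src, fixed = TRUE))
    }
})

test_that("truth-log maternal share concentrates at the configured fraction", {
    d <- makeDataset(simConfig(nChromosomes = 1L, chromosomeLength = 80000L,
                               nGenes = 12L, nReads = 100000L,
                               maternalFraction = 0.69, rngSeed = 8L))
    reads <- simulateReads(d$maternalTx, d$paternalTx, d$truth, d$cfg)
    expect_lt(abs(mean(reads$truthLog$accession == "maternal") - 0.69), 0.015)
})

test_that("expressed transcripts shorter than the fragment length are skipped", {
    d <- makeDataset(tinyConfig())
    shortTx <- d$maternalTx
    # truncate one expressed gene below the nominal fragment length
    expressed <- d$truth$genes$gene_id[d$truth$genes$levelStigma > 0]
    g <- expressed[1]
    shortTx[[g]] <- shortTx[[g]][1:100]
    expect_warning(
        reads <- simulateReads(shortTx, d$paternalTx, d$truth, d$cfg),
        "shorter than"
    )
    expect_true(g %in% reads$skippedGenes)
    expect_false(g %in% reads$truthLog$gene_id[reads$truthLog$accession == "maternal"])
})

test_that("FASTQ round trip preserves reads and naming convention", {
    d <- makeDataset(tinyConfig(nReads = 200L))
    reads <- simulateReads(d$maternalTx, d$paternalTx, d$truth, d$cfg)
    pre <- tempfile()
    writeFastqPair(reads, pre)
    l1 <- readLines(paste0(pre, "_1.fastq"))
    expect_identical(length(l1), 800L)
    expect_match(l1[1], "/1$")
    back <- readFastqPair(pre)
    expect_identical(back$mate1, reads$mate1)
    expect_identical(back$mate2, reads$mate2)
})

test_that("mutual-rank neighbors reflect tissue labels, degraded by corruption", {
    set.seed(1)
    n <- 500L
    labels <- sample(c("stigma", "pollen", "shared"), n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.4))
    snpless <- runif(n) < 0.2
    truth <- fakeTruth(n, labels, snpless)
    cfg <- tinyConfig()

    clean <- generateMutualRankTable(truth, cfg, nNeighbors = 60L,
                                     corruption = 0)
    g <- truth$genes
    targets <- g$gene_id[g$label == "stigma"][1:20]
    for (tg in targets) {
        nb <- clean$neighbor[clean$target == tg][1:50]
        expect_true(all(g$label[match(nb, g$gene_id)] == "stigma"))
        expect_false(any(g$snpless[match(nb, g$gene_id)]))
        expect_false(tg %in% nb)
    }

    corrupt <- generateMutualRankTable(truth, cfg, nNeighbors = 60L,
                                       corruption = 1)
    top <- corrupt[corrupt$rank <= 50, ]
    tab <- table(g$label[match(top$target, g$gene_id)],
                 g$label[match(top$neighbor, g$gene_id)])
    # neighbor labels independent of target label at full corruption
    expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)

    # asymmetry is legal: neighbor lists need not be mutual
    a <- clean[clean$target == targets[1], "neighbor"][1]
    expect_true(is.character(a))
})
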