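# Variant filtering, consensus substitution, annotation transfer, transcript
# extraction and pairing, with brute-force string oracles on toy genomes.

vrec <- function(pos, ref, alt, depth = 10L, gt = "1/1", chrom = "chr1") {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, depth = depth,
               genotype = gt, is_snp = nchar(ref) == 1L & nchar(alt) == 1L,
               stringsAsFactors = FALSE)
}

test_that("variant filtering applies depth, zygosity and SNP-only rules", {
    recs <- rbind(vrec(5L, "A", "G", depth = 3L),
                  vrec(9L, "AT", "A", depth = 5L),           # 2-bp deletion
                  vrec(12L, "C", "T", depth = 2L),
                  vrec(20L, "G", "A", depth = 8L, gt = "0/1"),
                  vrec(33L, "T", "C", depth = 8L, gt = "1|1"))
    out <- filterVariants(recs, minDepth = 3L)
    expect_identical(out$pos, c(5L, 33L))
    # depth threshold inclusive at the boundary
    expect_true(5L %in% filterVariants(recs, minDepth = 3L)$pos)
    expect_false(5L %in% filterVariants(recs, minDepth = 6L)$pos)
    # indel removed under snpsOnly even at good depth
    expect_false(9L %in% filterVariants(recs, minDepth = 3L, snpsOnly = TRUE)$pos)
    expect_true(9L %in% filterVariants(recs, minDepth = 3L, snpsOnly = FALSE)$pos)
    # heterozygous call removed unless zygosity relaxed
    expect_true(20L %in% filterVariants(recs, minDepth = 3L,
                                        requireHomozygous = FALSE)$pos)
    # identity on empty input
    empty <- recs[0, ]
    expect_identical(nrow(filterVariants(empty, 3L)), 0L)
    # malformed genotype dropped with a warning, not an error
    badgt <- rbind(recs[1, ], vrec(40L, "A", "C", gt = "x?"))
    expect_warning(out2 <- filterVariants(badgt, 3L), "malformed")
    expect_identical(out2$pos, 5L)
})

test_that("SNP substitution edits exactly the called positions", {
    g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
    out <- applySnps(g, vrec(2L, "C", "T"))
    expect_identical(as.character(out)[["chr1"]], "ATGT")
    # empty SNP set is the identity
    expect_identical(as.character(applySnps(g, vrec(1L, "A", "G")[0, ])),
                     as.character(g))
    # chromosome lengths unchanged
    expect_identical(Biostrings::width(out), Biostrings::width(g))
    # reference mismatch names the position
    expect_error(applySnps(g, vrec(2L, "G", "T")), "chr1:2")
    expect_error(applySnps(g, vrec(99L, "C", "T")), "outside")
})

test_that("pairwise divergence equals the symmetric difference of substitutions", {
    set.seed(7)
    for (rep in 1:5) {
        L <- 400L
        g <- Biostrings::DNAStringSet(setNames(randomDna(L), "chr1"))
        base <- strsplit(as.character(g)[[1]], "")[[1]]
        posM <- sort(sample(L, 12L)); posP <- sort(sample(L, 15L))
        altOf <- function(p) vapply(p, function(i)
            sample(setdiff(c("A", "C", "G", "T"), base[i]), 1L), character(1))
        set.seed(rep); altM <- altOf(posM)
        set.seed(rep + 100); altP <- altOf(posP)
        vm <- vrec(posM, base[posM], altM)
        vp <- vrec(posP, base[posP], altP)
        gm <- applySnps(g, vm); gp <- applySnps(g, vp)
        # oracle: positions where the two consensus sequences differ
        a <- strsplit(as.character(gm)[[1]], "")[[1]]
        b <- strsplit(as.character(gp)[[1]], "")[[1]]
        observed <- sum(a != b)
        # effective substitutions that differ between the two sets
        eff <- union(posM, posP)
        same <- intersect(posM, posP)
        sameAlt <- same[altM[match(same, posM)] == altP[match(same, posP)]]
        expect_identical(observed, length(eff) - length(sameAlt))
    }
})

test_that("substitution followed by the reverse substitution restores the genome", {
    set.seed(3)
    g <- Biostrings::DNAStringSet(setNames(randomDna(300L), "chr1"))
    base <- strsplit(as.character(g)[[1]], "")[[1]]
    pos <- sort(sample(300L, 20L))
    alt <- vapply(pos, function(i)
        sample(setdiff(c("A", "C", "G", "T"), base[i]), 1L), character(1))
    fwd <- vrec(pos, base[pos], alt)
    sub <- applySnps(g, fwd)
    back <- applySnps(sub, vrec(pos, alt, base[pos]))
    expect_identical(as.character(back), as.character(g))
})

test_that("annotation transfer reports identity and flags divergent genes", {
    set.seed(5)
    L <- 1200L
    g <- Biostrings::DNAStringSet(setNames(randomDna(L), "chr1"))
    gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 1100L),
                                 strand = "+", gene_id = "gX", exon_rank = 1L)
    # no SNPs inside: identity 100%, not flagged
    t0 <- transferAnnotation(gm, g, g)
    expect_equal(t0$report$identity, 1)
    expect_false(t0$report$flagged)
    # 10 SNPs in a 1 kb transcript: identity 99.0%
    base <- strsplit(as.character(g)[[1]], "")[[1]]
    pos10 <- sort(sample(101:1100, 10L))
    alt10 <- vapply(pos10, function(i)
        sample(setdiff(c("A", "C", "G", "T"), base[i]), 1L), character(1))
    t10 <- transferAnnotation(gm, applySnps(g, vrec(pos10, base[pos10], alt10)), g)
    expect_equal(t10$report$identity, 0.99)
    expect_false(t10$report$flagged)
    # identity below the 95% criterion is flagged
    pos60 <- sort(sample(101:1100, 60L))
    alt60 <- vapply(pos60, function(i)
        sample(setdiff(c("A", "C", "G", "T"), base[i]), 1L), character(1))
    t60 <- transferAnnotation(gm, applySnps(g, vrec(pos60, base[pos60], alt60)), g)
    expect_equal(t60$report$identity, 0.94)
    expect_true(t60$report$flagged)
    # coordinates are never shifted
    expect_identical(as.data.frame(t60$geneModels), as.data.frame(gm))
})

test_that("transcript extraction splices exons and honors strand", {
    g <- Biostrings::DNAStringSet(c(chr1 = "ACGTTGCA"))
    gmPlus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1L, 5L), c(3L, 7L)),
                                     strand = "+",
                                     gene_id = "gA", exon_rank = 1:2)
    expect_identical(as.character(extractTranscripts(g, gmPlus))[["gA"]],
                     "ACGTGC")
    # reverse-complement palindrome maps to itself
    g2 <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
    gmMinus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 4L),
                                      strand = "-", gene_id = "gB",
                                      exon_rank = 1L)
    expect_identical(as.character(extractTranscripts(g2, gmMinus))[["gB"]],
                     "ACGT")
    # minus-strand non-palindrome
    g3 <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTT"))
    gm3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 4L),
                                  strand = "-", gene_id = "gC", exon_rank = 1L)
    expect_identical(as.character(extractTranscripts(g3, gm3))[["gC"]],
                     "GGTT")
    expect_error(extractTranscripts(g2, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(2L, 9L), strand = "+", gene_id = "gD",
        exon_rank = 1L)), "bounds")
})

test_that("substitution and extraction commute through the exon map", {
    set.seed(11)
    for (rep in 1:4) {
        cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 30000L,
                         nGenes = 5L, rngSeed = rep)
        ref <- generateReference(cfg)
        base <- strsplit(as.character(ref$genome)[[1]], "")[[1]]
        pos <- sort(sample(length(base), 80L))
        alt <- vapply(pos, function(i)
            sample(setdiff(c("A", "C", "G", "T"), base[i]), 1L), character(1))
        snps <- vrec(pos, base[pos], alt)
        txSub <- extractTranscripts(applySnps(ref$genome, snps), ref$geneModels)
        txRef <- extractTranscripts(ref$genome, ref$geneModels)
        # oracle: project each genomic SNP through the exon map by hand
        gm <- ref$geneModels
        for (gid in names(txRef)) {
            ex <- gm[GenomicRanges::mcols(gm)$gene_id == gid]
            ex <- ex[order(GenomicRanges::start(ex))]
            s <- strsplit(as.character(txRef)[[gid]], "")[[1]]
            offs <- cumsum(c(0L, GenomicRanges::width(ex)))
            for (k in seq_along(pos)) {
                hit <- which(pos[k] >= GenomicRanges::start(ex) &
                             pos[k] <= GenomicRanges::end(ex))
                if (!length(hit)) next
                txPos <- offs[hit] + (pos[k] - GenomicRanges::start(ex)[hit]) + 1L
                if (as.character(GenomicRanges::strand(ex))[1] == "-") {
                    txPos <- length(s) - txPos + 1L
                    s[txPos] <- chartr("ACGT", "TGCA", alt[k])
                } else {
                    s[txPos] <- alt[k]
                }
            }
            expect_identical(paste(s, collapse = ""),
                             as.character(txSub)[[gid]])
        }
    }
})

test_that("transcript pairing locates SNPs and summarizes the bearing fraction", {
    # identical sets: nothing SNP-bearing
    tx <- Biostrings::DNAStringSet(c(g1 = "ACGTACGT", g2 = "GGGCCC"))
    same <- buildTranscriptPairs(tx, tx)
    expect_identical(same$summary$n_snp_bearing, 0L)
    expect_equal(same$summary$snp_bearing_pct, 0)
    # positions found by comparison match the planted differences (0-based)
    tx2 <- Biostrings::DNAStringSet(c(g1 = "AGGTACGA", g2 = "GGGCCC"))
    tp <- buildTranscriptPairs(tx, tx2)
    expect_identical(tp$pairs$n_snps_tx[tp$pairs$gene_id == "g1"], 2L)
    expect_identical(tp$pairs$snp_positions[tp$pairs$gene_id == "g1"], "1,7")
    # unpaired genes excluded and reported
    tx3 <- Biostrings::DNAStringSet(c(g1 = "ACGTACGT", g3 = "TTTT"))
    expect_message(tp3 <- buildTranscriptPairs(tx, tx3), "only one")
    expect_setequal(tp3$dropped, c("g2", "g3"))
    expect_identical(tp3$pairs$gene_id, "g1")
    # length-divergent pairs are a hard error
    tx4 <- Biostrings::DNAStringSet(c(g1 = "ACGTACG", g2 = "GGGCCC"))
    expect_error(buildTranscriptPairs(tx, tx4), "length")
})

test_that("pairing agrees with the exon-projection of genomic SNPs", {
    d <- makeDataset(tinyConfig(rngSeed = 13L))
    tp <- buildTranscriptPairs(d$maternalTx, d$paternalTx)
    # oracle: project every genomic variant through the exon map; the
    # generator places maternal and paternal SNPs at distinct positions, so
    # every exonic variant is a transcript-coordinate difference
    snps <- rbind(d$pair$vcfMaternal, d$pair$vcfPaternal)
    gm <- d$ref$geneModels
    for (i in seq_len(nrow(tp$pairs))) {
        gid <- tp$pairs$gene_id[i]
        ex <- gm[GenomicRanges::mcols(gm)$gene_id == gid]
        ex <- ex[order(GenomicRanges::start(ex))]
        cn <- as.character(GenomicRanges::seqnames(ex))[1]
        offs <- cumsum(c(0L, GenomicRanges::width(ex)))
        txLen <- sum(GenomicRanges::width(ex))
        projected <- integer()
        sc <- snps[snps$chrom == cn, , drop = FALSE]
        for (k in seq_len(nrow(sc))) {
            hit <- which(sc$pos[k] >= GenomicRanges::start(ex) &
                         sc$pos[k] <= GenomicRanges::end(ex))
            if (!length(hit)) next
            p <- offs[hit] + (sc$pos[k] - GenomicRanges::start(ex)[hit])  # 0-based
            if (as.character(GenomicRanges::strand(ex))[1] == "-")
                p <- txLen - 1L - p
            projected <- c(projected, p)
        }
        found <- if (nzchar(tp$pairs$snp_positions[i]))
            as.integer(strsplit(tp$pairs$snp_positions[i], ",")[[1]])
        else integer()
        expect_identical(sort(found), sort(projected))
    }
})

test_that("transcript SNPs split into UTR and CDS by the span map", {
    pairs <- data.frame(gene_id = c("g1", "g2"), tx_length = c(100L, 80L),
                        n_snps_tx = c(4L, 2L),
                        snp_positions = c("2,10,50,90", "5,70"),
                        stringsAsFactors = FALSE)
    cds <- data.frame(gene_id = "g1", cds_start = 10L, cds_end = 60L)
    out <- classifySnpRegions(pairs, cds, nGenomeSnps = 60L)
    expect_identical(out$n_snps_cds, c(2L, 0L))   # 10 and 50 in [10, 60)
    expect_identical(out$n_snps_utr, c(2L, 2L))
    expect_equal(attr(out, "genic_share"), 6 / 60)
})
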