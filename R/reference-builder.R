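## Variant-aware consensus construction: filtered SNPs are substituted into
## the reference to give per-accession genomes; annotations transfer by
## coordinate identity (SNP-only substitution cannot shift coordinates);
## spliced transcripts are extracted and paired per gene.

#' Filter called variants
#'
#' Retains variant records passing a minimum read depth, optionally requiring
#' a homozygous genotype and single-base (SNP) alleles. Multi-allelic records
#' must be split to biallelic rows beforehand (see [readVariantVcf()], which
#' does so). Records with an unparseable genotype are dropped with a warning
#' rather than failing the run.
#'
#' @param records variant record data.frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `depth`, `genotype`, `is_snp`.
#' @param minDepth minimum read depth; the emulated pipeline used 3 for the
#'   maternal and 6 for the paternal line.
#' @param requireHomozygous keep only homozygous (`1/1` or `1|1`) calls.
#' @param snpsOnly keep only single-base substitutions.
#' @return the filtered data.frame.
#' @examples
#' v <- data.frame(chrom = "chr1", pos = c(5, 9), ref = c("A", "AT"),
#'                 alt = c("G", "A"), depth = c(3, 8),
#'                 genotype = "1/1", is_snp = c(TRUE, FALSE))
#' filterVariants(v, minDepth = 3)
#' @export
filterVariants <- function(records, minDepth = 3L, requireHomozygous = TRUE,
                           snpsOnly = TRUE) {
    if (!nrow(records)) return(records)
    gt <- as.character(records$genotype)
    parseable <- grepl("^[0-9.]+([/|][0-9.]+)?$", gt)
    if (any(!parseable)) {
        warning(sum(!parseable), " record(s) with malformed genotype dropped")
        records <- records[parseable, , drop = FALSE]
        gt <- gt[parseable]
    }
    keep <- records$depth >= minDepth
    if (requireHomozygous) {
        al <- strsplit(gt, "[/|]")
        hom <- vapply(al, function(a) length(unique(a)) == 1L && a[1] != "0" &&
                                       a[1] != ".", logical(1))
        keep <- keep & hom
    }
    if (snpsOnly)
        keep <- keep & records$is_snp &
            nchar(records$ref) == 1L & nchar(records$alt) == 1L
    records[keep, , drop = FALSE]
}

#' Substitute SNP alleles into a genome
#'
#' Produces the accession consensus by replacing the reference base with the
#' alternate allele at every SNP. Only single-base substitutions are applied,
#' so chromosome lengths are preserved and downstream annotation coordinates
#' remain valid. A reference-allele mismatch is a hard error naming the
#' offending position, since it signals a wrong reference build.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param snps variant record data.frame (SNP rows only; others rejected).
#' @return the substituted [Biostrings::DNAStringSet].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' snp <- data.frame(chrom = "chr1", pos = 2L, ref = "C", alt = "T")
#' as.character(applySnps(g, snp))
#' @export
applySnps <- function(genome, snps) {
    if (is.null(snps) || !nrow(snps)) return(genome)
    if (any(nchar(snps$ref) != 1L | nchar(snps$alt) != 1L))
        stop("applySnps only accepts single-base substitutions")
    out <- genome
    for (cn in unique(snps$chrom)) {
        if (!cn %in% names(out))
            stop("SNP on unknown chromosome ", cn)
        s <- snps[snps$chrom == cn, , drop = FALSE]
        if (any(s$pos < 1L | s$pos > length(out[[cn]])))
            stop("SNP position outside chromosome ", cn)
        have <- as.character(Biostrings::extractAt(out[[cn]],
                                                   IRanges(s$pos, s$pos)))
        bad <- which(have != toupper(s$ref))
        if (length(bad))
            stop("reference allele mismatch at ", cn, ":", s$pos[bad[1]],
                 " (expected ", s$ref[bad[1]], ", found ", have[bad[1]],
                 "); wrong reference build?")
        out[[cn]] <- Biostrings::replaceLetterAt(
            out[[cn]], s$pos, paste(toupper(s$alt), collapse = ""))
    }
    out
}

#' Transfer annotations onto a substituted genome
#'
#' With SNP-only substitution coordinates cannot shift, so the transfer is
#' the identity on coordinates; what remains informative is the per-gene
#' sequence identity between the source-model transcript and its counterpart
#' on the accession genome. Genes below `identityThreshold` are flagged (the
#' emulated transfer accepted genes at >= 95% similarity).
#'
#' @param geneModels exon [GenomicRanges::GRanges] with `gene_id`.
#' @param genome the substituted accession genome.
#' @param sourceGenome the original reference genome.
#' @param identityThreshold fraction below which a gene is flagged.
#' @return list with `geneModels` (unchanged coordinates) and `report`
#'   (data.frame: gene_id, tx_length, n_mismatch, identity, flagged).
#' @export
transferAnnotation <- function(geneModels, genome, sourceGenome,
                               identityThreshold = 0.95) {
    txNew <- extractTranscripts(genome, geneModels)
    txOld <- extractTranscripts(sourceGenome, geneModels)
    stopifnot(identical(names(txNew), names(txOld)))
    nm <- mapply(function(a, b) .countDiff(a, b),
                 as.character(txOld), as.character(txNew))
    len <- nchar(as.character(txOld))
    identity <- 1 - nm / len
    report <- data.frame(gene_id = names(txOld), tx_length = len,
                         n_mismatch = as.integer(nm), identity = identity,
                         flagged = identity < identityThreshold,
                         stringsAsFactors = FALSE, row.names = NULL)
    list(geneModels = geneModels, report = report)
}

.countDiff <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Extract spliced transcript sequences
#'
#' Concatenates each gene's exons in genomic order and reverse-complements
#' minus-strand genes, giving one mRNA per gene model.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param geneModels exon [GenomicRanges::GRanges] with `gene_id`; exons of a
#'   gene must lie on one chromosome and strand, within bounds.
#' @return named [Biostrings::DNAStringSet], one transcript per gene.
#' @export
extractTranscripts <- function(genome, geneModels) {
    ord <- order(mcols(geneModels)$gene_id, start(geneModels))
    gm <- geneModels[ord]
    ids <- unique(mcols(gm)$gene_id)
    seqs <- vapply(ids, function(g) {
        ex <- gm[mcols(gm)$gene_id == g]
        cn <- as.character(seqnames(ex))[1]
        if (!cn %in% names(genome)) stop("gene ", g, " on unknown chromosome ", cn)
        if (any(start(ex) < 1L) || any(end(ex) > length(genome[[cn]])))
            stop("exon of gene ", g, " outside chromosome bounds")
        pieces <- as.character(Biostrings::extractAt(
            genome[[cn]], IRanges(start(ex), end(ex))))
        s <- paste(pieces, collapse = "")
        if (as.character(strand(ex))[1] == "-")
            s <- as.character(reverseComplement(Biostrings::DNAString(s)))
        s
    }, character(1))
    DNAStringSet(setNames(seqs, ids))
}

#' Pair maternal and paternal transcripts and count their SNPs
#'
#' Pairs transcripts by gene id across the two accession transcriptomes,
#' locates every mismatch position (0-based, transcript coordinates) by
#' direct sequence comparison, and summarizes the fraction of gene models
#' distinguishable by at least one SNP.
#'
#' @param maternalTx,paternalTx named [Biostrings::DNAStringSet]. Genes
#'   present in only one set are excluded and reported.
#' @return list with `pairs` (data.frame: gene_id, tx_length, n_snps_tx,
#'   snp_positions as comma string), `summary` (n_genes, n_snp_bearing,
#'   snp_bearing_fraction, snp_bearing_pct) and `dropped` (gene ids present
#'   in only one set).
#' @export
buildTranscriptPairs <- function(maternalTx, paternalTx) {
    shared <- intersect(names(maternalTx), names(paternalTx))
    dropped <- setdiff(union(names(maternalTx), names(paternalTx)), shared)
    if (length(dropped))
        message(length(dropped), " gene(s) present in only one transcript set excluded")
    mt <- as.character(maternalTx[shared])
    pt <- as.character(paternalTx[shared])
    if (any(nchar(mt) != nchar(pt)))
        stop("transcript length differs within a pair; SNP-only substitution violated")
    pairs <- data.frame(gene_id = shared, tx_length = nchar(mt),
                        n_snps_tx = 0L, snp_positions = "",
                        stringsAsFactors = FALSE, row.names = NULL)
    for (i in seq_along(shared)) {
        a <- strsplit(mt[i], "")[[1]]
        b <- strsplit(pt[i], "")[[1]]
        d <- which(a != b) - 1L      # 0-based transcript coordinates
        pairs$n_snps_tx[i] <- length(d)
        pairs$snp_positions[i] <- paste(d, collapse = ",")
    }
    list(pairs = pairs, summary = snpBearingSummary(pairs), dropped = dropped)
}

#' Summarize SNP-bearing gene fraction
#'
#' @param pairs the `pairs` data.frame of [buildTranscriptPairs()] (or any
#'   data.frame with an `n_snps_tx` column).
#' @return list with `n_genes`, `n_snp_bearing`, `snp_bearing_fraction` and
#'   `snp_bearing_pct` (percentage rounded to one decimal, the headline
#'   "fraction of gene models distinguishable by SNPs").
#' @export
snpBearingSummary <- function(pairs) {
    n <- nrow(pairs)
    k <- sum(pairs$n_snps_tx >= 1L)
    list(n_genes = n, n_snp_bearing = k,
         snp_bearing_fraction = if (n) k / n else NA_real_,
         snp_bearing_pct = if (n) round(100 * k / n, 1) else NA_real_)
}

#' Classify transcript SNP positions by region
#'
#' Splits each gene's transcript-coordinate SNPs into UTR and CDS classes
#' given per-gene CDS spans in transcript coordinates. The emulated pipeline
#' reported the share of genome polymorphism falling in UTRs and CDSs; both
#' the within-transcript and whole-genome denominators are returned since
#' the printed figure is ambiguous about intronic sites.
#'
#' @param pairs the `pairs` data.frame of [buildTranscriptPairs()].
#' @param cdsSpans optional data.frame (gene_id, cds_start, cds_end; 0-based
#'   transcript coordinates, end exclusive). Missing genes count all
#'   transcript SNPs as UTR.
#' @param nGenomeSnps optional total SNP count between the accession genomes
#'   for the whole-genome denominator.
#' @return data.frame per gene (n_snps_tx, n_snps_cds, n_snps_utr) with
#'   attribute `genic_share` (transcript SNPs / genome SNPs) when
#'   `nGenomeSnps` is given.
#' @export
classifySnpRegions <- function(pairs, cdsSpans = NULL, nGenomeSnps = NULL) {
    out <- data.frame(gene_id = pairs$gene_id, n_snps_tx = pairs$n_snps_tx,
                      n_snps_cds = 0L, n_snps_utr = pairs$n_snps_tx,
                      stringsAsFactors = FALSE)
    if (!is.null(cdsSpans)) {
        for (i in seq_len(nrow(out))) {
            j <- match(out$gene_id[i], cdsSpans$gene_id)
            if (is.na(j) || !nzchar(pairs$snp_positions[i])) next
            p <- as.integer(strsplit(pairs$snp_positions[i], ",")[[1]])
            inCds <- p >= cdsSpans$cds_start[j] & p < cdsSpans$cds_end[j]
            out$n_snps_cds[i] <- sum(inCds)
            out$n_snps_utr[i] <- sum(!inCds)
        }
    }
    if (!is.null(nGenomeSnps))
        attr(out, "genic_share") <- sum(out$n_snps_tx) / nGenomeSnps
    out
}
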