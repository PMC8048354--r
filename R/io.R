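## Boundary I/O: VCF 4.2, GFF3 and FASTA live in their native conventions;
## internally variants are plain data.frames and gene models are GRanges.

#' Write variant records as VCF 4.2
#'
#' Emits a minimal single-sample VCF with `GT` and `DP` fields, sorted by
#' chromosome and position.
#'
#' @param records variant record data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `genotype`).
#' @param path output file.
#' @param sampleName sample column name.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(records, path, sampleName = "sample") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleName, sep = "\t")), con)
    if (nrow(records)) {
        records <- records[order(records$chrom, records$pos), , drop = FALSE]
        writeLines(paste(records$chrom, records$pos, ".", records$ref,
                         records$alt, ".", "PASS", ".", "GT:DP",
                         paste0(records$genotype, ":", records$depth),
                         sep = "\t"), con)
    }
    invisible(path)
}

#' Read a VCF into variant records
#'
#' Parses a VCF via \pkg{vcfR}, splits multi-allelic rows into biallelic
#' records (each alternate allele becomes its own record, as the pipeline
#' treats SNPs as single substitutions) and extracts per-sample depth and
#' genotype.
#'
#' @param path VCF file.
#' @param sample sample column index.
#' @return variant record data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `genotype`, `is_snp`.
#' @export
readVariantVcf <- function(path, sample = 1L) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (!nrow(fix))
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          depth = integer(), genotype = character(),
                          is_snp = logical()))
    gt <- tryCatch(vcfR::extract.gt(v, element = "GT")[, sample],
                   error = function(e) rep(NA_character_, nrow(fix)))
    dp <- tryCatch(suppressWarnings(
        as.integer(vcfR::extract.gt(v, element = "DP")[, sample])),
        error = function(e) rep(NA_integer_, nrow(fix)))
    out <- vector("list", nrow(fix))
    for (i in seq_len(nrow(fix))) {
        alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
        out[[i]] <- data.frame(
            chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
            ref = fix$REF[i], alt = alts,
            depth = if (is.na(dp[i])) 0L else dp[i],
            genotype = if (is.na(gt[i])) "." else gt[i],
            stringsAsFactors = FALSE, row.names = NULL)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res$is_snp <- nchar(res$ref) == 1L & nchar(res$alt) == 1L
    res
}

#' Write gene models as GFF3
#'
#' @param geneModels exon [GenomicRanges::GRanges] with `gene_id`,
#'   `exon_rank`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGff3 <- function(geneModels, path) {
    gm <- geneModels
    mcols(gm)$type <- "exon"
    mcols(gm)$ID <- paste0(mcols(gm)$gene_id, ".exon", mcols(gm)$exon_rank)
    mcols(gm)$Parent <- mcols(gm)$gene_id
    rtracklayer::export(gm, path, format = "gff3")
    invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file written by [writeGeneModelsGff3()] (or any GFF3
#'   whose exon features carry a `gene_id` or `Parent` attribute).
#' @return exon [GenomicRanges::GRanges] with `gene_id` and `exon_rank`.
#' @export
readGeneModelsGff3 <- function(path) {
    g <- rtracklayer::import(path, format = "gff3")
    g <- g[mcols(g)$type == "exon"]
    gid <- mcols(g)$gene_id
    if (is.null(gid)) gid <- as.character(mcols(g)$Parent)
    ord <- order(gid, start(g))
    g <- g[ord]
    gid <- gid[ord]
    rank <- unlist(lapply(split(seq_along(g), gid), seq_along), use.names = FALSE)
    out <- GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g))
    mcols(out)$gene_id <- gid
    mcols(out)$exon_rank <- rank
    out
}

## TSV with provenance header lines (# key: value), read back transparently
.writeTsv <- function(df, path, provenance = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(provenance))
        writeLines(paste0("# ", k, ": ", provenance[[k]]), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.readTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
}
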