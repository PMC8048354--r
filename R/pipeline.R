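## End-to-end orchestration on synthetic data: generation -> reference
## building -> per-sample EM quantification -> nFPKM -> classification ->
## differential testing -> Venn algebra -> selective induction -> ECM.
## Every output TSV carries provenance headers (version, seed, parameters).

.pkgVersion <- function() as.character(utils::packageVersion("duetSeq"))

#' Run the full synthetic pipeline
#'
#' Generates a two-accession dataset under `config`, rebuilds the diploid
#' references through the variant-filtering path, quantifies every
#' condition x replicate sample with the EM estimator, normalizes to nFPKM,
#' classifies baseline specificity, tests each condition against baseline
#' per tissue, partitions upregulated sets, ranks selectively induced genes
#' and predicts SNP-less gene specificity by ECM.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory for TSV artifacts; `NULL` skips writing.
#' @param nReplicates samples per condition.
#' @param corruption mutual-rank table corruption rate for the ECM stage.
#' @param minDepthMaternal,minDepthPaternal variant depth filters.
#' @return a list report: `proportions` (per condition), `snpSummary`,
#'   `classes`, `venn` (per tissue), `induced` (per tissue), `ecm`,
#'   `expression` (SummarizedExperiment), `converged`, `stageCounts`,
#'   `truth`, and the per-contrast DE tables.
#' @export
runPipeline <- function(config = simConfig(), outdir = NULL,
                        nReplicates = 3L, corruption = 0,
                        minDepthMaternal = 3L, minDepthPaternal = 6L) {
    report <- list(seed = config@rngSeed, version = .pkgVersion())

    ref <- generateReference(config)
    pair <- generateAccessionPair(ref$genome, ref$geneModels, config)
    truth <- generateExpressionTruth(ref$geneModels, pair$snplessGenes, config)

    vcfM <- filterVariants(pair$vcfMaternal, minDepth = minDepthMaternal)
    vcfP <- filterVariants(pair$vcfPaternal, minDepth = minDepthPaternal)
    maternalGenome <- applySnps(ref$genome, vcfM)
    paternalGenome <- applySnps(ref$genome, vcfP)
    maternalTx <- extractTranscripts(maternalGenome, ref$geneModels)
    paternalTx <- extractTranscripts(paternalGenome, ref$geneModels)
    tp <- buildTranscriptPairs(maternalTx, paternalTx)
    merged <- mergeTranscriptomes(maternalTx, paternalTx)

    conds <- config@conditions
    geneIds <- sort(unique(mcols(ref$geneModels)$gene_id))
    nSamp <- length(conds) * nReplicates
    matCounts <- patCounts <- matFpkm <- patFpkm <-
        matrix(0, nrow = length(geneIds), ncol = nSamp,
               dimnames = list(geneIds, NULL))
    sampleCond <- character(nSamp)
    propSamples <- numeric(nSamp)
    convergedAll <- TRUE
    j <- 0L
    for (ci in seq_along(conds)) {
        for (r in seq_len(nReplicates)) {
            j <- j + 1L
            reads <- simulateReads(maternalTx, paternalTx, truth, config,
                                   condition = conds[ci],
                                   seed = config@rngSeed + 1000L + 20L * ci + r)
            compat <- buildCompatibility(reads$mate1, reads$mate2, merged)
            est <- estimateAbundance(compat,
                                     errorRate = max(config@sequencingErrorRate, 1e-3),
                                     fragmentLength = config@fragmentLengthMean)
            convergedAll <- convergedAll && est@converged
            gc <- geneAccessionCounts(est)
            matCounts[gc$gene_id, j] <- gc$maternal_count
            patCounts[gc$gene_id, j] <- gc$paternal_count
            matFpkm[gc$gene_id, j] <- gc$maternal_fpkm
            patFpkm[gc$gene_id, j] <- gc$paternal_fpkm
            propSamples[j] <- tissueProportions(est)[["maternal"]]
            sampleCond[j] <- conds[ci]
        }
    }
    colnames(matCounts) <- colnames(patCounts) <- colnames(matFpkm) <-
        colnames(patFpkm) <- paste0(sampleCond, "_r",
                                    rep(seq_len(nReplicates), length(conds)))

    propByCond <- tapply(propSamples, sampleCond, mean)[conds]
    condMeans <- function(m) vapply(conds, function(cc)
        rowMeans(m[, sampleCond == cc, drop = FALSE]), numeric(length(geneIds)))
    expr <- buildExpressionTable(
        counts = cbind(condMeans(matCounts), condMeans(patCounts)),
        fpkm = cbind(condMeans(matFpkm), condMeans(patFpkm)),
        condition = rep(conds, 2L),
        tissue = rep(c("stigma", "pollen"), each = length(conds)),
        proportion = c(propByCond, 1 - propByCond))
    rownames(expr) <- geneIds
    colnames(expr) <- paste0(rep(c("stigma_", "pollen_"), each = length(conds)),
                             rep(conds, 2L))

    nf0 <- conditionNfpkm(expr, "C0")
    calls <- classifyExpression(nf0$stigma, nf0$pollen)

    deTables <- list()
    upSets <- list(stigma = list(), pollen = list())
    tissueCounts <- list(stigma = matCounts, pollen = patCounts)
    for (tis in c("stigma", "pollen")) {
        cm <- tissueCounts[[tis]]
        for (cc in setdiff(conds, "C0")) {
            de <- nbWaldTest(cm[, sampleCond == "C0", drop = FALSE],
                             cm[, sampleCond == cc, drop = FALSE])
            deTables[[paste(tis, cc, "vs_C0", sep = "_")]] <- de
            upSets[[tis]][[cc]] <- upregulatedSet(de)
        }
    }

    nExpr <- sum(nf0$stigma > 1 | nf0$pollen > 1)
    venn <- list(); induced <- list()
    for (tis in c("stigma", "pollen")) {
        u <- upSets[[tis]]
        venn[[tis]] <- vennPartition(u$C10, u$C60, u$I10, u$I60,
                                     nExpressed = nExpr)
        cm <- tissueCounts[[tis]]
        deRatio <- nbWaldTest(cm[, sampleCond == "I60", drop = FALSE],
                              cm[, sampleCond == "C60", drop = FALSE])
        deTables[[paste0(tis, "_C60_vs_I60")]] <- deRatio
        induced[[tis]] <- selectInduced(venn[[tis]]$exclusiveCompatible, deRatio)
    }

    ranks <- generateMutualRankTable(truth, config, corruption = corruption)
    snpBearing <- tp$pairs$gene_id[tp$pairs$n_snps_tx > 0]
    labels <- setNames(rep("none", length(snpBearing)), snpBearing)
    sg <- specificGenes(calls, "stigma"); pg <- specificGenes(calls, "pollen")
    labels[names(labels) %in% sg] <- "stigma"
    labels[names(labels) %in% pg] <- "pollen"
    elig <- eligibleTargets(nf0$stigma, nf0$pollen)
    preds <- predictSpecificityAll(elig, ranks, labels)
    truthSpec <- setNames(ifelse(truth$genes$classStigma == "specific", "stigma",
                          ifelse(truth$genes$classPollen == "specific", "pollen",
                                 "none")), truth$genes$gene_id)
    ecmEval <- evaluateEcm(preds, truthSpec)

    report <- c(report, list(
        snpSummary = tp$summary,
        proportions = setNames(as.numeric(propByCond), conds),
        classes = calls, expression = expr, de = deTables,
        venn = venn, induced = induced,
        ecm = list(predictions = preds, evaluation = ecmEval),
        converged = convergedAll,
        truth = truth,
        stageCounts = list(
            nGenes = length(geneIds),
            nVariantsMaternal = nrow(vcfM), nVariantsPaternal = nrow(vcfP),
            nSnplessGenes = length(pair$snplessGenes),
            nSamples = nSamp, nFragmentsPerSample = config@nReads,
            nExpressed = nExpr)))

    if (!is.null(outdir)) .writePipelineOutputs(report, outdir, config,
                                                vcfM, vcfP, ref, maternalTx,
                                                paternalTx, tp)
    report
}

.writePipelineOutputs <- function(report, outdir, config, vcfM, vcfP, ref,
                                  maternalTx, paternalTx, tp) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(package = "duetSeq", version = report$version,
                 seed = report$seed,
                 parameters = paste0("nGenes=", config@nGenes,
                                     ";nReads=", config@nReads,
                                     ";maternalFraction=", config@maternalFraction))
    writeVariantVcf(vcfM, file.path(outdir, "maternal.vcf"), "maternal")
    writeVariantVcf(vcfP, file.path(outdir, "paternal.vcf"), "paternal")
    writeGeneModelsGff3(ref$geneModels, file.path(outdir, "gene_models.gff3"))
    writeXStringSet(maternalTx, file.path(outdir, "transcripts_maternal.fasta"))
    writeXStringSet(paternalTx, file.path(outdir, "transcripts_paternal.fasta"))
    .writeTsv(tp$pairs, file.path(outdir, "snp_pairs.tsv"), prov)
    .writeTsv(report$classes, file.path(outdir, "classes.tsv"), prov)
    .writeTsv(data.frame(condition = names(report$proportions),
                         maternal_proportion = as.numeric(report$proportions)),
              file.path(outdir, "proportions.tsv"), prov)
    nf <- as.data.frame(SummarizedExperiment::assays(report$expression)$nfpkm)
    nf <- cbind(gene_id = rownames(nf), nf)
    .writeTsv(nf, file.path(outdir, "nfpkm.tsv"), prov)
    for (nm in names(report$de))
        .writeTsv(report$de[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")),
                  prov)
    for (tis in names(report$venn)) {
        v <- report$venn[[tis]]
        .writeTsv(v$regions[, c("region", "count")],
                  file.path(outdir, paste0("venn_", tis, ".tsv")),
                  c(prov, list(union_size = length(v$union),
                               exclusive_compatible = length(v$exclusiveCompatible),
                               exclusive_incompatible = length(v$exclusiveIncompatible))))
        .writeTsv(report$induced[[tis]],
                  file.path(outdir, paste0("induced_", tis, ".tsv")), prov)
    }
    .writeTsv(report$ecm$predictions, file.path(outdir, "ecm.tsv"), prov)
    rep2 <- data.frame(
        key = c("seed", "version", "n_genes", "snp_bearing_pct",
                "maternal_proportion_C0", "converged"),
        value = c(report$seed, report$version,
                  report$stageCounts$nGenes, report$snpSummary$snp_bearing_pct,
                  round(report$proportions[["C0"]], 4), report$converged))
    .writeTsv(rep2, file.path(outdir, "report.tsv"), prov)
    invisible(outdir)
}

#' Validate a pipeline output directory
#'
#' Itemized checks on a [runPipeline()] output directory: required files
#' present, column schemas intact, Venn region counts summing to the union,
#' class labels drawn from the legal set and nested consistently, and
#' proportions within (0, 1).
#'
#' @param outdir directory written by [runPipeline()].
#' @return data.frame `check`, `pass`, `detail`; attribute `ok` is TRUE when
#'   every check passed.
#' @export
validateOutputs <- function(outdir) {
    checks <- list()
    addCheck <- function(name, pass, detail = "")
        checks[[length(checks) + 1L]] <<- data.frame(
            check = name, pass = pass, detail = detail,
            stringsAsFactors = FALSE)

    needed <- c("maternal.vcf", "paternal.vcf", "gene_models.gff3",
                "transcripts_maternal.fasta", "transcripts_paternal.fasta",
                "snp_pairs.tsv", "classes.tsv", "proportions.tsv",
                "nfpkm.tsv", "venn_stigma.tsv", "venn_pollen.tsv",
                "ecm.tsv", "report.tsv")
    for (f in needed)
        addCheck(paste0("file:", f), file.exists(file.path(outdir, f)))

    schema <- function(file, cols) {
        ok <- FALSE; detail <- "missing"
        p <- file.path(outdir, file)
        if (file.exists(p)) {
            d <- tryCatch(.readTsv(p), error = function(e) NULL)
            if (is.null(d)) detail <- "unreadable"
            else if (!all(cols %in% names(d)))
                detail <- paste("missing columns:",
                                paste(setdiff(cols, names(d)), collapse = ","))
            else { ok <- TRUE; detail <- "" }
        }
        addCheck(paste0("schema:", file), ok, detail)
        if (ok) .readTsv(p) else NULL
    }
    cls <- schema("classes.tsv", c("gene_id", "stigma_class", "pollen_class"))
    schema("snp_pairs.tsv", c("gene_id", "tx_length", "n_snps_tx"))
    prop <- schema("proportions.tsv", c("condition", "maternal_proportion"))
    schema("ecm.tsv", c("gene_id", "n_stigma", "n_pollen", "call"))

    if (!is.null(cls)) {
        legal <- c("none", "expressed", "preferential", "specific")
        addCheck("classes:legal-labels",
                 all(cls$stigma_class %in% legal) && all(cls$pollen_class %in% legal))
        addCheck("classes:not-doubly-specific",
                 !any(cls$stigma_class == "specific" & cls$pollen_class == "specific"))
    }
    if (!is.null(prop))
        addCheck("proportions:in-(0,1)",
                 all(prop$maternal_proportion > 0 & prop$maternal_proportion < 1))
    for (tis in c("stigma", "pollen")) {
        f <- paste0("venn_", tis, ".tsv")
        p <- file.path(outdir, f)
        if (file.exists(p)) {
            hdr <- readLines(p, n = 20L)
            uni <- suppressWarnings(as.integer(
                sub(".*union_size: ", "", grep("union_size", hdr, value = TRUE))))
            v <- .readTsv(p)
            addCheck(paste0("venn:", tis, ":partition"),
                     length(uni) == 1L && !is.na(uni) && sum(v$count) == uni,
                     paste0("sum=", sum(v$count), " union=",
                            paste(uni, collapse = ",")))
        }
    }
    res <- do.call(rbind, checks)
    rownames(res) <- NULL
    attr(res, "ok") <- all(res$pass)
    res
}
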