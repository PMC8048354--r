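#' Simulation configuration for synthetic two-accession data
#'
#' Holds every knob of the synthetic-data generator: genome layout, SNP
#' density between the two accessions, expression truth (tissue specificity,
#' pollination-responsive genes), sequencing layout and mixing proportion.
#' Defaults describe the emulated study design: a mixed stigma+pollen sample
#' in which 69% of fragments are maternal, 2x75 bp paired-end reads, five
#' time-point conditions (C0, C10, C60, I10, I60), ~0.5% SNP divergence and
#' 20% of genes carrying no transcript SNP.
#'
#' @slot nChromosomes,chromosomeLength genome layout (bases).
#' @slot nGenes number of gene models (one transcript each).
#' @slot exonsPerGene integer range (min, max) of exons per gene.
#' @slot snpRate per-base substitution rate between the two accessions.
#' @slot maternalSnpFraction fraction of inter-accession SNPs attributed to
#'   the maternal line relative to the common reference (the rest are
#'   paternal).
#' @slot snplessGeneFraction fraction of genes forced to carry zero SNPs in
#'   their spliced transcript.
#' @slot nReads number of read *fragments* (pairs) per sample.
#' @slot readLength,fragmentLengthMean,fragmentLengthSd read layout (bases).
#' @slot sequencingErrorRate per-base substitution error probability.
#' @slot maternalFraction proportion of fragments drawn from the maternal
#'   (stigma) accession, in (0, 1).
#' @slot conditions ordered condition labels.
#' @slot nResponseGenes pollination-responsive genes per tissue.
#' @slot responseFoldChange multiplicative induction factor at the flagged
#'   condition(s).
#' @slot stigmaSpecificFraction,pollenSpecificFraction fractions of genes
#'   expressed in only one tissue.
#' @slot snplessLevelScale relative expression level of SNP-less genes; the
#'   default makes the expected SNP-less read share about 15% when 20% of
#'   genes are SNP-less.
#' @slot levelMeanlog,levelSdlog log-normal parameters of per-gene,
#'   per-tissue expression levels.
#' @slot rngSeed integer seed; all generators are bit-reproducible under it.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nChromosomes = "integer", chromosomeLength = "integer",
    nGenes = "integer", exonsPerGene = "integer",
    snpRate = "numeric", maternalSnpFraction = "numeric",
    snplessGeneFraction = "numeric",
    nReads = "integer", readLength = "integer",
    fragmentLengthMean = "numeric", fragmentLengthSd = "numeric",
    sequencingErrorRate = "numeric", maternalFraction = "numeric",
    conditions = "character", nResponseGenes = "integer",
    responseFoldChange = "numeric",
    stigmaSpecificFraction = "numeric", pollenSpecificFraction = "numeric",
    snplessLevelScale = "numeric",
    levelMeanlog = "numeric", levelSdlog = "numeric",
    rngSeed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    pos <- c(nChromosomes = object@nChromosomes,
             chromosomeLength = object@chromosomeLength,
             nGenes = object@nGenes, nReads = object@nReads,
             readLength = object@readLength)
    bad <- names(pos)[pos < 1L]
    if (length(bad))
        msg <- c(msg, paste0("counts must be positive: ", paste(bad, collapse = ", ")))
    if (object@maternalFraction <= 0 || object@maternalFraction >= 1)
        msg <- c(msg, "maternalFraction must lie in (0, 1)")
    if (object@snpRate <= 0 || object@snpRate > 0.05)
        msg <- c(msg, "snpRate must lie in (0, 0.05]")
    if (object@readLength >= object@chromosomeLength)
        msg <- c(msg, "readLength must be smaller than chromosomeLength")
    if (length(object@exonsPerGene) != 2L || any(object@exonsPerGene < 1L) ||
        object@exonsPerGene[1] > object@exonsPerGene[2])
        msg <- c(msg, "exonsPerGene must be an increasing positive pair")
    if (object@snplessGeneFraction < 0 || object@snplessGeneFraction >= 1)
        msg <- c(msg, "snplessGeneFraction must lie in [0, 1)")
    if (object@sequencingErrorRate < 0 || object@sequencingErrorRate >= 1)
        msg <- c(msg, "sequencingErrorRate must lie in [0, 1)")
    if (object@stigmaSpecificFraction + object@pollenSpecificFraction >= 1)
        msg <- c(msg, "specific fractions must sum to less than 1")
    if (object@snplessLevelScale <= 0)
        msg <- c(msg, "snplessLevelScale must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param nChromosomes,chromosomeLength,nGenes,exonsPerGene genome layout.
#' @param snpRate,maternalSnpFraction,snplessGeneFraction SNP structure.
#' @param nReads,readLength,fragmentLengthMean,fragmentLengthSd,sequencingErrorRate
#'   sequencing layout.
#' @param maternalFraction maternal (stigma) fragment proportion.
#' @param conditions ordered condition labels.
#' @param nResponseGenes,responseFoldChange pollination response design.
#' @param stigmaSpecificFraction,pollenSpecificFraction,snplessLevelScale,levelMeanlog,levelSdlog
#'   expression truth design.
#' @param rngSeed integer seed.
#' @return A validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(nGenes = 20L, nReads = 2000L, rngSeed = 7L)
#' cfg
#' @export
simConfig <- function(nChromosomes = 2L, chromosomeLength = 400000L,
                      nGenes = 100L, exonsPerGene = c(1L, 4L),
                      snpRate = 0.005, maternalSnpFraction = 0.003,
                      snplessGeneFraction = 0.2,
                      nReads = 50000L, readLength = 75L,
                      fragmentLengthMean = 250, fragmentLengthSd = 30,
                      sequencingErrorRate = 0.005, maternalFraction = 0.69,
                      conditions = c("C0", "C10", "C60", "I10", "I60"),
                      nResponseGenes = 10L, responseFoldChange = 4,
                      stigmaSpecificFraction = 0.3,
                      pollenSpecificFraction = 0.3,
                      snplessLevelScale = 0.44,
                      levelMeanlog = 2, levelSdlog = 1.5,
                      rngSeed = 1L) {
    new("SimConfig",
        nChromosomes = as.integer(nChromosomes),
        chromosomeLength = as.integer(chromosomeLength),
        nGenes = as.integer(nGenes), exonsPerGene = as.integer(exonsPerGene),
        snpRate = snpRate, maternalSnpFraction = maternalSnpFraction,
        snplessGeneFraction = snplessGeneFraction,
        nReads = as.integer(nReads), readLength = as.integer(readLength),
        fragmentLengthMean = fragmentLengthMean,
        fragmentLengthSd = fragmentLengthSd,
        sequencingErrorRate = sequencingErrorRate,
        maternalFraction = maternalFraction,
        conditions = conditions, nResponseGenes = as.integer(nResponseGenes),
        responseFoldChange = responseFoldChange,
        stigmaSpecificFraction = stigmaSpecificFraction,
        pollenSpecificFraction = pollenSpecificFraction,
        snplessLevelScale = snplessLevelScale,
        levelMeanlog = levelMeanlog, levelSdlog = levelSdlog,
        rngSeed = as.integer(rngSeed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes on", object@nChromosomes,
        "chromosome(s) of", object@chromosomeLength, "bp\n")
    cat("  SNP rate", object@snpRate, "| SNP-less gene fraction",
        object@snplessGeneFraction, "\n")
    cat("  ", object@nReads, " fragments of 2 x ", object@readLength,
        " bp | maternal fraction ", object@maternalFraction, "\n", sep = "")
    cat("  conditions:", paste(object@conditions, collapse = ", "),
        "| seed", object@rngSeed, "\n")
})

#' Fragment-by-transcript compatibility structure
#'
#' Sparse set of gapless end-to-end placements of read fragments on the
#' merged maternal+paternal transcript universe, with mismatch counts. This
#' is the sufficient statistic consumed by [estimateAbundance()].
#'
#' @slot entries data.frame with columns `fragment` (integer index), `tx`
#'   (integer index into `txNames`), `mismatch`, `offset1`, `offset2`
#'   (1-based; `offset2` NA in single-end mode), `alen` (aligned bases).
#' @slot txNames,txLengths the transcript universe.
#' @slot nFragments total fragments queried (assigned + unassigned).
#' @slot unassigned integer indices of fragments with no compatible
#'   transcript.
#' @slot maxMismatches the mismatch budget used.
#' @exportClass CompatMatrix
setClass("CompatMatrix", representation(
    entries = "data.frame", txNames = "character", txLengths = "integer",
    nFragments = "integer", unassigned = "integer", maxMismatches = "integer"))

setValidity("CompatMatrix", function(object) {
    e <- object@entries
    msg <- character()
    need <- c("fragment", "tx", "mismatch", "offset1", "offset2", "alen")
    if (!all(need %in% names(e)))
        msg <- c(msg, "entries must have fragment/tx/mismatch/offset1/offset2/alen")
    else if (nrow(e)) {
        if (any(e$mismatch > object@maxMismatches))
            msg <- c(msg, "mismatch exceeds maxMismatches")
        if (any(e$tx < 1L | e$tx > length(object@txNames)))
            msg <- c(msg, "tx index out of range")
        if (any(e$offset1 < 1L | e$offset1 > object@txLengths[e$tx]))
            msg <- c(msg, "offset places fragment outside the transcript")
    }
    if (length(object@txLengths) != length(object@txNames))
        msg <- c(msg, "txLengths/txNames length mismatch")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CompatMatrix", function(object) {
    cat("CompatMatrix:", object@nFragments, "fragments x",
        length(object@txNames), "transcripts;", nrow(object@entries),
        "compatible placements;", length(object@unassigned), "unassigned\n")
})

#' @rdname CompatMatrix-class
#' @param x a `CompatMatrix`.
#' @return `compatEntries()`: the sparse placement data.frame;
#'   `unassignedFragments()`: integer indices of unplaceable fragments.
#' @export
compatEntries <- function(x) x@entries

#' @rdname CompatMatrix-class
#' @export
unassignedFragments <- function(x) x@unassigned

#' Allele-specific abundance estimate
#'
#' Result of the EM/MAP estimator over the merged maternal+paternal
#' transcript universe: relative abundances on the simplex, expected fragment
#' counts (responsibility sums), effective lengths and FPKM, plus the
#' optimization trace.
#'
#' @slot theta named numeric, relative fragment abundance (sums to 1).
#' @slot expectedCounts named numeric, sums to the number of assigned
#'   fragments.
#' @slot effectiveLengths,fpkm per-transcript values.
#' @slot logPosteriorTrace per-iteration value of the maximized objective
#'   (data log-likelihood plus Dirichlet log-prior); non-decreasing.
#' @slot logLikelihood final data log-likelihood.
#' @slot iterations,converged EM bookkeeping.
#' @slot nFragments number of assigned fragments.
#' @exportClass AbundanceEstimate
setClass("AbundanceEstimate", representation(
    theta = "numeric", expectedCounts = "numeric",
    effectiveLengths = "numeric", fpkm = "numeric",
    logPosteriorTrace = "numeric", logLikelihood = "numeric",
    iterations = "integer", converged = "logical", nFragments = "integer"))

setValidity("AbundanceEstimate", function(object) {
    msg <- character()
    if (abs(sum(object@theta) - 1) > 1e-6)
        msg <- c(msg, "theta must sum to 1")
    if (abs(sum(object@expectedCounts) - object@nFragments) > 1e-6 * max(1, object@nFragments))
        msg <- c(msg, "expectedCounts must sum to the number of assigned fragments")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AbundanceEstimate", function(object) {
    cat("AbundanceEstimate:", length(object@theta), "transcripts,",
        object@nFragments, "assigned fragments\n")
    cat("  EM:", object@iterations, "iterations, converged =",
        object@converged, "\n")
})

#' @rdname AbundanceEstimate-class
#' @param x an `AbundanceEstimate`.
#' @return Accessors return the corresponding per-transcript vectors or
#'   scalars.
#' @export
abundanceTheta <- function(x) x@theta

#' @rdname AbundanceEstimate-class
#' @export
expectedCounts <- function(x) x@expectedCounts

#' @rdname AbundanceEstimate-class
#' @export
fpkmValues <- function(x) x@fpkm

#' @rdname AbundanceEstimate-class
#' @export
emConverged <- function(x) x@converged

#' @rdname AbundanceEstimate-class
#' @export
logPosteriorTrace <- function(x) x@logPosteriorTrace
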