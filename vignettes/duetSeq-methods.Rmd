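---
title: "duetSeq: methods and design notes"
author: "duetSeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duetSeq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duetSeq)
```

## The problem

When pollen lands on a stigma, any RNA-seq library made from the pollinated
tissue is a mixture of male (pollen) and female (stigma) transcripts.
duetSeq separates the two sides using the natural sequence variation between
two plant accessions, one used as the maternal and one as the paternal
parent. Every stage of the analysis — building variant-substituted
references, assigning mixed reads to parental transcripts, normalizing,
classifying sex-specific expression, selecting pollination-induced genes and
predicting specificity for genes without any distinguishing SNP — is
implemented here against synthetic data with recorded ground truth, so the
whole pipeline is testable without any external download.

## Diploid reference construction

Variant records are filtered on read depth (defaults 3 for the maternal, 6
for the paternal line), homozygosity and SNP-ness; indels are excluded by
design, so substituting the alternate allele at every SNP preserves all
coordinates. Because coordinates cannot shift, annotation "transfer" onto
the substituted genomes is the identity on coordinates; what remains
informative is the per-gene sequence identity between the source and
substituted transcript, reported per gene and flagged below a 95% identity
threshold. Spliced transcripts are then extracted per gene model
(minus-strand genes reverse-complemented) and paired across the accessions;
the per-transcript mismatch positions are the gene's transcript-coordinate
SNPs, and the headline summary is the fraction of gene models
distinguishable by at least one SNP.

Internal coordinates follow the host ecosystem's 1-based closed convention
(`IRanges`/`GRanges`); VCF and GFF3 are read and written in their native
conventions, with conversion confined to the I/O layer. Transcript-local
SNP positions are reported 0-based, matching the usual convention for
string offsets.

## Read assignment model

Fragments are placed on the merged maternal+paternal transcript set by a
gapless end-to-end matcher: since the two alleles of a gene differ only by
substitutions, gapped alignment adds nothing. Each mate is partitioned into
`maxMismatches + 1` contiguous pieces; by pigeonhole at least one piece of
any alignment within budget is exact, so seeding with the k-mer at each
piece start enumerates every reachable placement and the matcher is exactly
equivalent to a brute-force scan over all offsets (a property the test
suite asserts against an independent scan). Mate 2 is reverse-complemented
and must place downstream of mate 1 on the same transcript; mates are
scored jointly because the fragment, not the read, is the sampling unit.

Abundances come from an EM for the finite mixture in which a fragment from
transcript $t$ with $m$ mismatches over $L$ aligned bases has likelihood
$\theta_t \, e^m (1-e)^{L-m}$, with $e$ the assumed per-base error rate
(default 0.01). The M-step uses the posterior-mean update under a symmetric
Dirichlet prior with pseudocount $a$ (default 1, the uniform-prior Bayesian
mean), $\theta_t \propto N_t + a$, where $N_t$ is the responsibility sum.
Two consequences matter scientifically:

* a gene whose two alleles are identical (no transcript SNP) receives an
  exactly equal split of its fragments between the maternal and paternal
  copy — the behavior that lets the method use *all* reads rather than
  only SNP-covering ones;
* the optimized objective (data log-likelihood plus Dirichlet log-prior) is
  non-decreasing across iterations; the trace is stored and its relative
  change (default tolerance $10^{-8}$) drives convergence.

Expected counts are responsibility sums, and FPKM uses effective length
$\max(1,\ \mathrm{length} - \mathrm{fragmentLength} + 1)$, the standard
correction for the number of distinct fragment start positions. Tissue
proportions are expected-count sums per accession.

### Identifiability of the mixing proportion

The equal split of SNP-less fragments is forced by symmetry: no estimator
can recover the parental origin of a read that matches both alleles
equally. Consequently the tissue mixing proportion is identifiable only
from SNP-informative mass, and any sex-biased expression among SNP-less
genes biases the estimated proportion toward 1/2 — a property of the
method, not of this implementation. The package handles this the way the
underlying analysis does: specificity of SNP-less genes is delegated to the
co-expression predictor (below), the synthetic generator models SNP-less
genes as tissue-balanced so that recorded truth is recoverable, and the
parameter-recovery experiments run on fully SNP-informative gene sets where
the proportion is identifiable. Real SNP-less genes with strong sex bias
would shift the estimated proportions; that limitation is inherent and
should be kept in mind when interpreting the tissue shares.

## Normalization and classification

FPKM is count per kilobase of effective length per million assigned
fragments. nFPKM divides each tissue's FPKM by that tissue's estimated
fragment proportion at the condition, which puts stigma and pollen values
on a common scale (an FPKM of 69 at proportion 0.69 and an FPKM of 31 at
proportion 0.31 both become 100).

Classification applies nested criteria per tissue, with deliberate strict
and non-strict inequalities pinned by boundary tests:

* expressed: nFPKM $> 1$;
* preferential: expressed and own $\ge 10\times$ the other tissue;
* specific: preferential and other $\le 1$ and own $> 100$ and own
  $> 100\times$ the other tissue.

The nesting makes "specific" imply "preferential" imply "expressed", and no
gene can be specific in both tissues.

## Differential testing

Counts are normalized by median-of-ratios size factors (genes with a zero
anywhere excluded from the geometric-mean reference). The per-gene test is
a negative-binomial Wald test: group means on the common scale, pooled
method-of-moments dispersion $\hat\alpha = \max(0, (s^2 - \bar\mu) /
\bar\mu^2)$, delta-method variance $(1/\mu + \alpha)/n$ per group, and BH
adjustment. With 3–4 replicates the gene-wise moment estimator is extremely
noisy and truncates at zero for roughly half of null genes, which makes the
raw statistic badly anticonservative; each gene's dispersion is therefore
floored at the 0.75 ensemble quantile of the gene-wise estimates — a simple
moderation toward a common dispersion. In calibration simulations (40
datasets of 2,000 null genes, 4 vs 4 replicates, NB dispersion 0.125) this
choice kept the rate of datasets with any BH discovery at 0.025 against a
nominal 0.1, while detecting planted four-fold inductions in over 95% of
runs; the raw estimator rejected in every null dataset, and a $t_{n-2}$
reference destroyed power. The fold change is reported on the linear scale
with a 0.5 pseudocount applied only to zero means, so ratios stay finite;
which fold-change flavor a shrinkage-based tool would report is a
downstream presentation choice, and the raw ratio is the default here.

Gene-set selection follows the printed thresholds: upregulated means fold
change $> 2$ with adjusted $p < 0.1$ against the baseline; the four
condition sets (C10, C60, I10, I60) are partitioned into all 15 Venn
regions by per-gene membership signature; exclusive-compatible is
$(C10 \cup C60) \setminus (I10 \cup I60)$ and mirror for incompatible; and
selectively induced genes are the exclusive genes passing the
between-treatment contrast (C60 vs I60 fold change $> 2$, adjusted
$p < 0.1$), sorted by that fold change, top 10.

## Predicting specificity for SNP-less genes

Genes whose alleles are identical carry no parent-of-origin signal, but
their tissue can often be read off their co-expression neighborhood. For a
target gene with baseline nFPKM sum $\ge 350$ (only highly expressed genes
are predictable), the predictor takes the target's mutual-rank neighbor
list — an ordered list of such tables is tried in sequence, modelling a
primary compendium with a fallback — filters it to SNP-bearing genes,
truncates to the top 50, and counts stigma-specific and pollen-specific
labels among them. Strictly more than 35 stigma-specific neighbors calls
the target stigma-specific; strictly more than 25 pollen-specific
neighbors calls it pollen-specific. Since 36 + 26 = 62 > 50, no target can
ever receive both calls. Neighbor labels default to baseline-condition
specificity calls, the condition on which all specificity lists are built.
The selection sentence "the 50 most correlated genes having polymorphism"
is read literally (filter to SNP-bearing genes first, then truncate); a
flag provides the other order. Ties in mutual rank break lexicographically
by gene id for determinism.

## The synthetic-data generator

The generator emulates the study design end to end and records every truth
needed for recovery tests:

* **Genome and gene models.** Uniform-random chromosomes (default 2 ×
  400 kb) with 100 non-overlapping single-transcript genes, 1–4 exons of
  150–400 bp, random strand; transcripts are padded to at least
  `fragmentLengthMean + 4 sd` so every gene is sequenceable.
* **Accession pair.** Biallelic SNPs scattered at 0.005 per base (the
  approximate genome-wide divergence of the emulated accession pair), a
  small fraction (0.003) attributed to the maternal line; 20% of genes are
  forced SNP-less by masking their exons, and every other gene is forced to
  carry at least one exonic SNP, so the SNP-less set is exact by
  construction (and the SNP-bearing fraction is 80%, matching the
  emulated 79.8%).
* **Expression truth.** 30% stigma-specific and 30% pollen-specific genes
  (silent tissue set to 0, making the 10×/100× criteria recoverable
  exactly), the rest shared with independent log-normal levels
  (meanlog 2, sdlog 1.5 — levels spanning several orders of magnitude, as
  real FPKM distributions do). SNP-less genes are tissue-balanced (one
  level for both tissues) and scaled by 0.44, which puts the expected
  SNP-less read share near the emulated 15%; see the identifiability note
  above for why their balance is a modelling requirement, not a
  convenience. Pollination-responsive genes (10 per tissue) multiply their
  level by 4 under fixed condition profiles (C10+C60, C60 only, I10+I60,
  I60 only, all four) so compatible-exclusive responders exist by design.
* **Reads.** Fragments sample the accession first (Bernoulli at the 0.69
  maternal fraction — mixing decoupled from expression truth), then a
  transcript within the accession proportionally to its level, then a
  normal fragment length (250 ± 30, clipped) and a uniform position; 2 ×
  75 bp mates with per-base substitution errors at 0.005, mate 2
  reverse-complemented. The insert-size distribution is not constrained by
  the emulated protocol and is a free parameter here.
* **Mutual-rank table.** Each gene's neighbor list is drawn from
  SNP-bearing genes sharing its tissue label, with a corruption parameter
  replacing slots by uniform draws — corruption 0 forces perfect neighbor
  structure, corruption 1 makes neighbor labels independent of the target.

What the generator does **not** emulate: isoform diversity (one transcript
per gene), indels, base-quality-dependent errors, library GC/positional
biases, intron signal, and biological replicate variance beyond read
resampling. Tests passing on this generator therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every artefact of real libraries.

## Experiment sizes used by the automated checks

The shipped checks run at desk scale, chosen to make binomial/Monte-Carlo
tolerances meaningful while keeping the whole suite in the low tens of
seconds: worked-example arithmetic at the published counts (39,204 gene
models; 21,335 expressed genes; Venn region sizes), EM-vs-enumeration
equivalence on all instances up to 5 fragments × 3 transcripts, parameter
recovery from 10^5 fragments over 60 genes at maternal fractions 0.3, 0.69
and 0.9, classification fuzzing over 10^4 draws, co-expression prediction
over 300 genes, and differential-test calibration over 15 null datasets of
10^4 genes plus 100 seeded power simulations.

## Numerical and degenerate-input choices

* EM convergence on relative change of the penalized objective
  ($10^{-8}$); non-convergence at `maxIter` returns `converged = FALSE`
  with a warning rather than an error.
* Per-fragment likelihoods are max-scaled in log space before
  exponentiation, so long fragments cannot underflow.
* A fragment with no compatible transcript is reported as unassigned, never
  silently dropped from the denominator of FPKM (the denominator is
  assigned fragments).
* Matcher ties (same mismatch count at several offsets) resolve to the
  smallest offsets; mutual-rank ties resolve lexicographically.
* All-zero genes in the differential test get $p = 1$ and an undefined
  fold change, flagged.
* Reference-allele mismatches during substitution are hard errors naming
  the position, because they indicate a wrong reference build; malformed
  genotype fields are dropped with a warning, because single corrupt VCF
  rows should not kill a run.
* Generators derive their RNG streams from `rngSeed` plus a fixed per-stage
  offset, so each stage is independently reproducible and replicate samples
  take explicit per-sample seeds.

## Known limitations

Single-transcript gene models only; no gapped alignment (real indel
variation between accessions would require it); the mixing-proportion bias
from sex-biased SNP-less genes discussed above; the differential stand-in
does not implement shrinkage, independent filtering or outlier replacement,
so its fold changes and tail behavior will differ in detail from
shrinkage-based tools even though the downstream thresholds consume only
fold change and adjusted p.
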