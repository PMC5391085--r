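---
title: "Predictive long-range allele-specific mapping with allelink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive long-range allele-specific mapping with allelink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelink)
```

## The problem

Most GWAS tag SNPs are non-coding, and the variant actually driving a
trait usually sits in a regulatory element that contacts its target gene
over a long genomic range. Cross-individual QTL mapping can connect such
variants to histone-modification levels and expression, but it needs many
samples because it works between genotype groups. Within a single
heterozygous individual, however, the two alleles of a cis-regulatory
variant are read out side by side under an identical trans-acting
background: unequal ChIP-seq read counts over the two alleles (allelic
imbalance) and unequal RNA-seq counts over a transcript SNP
(allele-specific expression) are paired, within-sample evidence of
cis-regulation. `allelink` implements that allelic mapping strategy end
to end, together with the machine-learning extension that rescues pairs
that cannot be tested directly for lack of heterozygotes.

## The allelic imbalance model

At a heterozygous SNP with reference depth $k$ and total depth $n$, the
null of no cis effect is binomial, $k \sim \mathrm{Bin}(n, 0.5)$. A site
enters testing only when

* total allelic depth $n > 8$, and
* the reference ratio $k/n$ lies in $[0.15, 0.85]$ (inclusive),

which guards against genotyping errors and allele-specific mapping
artefacts at the cost of censoring the most extreme true imbalances.
The two-sided P value is the doubled smaller tail capped at 1,
$\min(1, 2\min(P(X \le k), P(X \ge k)))$; with the symmetric null this
equals the minimum-likelihood two-sided test and is checkable against
direct outcome enumeration, which the test suite does for all
$0 \le k \le n \le 30$. When the same sample, assay and SNP were
measured by several studies, depths are averaged component-wise across
studies and rounded half-up to integers first (the binomial test needs
integer counts; the rounding direction is a package choice).

Evidence across samples is combined with Fisher's method,
$\chi^2 = -2\sum_i \ln p_i$ on $2k$ degrees of freedom, and a site is
called imbalanced at combined $P < 0.05$. No multiple-testing correction
is applied by default, matching the published procedure; a
Benjamini-Hochberg option exists in `imbalanceConfig()`. We combine
per-sample P values regardless of the direction each sample leans,
and expose the mean oriented ratio so direction consistency can be
inspected; requiring directional concordance inside the meta-analysis
would be stricter than the procedure we implement.

## Phasing, flipping and direction matching

Reference and alternative alleles are defined on the reference genome,
so the ref-allele ratios of a distant regulatory/transcript SNP pair are
not comparable allele-wise unless the pair is phased. Following the
published rule, the transcript ratio is flipped ($r \mapsto 1-r$) in
samples where the two alternative alleles lie on different haplotypes.

A subtlety decided here: per-sample `hap1`/`hap2` labels are arbitrary,
so orienting each locus to "haplotype 1" would make cross-sample means
meaningless. Instead the regulatory SNP keeps its reference-allele
ratio and only the transcript ratio is flipped. After the flip, both
members of a pair measure the read fraction of the same physical
haplotype — the one carrying the regulatory *reference* allele — which
is a frame stable across samples and lets per-sample ratios be averaged
and compared. The truth-table test in the suite verifies this frame
against a brute-force haplotype evaluator over every het-het phase
configuration.

Direction matching then uses histone-mark polarity: H3K27ac, H3K4me1,
H3K4me3 and H3K36me3 are activating (major regulatory allele and major
transcript allele must lie on the same haplotype), H3K27me3 is
repressive (they must oppose). A mean ratio of exactly 0.5 has no major
allele; such pairs are excluded from direction matching and fall into
the control class.

### Pair testability

Pair labels partition candidates exhaustively:

* **true pair** — both loci imbalanced (Fisher $P < 0.05$) and direction
  matched;
* **control pair** — testable but failing either imbalance or direction;
* **untestable** — no usable heterozygote.

The locus-level tests need a heterozygous, filter-passing sample at each
SNP, but phase flipping is only defined in samples heterozygous at
*both* SNPs, so we additionally require at least one jointly
heterozygous filter-passing sample for a pair to count as testable.
This is slightly stricter than requiring each locus to be testable
separately, and is the only reading under which the orientation step is
always well defined.

## LD expansion

Candidate regulatory variants for a GWAS tag are the SNPs sharing its
haplotype block in all configured populations (intersection over
populations; a tag that is blockless anywhere degenerates to itself).
Four-gamete blocks are built greedily left to right: a SNP joins the
current block iff every pair it forms with current members shows at most
three of the four gametes. The scan order is not specified by the
classical rule; the greedy all-pairs version is the strictest
deterministic reading and is property-tested against a brute-force
checker. Confidence-interval (Gabriel-style) blocks are consumed from a
block definition file rather than recomputed, and the two partitions of
one population are merged by transitive closure of co-occurrence —
whether the original merging was a plain union or a closure is not
documented, and the closure is the only choice that again yields a
partition. LD itself is the Pearson correlation $r$ of allele
indicators over the $2N$ phased chromosomes (not genotype dosages), and
the genetic distance used throughout is $1-|r|$.

## Explanatory power and its controls

Transcript oriented ratios are regressed on regulatory oriented ratios
by ordinary least squares and summarised by $R^2$. Observations are
per-sample (regulatory, transcript) ratio points pooled across samples
and pairs; per-pair averaging is available via `per_pair = TRUE`. The
distance curve is cumulative — at each threshold $d$ the regression
pools all pairs with $1-|r| \le d$ — with a default grid of 0 to 1 in
steps of 0.1 and `NA` wherever fewer than three points qualify.

Two controls accompany the curve: pairing through four independently
permuted interactomes (second anchors shuffled within chromosome,
preserving the anchor multisets), which should and does collapse the
explanatory power, and an eQTL-edge pairing mode in which SNP-gene
links replace chromatin interactions in the same pipeline.

The phased/unphased contrast is generated by `simulateLdPairs()`:
two-locus systems spanning the LD decay, with the planted effect
attached to a physical haplotype. Phased orientation keeps the pooled
$R^2$ flat in distance; reference-genome orientation retains it only at
short range. This mirrors the published observation that phasing is
what makes long-range allelic pairing possible.

## The QTL comparator arm

Peak intensities and expression levels are regressed on additive
genotype dosage (0/1/2 alternative alleles) with no covariates or
normalisation, using the two-sided t-test on the slope; hQTL-eQTL pairs
require both associations at unadjusted $P < 0.05$ and effect signs
that agree for activating marks. The published comparison only covered
activating marks; for completeness the sign rule inverts for the
repressive mark, flagged via the `polarity` argument. On small panels
with realistic trait noise the allelic arm detects at least as many
tags as the QTL arm — the acceptance script reports both counts on a
10-sample synthetic panel.

## Predictive allelic mapping

Features per variant-gene pair are binary epigenomic overlap bits (peak
covering the variant; peak covering at least half of the promoter,
where the promoter spans 1.5 kb upstream to 0.5 kb downstream of the
TSS, strand-aware, 2000 bp before clamping), GO membership bits,
unsigned variant-TSS distance, and precomputed TF binding affinities
(absent evidence scores 0). Motif scanning itself is out of scope;
affinities are inputs.

The classifier is a Random Forest ensemble: stratified 5-fold cross
validation repeated twice gives 10 forests of 1,000 trees each (default
`mtry` $= \lfloor\sqrt{p}\rfloor$, node size 1), every pair held out
exactly twice. The 10:1 class imbalance of the real data is handled
without resampling, as published; stratification (a package choice, the
published folds are not described) keeps per-fold class ratios stable.
AUC is computed from held-out probabilities by the midrank statistic
and cross-checked against an independent implementation in the tests.
All 10 classifiers vote on every untestable pair and a rescue call
requires strictly more than 5 positive votes. Subpanel experiments
draw 2, 5, 10 or 20 samples, 10 resamplings each, retrain per subpanel
and validate rescued calls against the full panel.

## What the generator emulates, and what it does not

`simulatePanel()` builds, per tag, a founder-copy haplotype segment
(redraw probability `ld_decay` per SNP, alt frequency `maf`), a ChIP
peak hosting the candidate block, an interaction to a downstream gene
with transcript SNPs, binomial allelic counts with the planted effect
attached to the haplotype carrying the causal alt allele, Gaussian
dosage-effect trait matrices, and per-pair feature tables whose bits
differ by latent class. Defaults are a 100-sample panel — the scale of
the real lymphoblastoid reference panel — with effect fraction 0.8 and
depth 50, the regime in which direct testing is near-saturated, so that
subpanel experiments isolate the heterozygote-availability limitation
the rescue model addresses. Alt-allele frequency 0.15 makes joint
heterozygotes scarce in small subpanels (the phenomenon under study)
while keeping the full panel informative.

The generator deliberately omits: read-level artefacts and reference
mapping bias, count overdispersion beyond binomial, trans effects and
covariance between samples, realistic feature correlation structure,
and coalescent-accurate LD. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not performance
on real sequencing data. Feature tables are generated with planted
class signal, so classifier results validate the ensemble machinery and
vote bookkeeping, not the biological informativeness of any real
feature set.

## Numerical choices

* Coordinates: VCF and SNP positions are 1-based; BED/BEDPE are 0-based
  half-open and converted once at import, so a 1-based position $p$ is
  inside a BED interval $[s, e)$ iff $s \le p-1 < e$.
* Study-averaged depths round half-up before testing.
* Zero P values are clamped to the smallest positive double before
  Fisher combination, with a warning.
* Monomorphic SNPs give a flagged undefined LD stat; monomorphic
  dosages are skipped by the QTL scan.
* Ratio ties at exactly 0.5 carry no major allele and are excluded from
  direction matching.
* All stochastic steps route through explicit integer seeds; reruns are
  reproducible file-for-file except for forest internals.

## Problem sizes

The test-suite and acceptance-script simulations use panels of 10-100
samples, 2-20 tags (up to 200 candidate pairs), depth 30-1000, forests
of 60-200 trees, and 5,000-pair regression recoveries; these sizes give
stable Monte-Carlo margins for every property asserted while keeping a
full run in minutes. The package defaults (`forestConfig()`: 1,000
trees; `simConfig()`: 100 samples) remain the published configuration.

## Known limitations

Beta-binomial overdispersion and WASP-style mapping-bias correction are
plausible extensions the implemented procedure does not use. Gabriel
confidence-interval blocks are consumed, never computed. Peak calling,
read alignment, variant calling and motif scanning are upstream of this
package: counts, peaks, interactions and affinities are inputs. The
direction-consistency question inside the Fisher combination (see
above) is exposed but not enforced.
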