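---
title: "Allele-specific methylation, imprinting and placental morphometry: methods"
author: "alleleMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific methylation, imprinting and placental morphometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleMeth)
```

## The scientific problem

Cloned (somatic cell nuclear transfer, SCNT) primate embryos fail
disproportionately around implantation. A key molecular signature is
epigenetic: compared to fertilization controls (intracytoplasmic sperm
injection, ICSI), cloned blastocysts carry thousands of differentially
methylated regions (DMRs) and lose the maternally biased DNA methylation
that marks imprinted loci, so genes that should be expressed from one
parental allele become biallelic (loss of imprinting, LOI). Detecting this
requires *allele-specific* analysis, which in turn requires a hybrid cross:
when the two parents are homozygous for different alleles at a SNP, every
offspring read covering that SNP reveals its parent of origin.

`alleleMeth` implements the full desk-scale analysis chain for such a
study: informative-SNP selection from parental variant calls, N-masking of
the reference, SNP-based assignment of bisulfite and RNA reads to alleles,
per-CpG methylation extraction with spike-in conversion control, DMR
calling, a negative-binomial differential-expression engine, the
imprinted-gene filtration cascade with LOI calls, calcification
morphometry of placenta slides, and gestational-outcome statistics. A
synthetic-data generator produces every input with known ground truth, so
each stage is validated end to end without any external download.

## The synthetic study and what it does (and does not) emulate

`simConfig()` fixes the study conditions. The defaults describe a hybrid
cross at desk scale:

* **Genome**: 2 chromosomes of 100 kb of uniform random sequence. Uniform
  base composition yields one CpG per ~16 bp, a convenient density: a
  650 bp planted region carries ~40 CpGs, a 2 kb region ~125.
* **SNPs**: homozygous-divergent parental SNPs at `snpRate = 2e-3` per bp,
  a generous hybrid density so most reads can be assigned. SNPs are never
  planted inside a CpG dinucleotide on either haplotype and substitutions
  that would create a CpG are excluded, so both haplotypes share one CpG
  landscape and no scored cytosine is confounded with a variant.
* **Methylome**: background CpG methylation 0.4 per allele (a
  blastocyst-like global level), with planted regions of three kinds:
  `maternal_imprint` (maternal 0.9 / paternal 0.1; a `lost` flag erases
  the maternal mark in the test condition), `somatic_hypo` and
  `somatic_hyper` (both alleles move together between conditions,
  emulating somatic-memory regions).
* **Reads**: directional bisulfite model (original-top and original-bottom
  strands only), reported on the reference frame with match-only CIGARs;
  unmethylated cytosines convert C→T (top) or appear as G→A (bottom) with
  probability `conversionEfficiency` (default 0.99). Non-CpG cytosines are
  fully unmethylated. `lambdaFraction` of reads come from an unmethylated
  spike-in contig. A `nonDirectional` flag is reserved for PBAT-style
  libraries; the generator defaults to the directional protocol rather
  than guessing per sample.
* **Expression**: negative-binomial counts per gene and group
  (`dispersion = 0` degenerates to Poisson); allelic RNA records are drawn
  with a configured maternal fraction and anchored on informative SNPs
  inside their gene, emulating the SNP-overlapping subset of an alignment
  (the only subset an allele splitter can use).
* **Slides**: a bright tissue ellipse on a dark background carrying a
  small population of brighter calcified particles, with bounded uniform
  intensity jitter (±6 grey levels). Bounded noise mirrors the even
  illumination the thresholding recipe assumes; with Gaussian tails the
  automatic thresholds cut one bin into a class tail and stray tail
  pixels masquerade as particles.
* **Gestation**: abortion days are lognormal per group; the defaults put
  the test-group median near day 60 and the control median near day 130,
  the contrast reported for cloned versus fertilized pregnancies.

What the generator does **not** emulate: sequencing errors and quality
scores, indels and structural variants, paired-end fragment geometry,
M-bias, PCR duplicates, non-CpG methylation, stain-specific colour
variation, and censored pregnancies (abortion-time tables record events
only). Green tests therefore demonstrate the correctness of the
*algorithms* under clean, well-specified inputs — not robustness to every
artefact of real libraries.

All randomness flows from one integer seed; each stage draws from a
deterministically derived substream, so adding a stage never perturbs the
draws of another and identical configs give byte-identical outputs.

## Informative SNPs and masking

Parental variant records are hard-filtered with the standard site filters
(QD < 2.0, MQ < 40.0, FS > 60.0, SOR > 3.0, MQRankSum < −12.5,
ReadPosRankSum < −8.0; all strict, so boundary values pass). A missing
annotation does not fail its sub-filter — rank-sum annotations are
routinely absent at sites without heterozygous calls — but the record is
flagged. Informative SNPs are exactly the homozygous-divergent sites;
heterozygous, shared-allele and multi-allelic sites are excluded. The
reference is N-masked at informative positions so alignment (out of scope
here) cannot prefer one allele; masking is idempotent and exported as
0-based half-open single-base BED. Coordinate conversions live in one
utility pair (`posToBed()` / `bedToPos()`) to prevent off-by-one drift.

## Allelic read assignment

A read is scored at every informative SNP it covers. In bisulfite mode a
SNP is unusable when conversion can mimic either allele — C/T SNPs (either
assignment) for top-strand reads, G/A for bottom-strand reads — and an
observed T additionally supports a C allele on the top strand (a converted
cytosine), mirrored on the bottom strand. Equal support for both alleles
is `conflicting` (the conservative convention); no usable SNP is
`unassigned`; a third base is a mismatched-base event supporting neither
side. The whole decision table is validated against an exhaustive
enumeration of base × strand × allele-pair combinations. Per-feature
allelic fractions require 10 assigned reads by default (`minReads`); the
floor is configurable since no standard value exists.

## Methylation extraction and conversion efficiency

Per-CpG calls mirror standard extractor logic: C over the CpG cytosine is
methylated, T unmethylated, with the mirror reading at the G on
bottom-strand reads; symmetric CpG calls are merged to the top-strand
coordinate by default (a flag preserves strand resolution). Conversion
efficiency is unmeth/(meth+unmeth) pooled over all spike-in calls, with an
explicit `no_coverage` status. Window levels (default 10 kb) are
*unweighted* means of per-CpG levels with a coverage floor of one read —
the tiling-window convention — and terminal partial windows are emitted
and flagged rather than dropped. Group comparisons use the two-sided
Wilcoxon rank-sum test, exact for small tie-free samples. Metaprofiles
rescale region bodies to a fixed bin count with absolute-bp flanks and
satisfy an additivity property: the profile of a union of disjoint region
sets equals the CpG-count-weighted average of the separate profiles.

## DMR calling

Each shared covered CpG is tested with a two-sided Fisher exact test on
the 2×2 methylated/unmethylated table (vectorized over unique tables; the
test suite checks equality with the reference exact test to 1e-12). A CpG
*qualifies* when p < 0.05 (unadjusted) with a nonzero, sign-consistent
difference. Qualifying CpGs chain into runs while the genomic gap stays
≤ 1 kb **and** at most 2 non-qualifying CpGs intervene, and a run boundary
is trimmed until its terminal qualifying CpG has a qualifying neighbour
within 1 intervening CpG. The extra locality rules are this package's
design: with a 5% per-CpG alpha, a 1 kb gap alone spans dozens of CpGs at
typical density, and isolated background-significant CpGs would otherwise
chain onto true region edges and blur boundaries. Emitted regions must
span ≥ 25 CpGs, contain ≥ 25 significant CpGs and show ≥ 25% absolute mean
difference — the region filters are enforced verbatim and independently
configurable, since the two stated forms (25 significant CpGs; 25%
difference) are both honoured by default. `meanDiff` averages the
(test − control) difference over *every* joined CpG in the span; `hypo`
means lower methylation in the test (cloned) condition. Annotation is by
DMR midpoint with priority promoter > exon > intron > TTS > intergenic,
promoter = [−1000, +100] bp around the strand-aware start and TTS its
mirror; without an exon table the gene body counts as exonic.

Reproducing any genome-wide DMR tally of a real study is explicitly not a
goal — that depends on the deposited data and the original HMM-based
toolchain; the 25/25/25% region contract is what is honoured.

## Differential expression and the imprinting cascade

The DE engine is deliberately self-contained: median-of-ratios size
factors, per-gene pooled within-group method-of-moments NB dispersion
floored at 0.01, and a normal Wald test on the log ratio of normalized
group means with a delta-method standard error
(var = μ + αμ² per group). Threshold semantics are the contract —
p < 0.01, fold change > 2, baseMean > 10 — not bit-compatibility with any
external engine (which the suite uses only as an independent
cross-check). With 3 replicates per group and dispersion 0.1, planted
4-fold genes pass at ≳95% sensitivity while null genes pass at ~1%; the
fold-change requirement, not the p-value, is what controls the null rate
at this design size.

The cascade filters an imprinted-gene catalogue (a synthetic
catalogue-style fixture ships with the package; users substitute their
own): stage 1 keeps genes with FPKM > 1 in both groups; stage 2 intersects
with DMR-associated genes (gene body ± 2 kb overlapping a called DMR);
stage 3 applies the FPKM-ratio screen (> 2 or < 0.5, control mean set
to 1). A parallel route intersects the catalogue with DE calls and then
with DMR association. Allelic status uses fraction bands —
monoallelic ≤ 0.15 or ≥ 0.85, biallelic 0.30–0.70, otherwise not
evaluable, with a 10-read floor; the bands are this package's choice since
no numeric bands are standard. LOI = monoallelic control plus biallelic
test, or (when allelic methylation is supplied) a maternal methylation
bias ≥ 0.3 in control lost in test. Stages are provably nested, and LOI
never fires when both conditions draw from the same allelic distribution.

## Morphometry

Slides are 8-bit grayscale. The total tissue area is segmented with the
Huang fuzzy-entropy threshold (membership bandwidth = span of the occupied
histogram; ties take the lowest level) and the calcified area with the Yen
maximum-correlation threshold, both as pixels strictly above the level,
with the calcified mask intersected with the tissue mask. Connected
particles (8-connectivity, the particle-analysis default) strictly smaller
than 0.0003 mm² are removed — a particle of exactly the cutoff is kept.
Areas and counts are pooled across a placenta's slides before division:

* CCI = (calcified area / total area) × 100 (percent),
* CCN = (calcified dots / total area) × 100 by the printed formula. The
  ×100 is kept as the default because the formula is printed that way,
  although CCN is described as dots per area; `ccnTimes100 = FALSE`
  reports plain dots/mm². Both conventions are computed.

Thickness is the minor bounding-box dimension of the largest connected
tissue component (debris cannot inflate it), averaged over slides.
Real-slide thickness direction is ambiguous; on synthetic slides the
tissue ellipse is axis-aligned so the minor extent is exact.
Reproducing any real study's CCI or thickness values is not a goal — those
slides are not available; the formulas and the truth-recovery tolerances
are the contract.

## Outcome statistics

Rates are 100·k/n rounded half away from zero to one decimal — the
convention that reproduces every printed outcome-table value (e.g. 3/113 →
2.7). The chain surviving ≤ live births ≤ fetuses ≤ implanted is enforced.
Survival uses the product-limit estimator with the median defined as the
earliest time the curve reaches 0.5 or below (reported as missing when it
never does — deliberately not the interpolated convention some packages
print when the curve sits exactly at 0.5). Group comparison is the
standard unweighted log-rank test (1 df). Abortion-time tables are
event-only records, matching curves drawn from aborted fetuses, with each
fetus as the unit of analysis. Densities are Gaussian-kernel with
Silverman's rule by default (no bandwidth is standard for these plots).

## Numerical choices and degenerate inputs

* Fisher p-values use the conventional (1 + 1e-7) relative slack for ties.
* `which.min`/`which.max` tie-breaks make Huang/Yen return the lowest
  optimal level.
* Constant images have no valid threshold and return a sentinel status.
* Zero-coverage CpGs are omitted; all-zero genes are excluded and flagged;
  empty spike-in coverage yields `no_coverage` rather than NaN.
* All validity checks live in S4 validity methods (`SimConfig`,
  `HybridGenome`, `DMRSet`), so malformed objects fail at construction.

## Problem sizes used in the test suite

The suite exercises the DMR caller on 2-Mb genomes over ten replicates
(~125,000 CpGs each at 30× coverage), the allelic pipeline on 40-kb
genomes at 40× over ten replicates, the DE engine on 440-gene designs over
twenty replicates, and the morphometry on 400×300-pixel slides — sizes
chosen so the entire suite completes in a few minutes on one core while
keeping every statistical check well-powered.

## Known limitations

* The bisulfite model has no sequencing error, so assignment accuracy is
  effectively perfect; real data would shift some reads to
  `unassigned`/mismatch rather than misassign, but rates will differ.
* Method-of-moments dispersion with 3 replicates is noisy; the floor and
  the fold-change threshold compensate at the tested effect sizes, and no
  shrinkage across genes is attempted.
* The DMR caller assumes two pooled samples per condition (count tables),
  not per-replicate variance.
* Spliced RNA CIGARs are handled only as N-gap skipping.
* The morphometry recipe applies global thresholds to the full histogram;
  slides whose classes overlap (heavy noise, uneven staining) need
  preprocessing outside this package's scope.
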