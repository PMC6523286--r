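---
title: "Detecting shadow-Y markers and characterizing Y retrocopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shadow-Y markers and characterizing Y retrocopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadowY)
```

## The problem

SNP genotyping arrays for species whose reference genome was assembled from
a female (as the canine reference was) can carry probes whose target has a
second, diverged copy on the Y chromosome.  In a male, the probe hybridizes
both the autosomal/X target and the hemizygous Y paralog, so every diverged
Y nucleotide is read as a heterozygous call; a female, lacking the Y copy,
shows one homozygous genotype.  These *shadow-Y markers* masquerade as
highly polymorphic autosomal SNPs and produce spurious associations
whenever sex is unbalanced between cases and controls.  When the duplicated
segment is an intron-less, reverse-transcribed gene copy (a *retrocopy*),
the markers also point at novel, unannotated Y-chromosome gene content.

shadowY implements the full detection-and-characterization pipeline:

1. a genome-wide association scan for sex with an exact dominant-model
   test (`filter_markers()`, `filter_samples()`, `run_sex_gwas()`);
2. genotype-pattern classification of the hits and merging into genomic
   regions (`classify_marker()`, `cluster_regions()`,
   `annotate_regions()`, `summarize_catalog()`);
3. a male-vs-female contrast of whole-genome alignment features that
   operationalizes the duplication signature of a Y retrocopy
   (`contrast_windows()`, `summarize_region_call()`);
4. sequence-level comparison of retrocopies: global alignment, percent
   identity, shared diverged sites, ORF truncation (`align_global()`,
   `shared_polymorphisms()`, `predict_orf_truncation()`);
5. Dollo-parsimony placement of retrocopy gains on a species tree
   (`dollo_place()`);
6. seeded simulators for every input, with ground truth
   (`simulate_genotypes()`, `simulate_feature_tracks()`,
   `simulate_retrocopy_sequences()`).

## The association model

Each marker is reduced to a 2x2 table of sex against dominant-model
carrier status (heterozygous or homozygous for the minor allele).  The
two-sided Fisher exact P is the sum of hypergeometric point probabilities,
over all tables with the observed margins, that do not exceed the observed
table's probability (ties included; no mid-P or continuity adjustment).
Point probabilities are computed in log space so a 25 + 25 cohort is far
from any overflow.  For the pattern of interest — all 25 males carriers,
no female carriers — only the observed table and its mirror image qualify,
so

$$P = \frac{2}{\binom{50}{25}} \approx 1.58 \times 10^{-14},$$

which is the value every true shadow-Y marker shares in a complete-call
cohort of that size.

```{r}
dominant_fisher(rep("het", 25), rep("hom_ref", 25))
```

Choices worth making explicit:

* **Minor allele.**  Dominant coding is with respect to the minor allele
  in the full QC-retained cohort at that marker.  A tie at MAF 0.5 is
  resolved to the alphabetically first allele letter — an arbitrary but
  deterministic rule; the two-sided P is unaffected by which allele is
  declared minor for the perfect-separation tables that matter here.
* **Significance.**  Bonferroni, `alpha / n_markers`, compared
  inclusively (`p <= threshold`).  Inclusive vs exclusive cannot change
  any call except at exact equality, which has probability zero in
  practice, but the boundary behavior is fixed and documented.
* **Missingness.**  Complete-case per marker; a marker with one sex
  entirely missing is flagged rather than aborting the scan.
* **QC boundaries.**  Marker filters are inclusive (call rate >= 0.95,
  MAF >= 0.05 retained); the sample filter is strictly exclusive
  (call rate > 0.97), mirroring the conventions of the study design the
  defaults come from.

## Pattern classification and regions

A significant marker is `SHADOW_Y` when all non-missing males are
heterozygous (up to `male_tolerance`, default 0) *and* all non-missing
females share one homozygous genotype.  "Monoallelic" deliberately
requires a homozygous genotype: a heterozygous female is direct evidence
the marker segregates in females and disqualifies the hemizygous-paralog
model.  Markers whose females are monoallelic but whose males mix
heterozygous and homozygous calls are `EXCLUDED_HOM` — the pattern that
led to one X-linked hit (in *PGK1*) being excluded in the motivating
study — and everything else is `OTHER`.  `male_tolerance` exists for
noisy cohorts; the default is strict because the pattern, when real, is
essentially deterministic.

Regions are built by single-linkage merging of markers along a
chromosome with a 1 Mb gap threshold.  No merging rule is canonical; 1 Mb
reproduces one region per published marker cluster (the 18
chromosome-19 markers merge into a single region spanning 279,310 bp,
i.e. just under 300 kb) and is exposed as `max_gap`.  Clustering is
order-invariant and idempotent.  Annotation is point-in-interval with
priority genic > telomeric > centromeric > intergenic; telomere and
centromere windows default to 500 kb and are explicit inputs because
centromere coordinates are genome-build-dependent and not something this
package should hard-code.

```{r}
cat50 <- sex_marker_catalog()
r <- cluster_regions(cat50[cat50$chrom == "19", c("id", "chrom", "pos")])
r[, c("region_id", "span_bp", "n_markers")]
```

## The duplication signature

In whole-genome alignments, a male-specific duplication of an expressed
exon shows four co-occurring anomalies relative to females: elevated
depth, elevated heterozygous-site density, discordant mate pairs, and
low-mapping-quality reads.  The original evidence for this signature was
visual; `contrast_windows()` turns it into explicit thresholds on
sex-mean contrasts:

| criterion | statistic | default threshold |
|---|---|---|
| depth (required) | male mean / female mean | >= 1.3 |
| heterozygosity | male - female, sites/kb | >= 1.0 |
| discordant mates | male - female fraction | >= 0.05 |
| low mapQ | male - female fraction | >= 0.05 |

A window is called when the depth criterion holds and at least
`min_supporting_criteria` (default 2) of the other three do.  All
thresholds are package inventions, chosen once so that a planted 1.5x
depth effect with elevated rates is recovered while null windows stay
below 5% false calls, and every one is a knob in
`signature_thresholds()`.  The female mean depth is used as the ratio
denominator directly; only a zero female mean is replaced by 0.5 to avoid
division by zero, so the calls are exactly invariant to a global depth
rescale whenever female coverage is positive.  A gene-level verdict
(`summarize_region_call()`) additionally requires the signal to be
exon-only — retrocopies are spliced, so intronic signal indicates a
tandem-like duplication instead.

## Sequence comparison

`align_global()` is an end-to-end dynamic-programming aligner with affine
gaps (a gap of length $k$ costs `gap_open + k * gap_extend`, defaults
-5 and -1, with +1/-1 match/mismatch) and fully deterministic
tie-breaking (diagonal, then up, then left).  Determinism matters because
diverged-site coordinates feed the shared-polymorphism rule; an aligner
that breaks ties arbitrarily could move an indel between runs.  Percent
identity excludes gap columns by default; an include-gaps mode exists
because similarity conventions differ between tools.

The ancestry rule: two retrocopies of the same parent that share more
than 2 diverged sites (same parent coordinate *and* same substituted
base) are called descendants of one ancestral retrotransposition;
`n_shared >= 3` is the strict reading of "more than 2".  Indel sharing is
reported separately and never counts toward the rule — "polymorphism" is
read conservatively as a single-base substitution.

`predict_orf_truncation()` reads the copy in the parent frame from the
aligned start codon and translates to the first stop.  The reported copy
protein length is the number of codons translated *before* that stop,
and the truncation fraction is `1 - copy/parent` against the parent
length excluding its stop codon.  Frameshifts are alignment indels whose
length is not a multiple of 3.

## Dollo placement

Retrocopy presence/absence across species is placed on a fixed rooted
tree under Dollo parsimony: the homologous copy arises exactly once and
may be lost repeatedly.  The minimal solution is a gain on the stem above
the most recent common ancestor of the present tips plus one loss per
maximal present-free subtree containing an absent tip.  Ties are broken
toward the root: the gain slides rootward across purely unconstrained
(unknown) sister clades, which also makes placements deterministic.
`unknown` tips impose no constraint; `present_independent` tips model a
copy known to be an independent event — they carry a mandatory gain on
their own terminal branch and are excluded from the shared copy's
objective.  The species tree is always an input (Newick); the 5-taxon
canid topology used in examples and tests is just a default fixture, not
hard-coded biology.

```{r}
tr <- "(urocyon,(vulpes,(lycaon,(latrans,familiaris))));"
dollo_place(tr, c(familiaris = "present", latrans = "present",
                  lycaon = "present", vulpes = "absent",
                  urocyon = "present_independent"))
```

## What the simulators emulate — and what they do not

`simulate_genotypes()` reproduces the statistical structure the inference
relies on: Hardy-Weinberg null markers with sex-independent allele
frequencies, the deterministic shadow-Y pattern, array-style X-linked
markers (male hemizygotes emitted as homozygous calls), and the
excluded-type male het/hom mixture (50:50 by default; the real example
was only described qualitatively).  Defaults are a 25 + 25 cohort with
uniform MAF in [0.05, 0.5].  It deliberately omits linkage
disequilibrium, population structure, relatedness, and genotyping-error
structure, so a passing recovery test demonstrates correctness of the
statistics, not robustness to confounding in real cohorts.

`simulate_feature_tracks()` draws per-window mean depth as a normal with
5% coefficient of variation (the mean of thousands of per-base depths in
a 1 kb window is tight; window-to-window mappability variation in real
data is larger and is *not* modeled), het sites as Poisson, and read
fractions as binomial on a finite read count.  Effect sizes in male exon
windows (1.5x depth, 4/kb heterozygosity, 15% discordant, 20% low-mapQ
against backgrounds of 1/kb, 1%, 2%) are plausible placeholders for a
signature that was never quantified in print; they are config fields,
not constants.

`simulate_retrocopy_sequences()` uses uniform base composition and
uniform substitutions (no transition/transversion bias, no rate
heterogeneity) because the quantities of interest — identity percentages
and shared diverged sites — depend only on substitution counts.
Divergence 0.02 and 0.11 reproduce the ~98% and ~89% identity regimes of
the two autosomal retrocopies that motivated the defaults.

All three generators draw every random number under a single seed via
`withr::with_seed()`, leaving the global RNG untouched and making every
output byte-reproducible.

## Problem sizes and numerical choices

The test suite runs the full scan on 5,010-marker arrays across 20 seeds
(the planted 10 shadow-Y markers are recovered exactly with zero false
calls), contrasts 200-window tracks across 3 seeds, checks the exact
test against a brute-force enumeration on all 8,281 tables with margins
up to 12, the aligner against exhaustive path enumeration on short pairs
and an independent affine-gap implementation on longer ones, and Dollo
placement against exhaustive gain/loss enumeration on all
present/absent profiles of trees up to 6 tips.  These sizes keep the
suite fast while leaving no untested branch in the combinatorial cores.

Numerical details fixed by design: exact-test ties are included with a
1e-7 relative tolerance (the conventional two-sided rule); QC boundary
comparisons carry a 1e-12 epsilon so exact-fraction call rates like
38/40 are retained at a 0.95 threshold; alignment scores are exact
integers in double precision for the default scheme.

## Known limitations

* The sex scan assumes correct sex labels; label errors break the
  perfect-separation pattern rather than producing false positives.
* Pseudoautosomal markers legitimately associate with sex and are not
  modeled separately; they surface as `OTHER` patterns.
* The signature module consumes precomputed per-window feature tables;
  computing those tables from BAM files is outside the package (any
  windowed coverage/flag summary tool produces the TSV contract).
* Telomeric/centromeric annotation is only as good as the interval
  inputs; counts derived from it are annotation-dependent by nature.
* Dollo placement assumes the input topology; it dates nothing and
  cannot distinguish a root-branch gain from a gain older than the root.
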