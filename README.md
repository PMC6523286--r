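# shadowY

Detection of cryptically Y-linked SNP-array markers ("shadow-Y" markers)
and characterization of the Y-chromosome retrocopies behind them.

## The problem

SNP arrays built against a female reference genome can carry probes whose
target sequence has a diverged, male-specific paralog on the Y chromosome
— often an intron-less retrocopy of an autosomal or X-linked gene.  In
males the probe hybridizes both copies, so each diverged Y nucleotide is
read as a heterozygous genotype; females, lacking a Y, are monomorphic.
Such markers look like highly polymorphic autosomal SNPs and generate
spurious hits whenever sex is unbalanced in a case-control cohort.  They
are also a map to unannotated Y-chromosome gene content.

shadowY is for geneticists working with array data from species with an
incomplete Y assembly (the motivating case is the dog).  It finds these
markers with a genome-wide association scan for sex, classifies and
clusters the hits, scores the whole-genome-sequencing duplication
signature of a retrocopy, compares retrocopy sequences across species,
and places retrotransposition events on a species tree.

## The statistics at the core

**Dominant-model exact test.**  Each marker becomes a 2x2 table of sex
against carrier status (carrier = heterozygous or homozygous for the
cohort minor allele).  The two-sided Fisher exact P sums hypergeometric
point probabilities ≤ that of the observed table over all tables with the
observed margins.  For the shadow-Y pattern in a complete-call 25 male /
25 female cohort — all males carriers, no female carriers — only the
observed table and its mirror qualify:

    P = 2 / C(50, 25) ≈ 1.58 x 10⁻¹⁴

Significance is Bonferroni at `alpha / n_markers`.

**Pattern rule.**  A hit is shadow-Y when all males are heterozygous and
all females share one homozygous genotype; females monoallelic with a
male het/hom mixture is the excluded pattern; anything else is other.

**Ancestry rule.**  Two retrocopies of one parent sharing more than 2
diverged sites (same parent position, same substituted base) are called
descendants of a single ancestral retrotransposition.

**Dollo placement.**  Presence/absence across species is explained by
exactly one gain plus a minimal number of losses on a fixed rooted tree,
with deterministic root-ward tie-breaking.

## Worked example

Simulate a 25 + 25 cohort with 5,000 Hardy-Weinberg null markers and 10
planted shadow-Y markers, scan for sex, and classify the hits:

```r
library(shadowY)

sim  <- simulate_genotypes(sim_config(n_males = 25, n_females = 25,
                                      n_null_markers = 5000,
                                      n_shadow_markers = 10, seed = 42))
gwas <- run_sex_gwas(sim$genotypes)
gwas
#> <sex_gwas> 5010 markers tested, Bonferroni threshold 9.98e-06
#>   genome-wide significant: 10

hits <- gwas$results$marker[gwas$results$significant]
pat  <- classify_markers(sim$genotypes, hits)
table(pat$pattern)
#> SHADOW_Y
#>       10

head(gwas$results[gwas$results$significant, ], 3)
#>   marker  chrom       pos     a     b     c     d  p_value
#> 1 M000304 13     44958991    25     0     0    25 1.58e-14
#> 2 M000860 7     116725069    25     0     0    25 1.58e-14
#> 3 M001024 14     26759211    25     0     0    25 1.58e-14
```

All ten hits are the planted markers, each with 25/25 male carriers vs
0/25 female carriers (`a`–`d`) and the perfect-separation P of
1.58 x 10⁻¹⁴; the 5,000 null markers produce zero hits at Bonferroni.

The package ships the published 50-marker catalog from the German
shepherd sex GWAS as a fixture:

```r
cat50 <- sex_marker_catalog()
cluster_regions(cat50[cat50$chrom == "19", c("id", "chrom", "pos")])
#>   region_id            chrom    start      end span_bp n_markers
#> 1 19:20034966-20314276 19    20034966 20314276  279310        18
```

— the 18 chromosome-19 markers merge into one region just under 300 kb.
See the vignette (`vignettes/shadow-y-detection.Rmd`) for the duplication
signature, sequence comparison and Dollo placement modules.

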