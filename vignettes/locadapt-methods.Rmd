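---
title: "Methods: detecting local adaptation in structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting local adaptation in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locadapt)
```

## The problem

`locadapt` implements a complete analysis path for detecting local
adaptation from whole-genome resequencing of a small number of natural
populations sampled along an environmental gradient — the motivating system
is three mangrove populations (labelled F, S and W; 14, 17 and 15 diploids)
spanning a coastal temperature cline. The pipeline answers three questions:

1. **How are the populations related and how did they get here?**
   Windowed diversity (θπ), divergence (FST, DXY), PCA, and SFS-based
   demographic model comparison.
2. **Where has recent positive selection acted?** Joint FST + XP-CLR
   sliding-window scans merged into highly differentiated regions (HDRs),
   corroborated by Fay and Wu's H and per-gene McDonald–Kreitman tests.
3. **Which loci track the environment?** Redundancy analysis (RDA) of the
   genotype matrix against location-level climate (MAT, MAMT, MAP),
   loading outliers, and enrichment of those outliers inside HDRs.

A candidate gene for local adaptation must satisfy both lines of evidence:
it overlaps an HDR *and* contains at least one RDA-outlier SNP within its
exons.

## Input model and filtering

Genotypes enter as VCF 4.2 with per-sample GT and DP and the usual GATK
site annotations. Hard filters follow the standard convention: genotypes
with depth < 3 are set missing; sites are removed when minor allele
frequency < 0.05 (computed over non-missing genotypes, minor allele
regardless of ref/alt orientation), QD < 2, FS > 60, MQ < 40,
MQRankSum < −12.5 or ReadPosRankSum < −8. The rank-sum thresholds follow
the conventional "fail low" direction; absent annotations never fail a
site because rank-sum statistics are undefined at homozygous-only sites.
Each removed site is counted once under the first failing rule, in a fixed
rule order, so removal reports are unambiguous and filtering is
idempotent.

Sites are classified by feature with the precedence exon (CDS) > UTR >
intron > promoter > intergenic. A promoter is the 2-kb window upstream of
a transcription start site, strand-respecting, and only outside gene
bodies: the precedence encodes "most specific wins". On-disk coordinates
are 1-based inclusive (VCF/GFF3); all in-memory intervals are 0-based
half-open.

## Diversity and spectra

Windowed θπ divides the sum of per-site heterozygosities
2j(n−j)/(n(n−1)) by the full bin span (20 kb by default), the convention
of variant-only windowed-π tools; the per-variant-site mean is also
reported because the two conventions differ by four orders of magnitude at
typical SNP densities and published values are often on the per-SNP scale.
DXY is offered in the same two modes (`per_site`, `per_snp`) for the same
reason — neither is asserted to be "the" published scale. Chromosome-end
partial bins divide by their actual span.

SFS construction uses hypergeometric projection: a site with derived count
j among n non-missing haplotypes contributes dhyper(k; j, n−j, m) to class
k at projection size m. Projection conserves mass, commutes with folding,
and fractional entries are kept as reals. Polarization takes the ancestral
allele from a single outgroup; sites where the outgroup matches neither
allele are excluded from polarized spectra.

## Demographic inference

Fifteen model templates cover one- and two-step divergence orders,
bottleneck-with-recovery or exponential change in each population, four
asymmetric migration configurations, and a composite model (divergence +
bottleneck in S + expansion in F + full asymmetric migration). Expected
joint SFS come from a structured-coalescent engine (C++): branch lengths
subtending each joint derived-count configuration are accumulated and
averaged over genealogies, which has far lower Monte-Carlo variance than
dropping mutations. The composite likelihood is multinomial over
polymorphic cells without the parameter-free multinomial coefficient;
empty expected cells are floored at 1e-10; monomorphic corner cells are
excluded.

Fitting is ECM-style coordinate ascent with multiplicative steps that
shrink over cycles, from log-uniform random restarts; within one start all
likelihood evaluations share one simulation seed (common random numbers)
so the search surface is deterministic, and the final point is re-scored
with a fresh seed to remove CRN optimism. Desk-scale defaults (10 starts,
20 cycles, 1000–2000 genealogies per evaluation) are deliberately smaller
than a production run (100 starts, 80 cycles, 1e5 simulations); all are
exposed as arguments. Model comparison uses AIC = 2k − 2 lnL and Akaike
weights; `compare_models()` also accepts precomputed AIC values, because
published model tables often print AIC without the per-model parameter
count. Parametric bootstrap CIs resample the fitted expected SFS
(multinomial at the observed SNP count) and refit from the fitted point,
the standard bootstrap restart.

Unit conversions: years = generations × generation time (20 years by
default); Nm multiplies the **source** population's final-epoch Ne by the
forward migration rate — with the composite defaults this gives
Nm(F→W) = 6142 × 6.35e-4 ≈ 3.90 migrants per generation. Migration is
specified forward-time source→destination and converted internally to
backward lineage movement; the convention is stated here once and in the
engine's header comment because it is the single most error-prone
convention in the field.

## Selection scans

FST uses the Weir–Cockerham variance components per site with
ratio-of-sums window combination (negative components not clamped).
XP-CLR follows the cross-population composite-likelihood model: the
neutral distribution of the object population's frequency given the
reference frequency p1 is a truncated normal with variance ω·p1(1−p1),
ω estimated genome-wide from mean (p2−p1)²/(p1(1−p1)); a sweep at the
window centre lets a site at genetic distance d escape with probability
c = 1 − exp(−d/s̃); observed counts enter by binomial sampling; the window
score is 2(max over the s̃ grid − neutral). Practical settings the method
leaves open are fixed and documented: s̃ grid logspace(−5, −0.5, 30) plus
the neutral point, 1 cM/Mb constant map, 200-SNP window cap, and
downweighting of reference-population LD groups (sites with r² ≥ 0.95
share one unit of weight). Windows are 20 kb with 5-kb steps.

Outliers are windows ≥ 1.96 SD above the comparison mean (upper-tailed
p = 0.025); HDRs are maximal merges of windows that are outliers for
*both* statistics, with book-ended intervals treated as adjacent. Fay and
Wu's H is the unnormalized θπ − θH over polarized segregating sites, with
the realized non-missing haplotype count per site.

A genuinely open numerical point: FST and XP-CLR are computed from the
same allele-frequency data, so their window scores are positively
correlated (r ≈ 0.3–0.5 in our synthetic panels) and a purely neutral
genome still yields a small number of joint outliers (~1% of windows).
HDR calling is therefore an enrichment device, not an error-controlled
test; the tests quantify the neutral joint-outlier rate rather than
assuming independence.

## McDonald–Kreitman test

Counts come from in-frame codon alignments of ingroup haplotypes plus one
outgroup. A site is a fixed difference only if the ingroup is monomorphic
and differs from the outgroup (a polymorphic site never counts toward D);
multi-hit codons are resolved by averaging over all orderings of
single-nucleotide steps with equal weights, giving fractional counts;
gapped or ambiguous codons are excluded and tallied. The primary test is
the one-sided Fisher exact test of [[Dn, Ds], [Pn, Ps]] in the
excess-nonsynonymous-divergence direction (fractional counts rounded
half-up only at the test stage), with BH correction across genes; a
Williams-corrected G test is available as an option since both statistics
appear in the MK literature. Polymorphism is unpolarized (classic MK).

## Genotype–environment association

RDA centres the 0/1/2 genotype columns (missing codes imputed with the
per-SNP mean, count logged), regresses them on the centred environment
table, and eigendecomposes the fitted covariance; R²adj uses the Ezekiel
correction. With three sampling locations the constraint space has rank 2
regardless of how many climate variables are supplied — this is why
exactly two constrained axes exist. Axis significance is a permutation
test of the marginal pseudo-F (999 permutations by default, add-one p);
loading outliers are two-tailed 1.96-SD calls per significant axis, union
across axes. Enrichment of outlier SNPs in HDRs uses Pearson χ² without
continuity correction (the counts are large); SFS contrasts use the
two-sample KS test; PCA uses the binomial (mean 2p, variance 2p(1−p))
scaling.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, not dials:

* three populations of 14, 17 and 15 diploids plus a 1-diploid outgroup;
* the composite demographic history at its fitted point estimates
  (ancestral Ne 57,833; split 4,654 generations ≈ 93,080 years ago; F at
  6,142 with growth 1.05e-4; S at 17,072 with a bottleneck; W at 778;
  migration dominated by F→W at 6.35e-4 and S→W at 2.62e-4);
* target density 1 SNP/kb; environment table fixed at the three
  locations' climate values (MAT 19.5/23.5/24.9 °C, MAMT 5.8/12.4/15.6 °C,
  MAP 1743.3/1889.3/1913.0 mm).

Chromosomes are tiled with independent 10-kb loci: one genealogy per
locus, infinite-sites mutations, no intra-locus recombination. The
mutation rate is tuned per run from a 100-genealogy pilot estimate of the
mean ingroup-segregating branch length so the emitted density hits the
target. Sweeps are injected post hoc: a carrier haplotype's alleles are
adopted by population mates with probability exp(−d/λ) (λ = 50 kb by
default), which produces the three signatures the scan must detect —
local fixation, high-frequency derived alleles (negative H), and elevated
differentiation — without forward simulation. GEA signal sets causal-SNP
frequencies to logistic(β·(MAMT − mean MAMT)) per population and redraws
genotypes binomially.

Coding bundles place non-overlapping genes (UTR–exon–intron structure,
2-kb promoter clearance) and generate per-gene alignments under a neutral
mutation model with per-site polymorphism and divergence rates 0.15 and
0.05 and 1,500-bp CDS. These rates are deliberately condensed relative to
per-site diversity in real resequencing data: the MK test's power is set
by the per-gene *counts* (the real study aggregates 46 genomes over
16,536 orthologs), and at desk scale the counts must arrive within a
single gene for the calibration targets (selected genes with 8× inflated
nonsynonymous divergence detected at q < 0.05; neutral type-I ≤ 0.07) to
be measurable at all. The neutral calibration is unaffected because both
classes share the same rates.

What the generator does **not** emulate: intra-locus recombination and
realistic LD decay, sequencing error and depth variation beyond Poisson
depth, reference bias, gene conversion, linked background selection, and
spatially continuous sampling. Passing recovery tests therefore
demonstrates that the statistics detect the signals they are designed
for under the stated history — not that real-data false-positive rates
will match.

## Problem sizes used by the test-suite and acceptance script

Unit and property tests run on toy fixtures (tens of samples, hundreds of
sites) and small simulations (1–4 Mb genomes, ~1,000–4,000 SNPs; 20
replicates for recovery suites; 8,000 genealogies for SFS laws). The
acceptance script runs one full pipeline bundle (2 × 2 Mb) plus reduced
replicate counts for the recovery rates. These sizes are the package's
chosen desk-scale defaults; every operation exposes the parameters needed
to run at full study scale (177 Mb, ~190k SNPs, 100 optimizer starts).

## Known limitations

* XP-CLR here integrates over a fixed 48-point frequency grid and scores
  the window centre only; per-position sweep placement within a window is
  not scanned.
* The ECM optimizer's multiplicative steps quantize parameter estimates at
  roughly the few-percent level at default cycle counts.
* `anova.cca`-style sequential axis tests are approximated by marginal
  pseudo-F permutation; with rank-2 constraint spaces the distinction is
  minor.
* The MK counting path averages substitution orderings with equal weights
  (no transition/transversion weighting).
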