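---
title: "Methods: X-versus-autosome differentiation, demography and selection scans"
author: "hapXscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: X-versus-autosome differentiation, demography and selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapXscan)
```

# The scientific problem

The X chromosome is haploid in males, so it has three-quarters of the
autosomal effective population size under gender-balanced demography, spends
two-thirds of its history in females, and exposes recessive variants to
selection in every male. Comparing X-linked with autosomal population
differentiation therefore carries information both about female-versus-male
demography (effective numbers and migration) and about selection. hapXscan
implements that comparison end to end for phased biallelic SNP panels:
per-SNP differentiation scans with clustering into fixed-width genomic
windows, a demographic grid scan that asks which female shares of effective
size and migration could reconcile the two chromosome classes, hierarchical
AMOVA, and haplotype-based selection scans.

All internal coordinates are 0-based half-open; VCF (1-based) and BED
(0-based half-open) dialects are converted at the file boundary. The central
container is the `HaplotypePanel`, a `SummarizedExperiment` whose assay is a
markers-by-chromosome-copies 0/1 matrix; on X panels males contribute one
column and females two, which makes haploid-aware allele counting automatic.

# Differentiation scans

For two populations with allele-1 sample frequencies $p_A, p_B$ on $n_A,
n_B$ observed copies, the package computes per SNP:

* **delta**, $\delta = |p_A - p_B|$, the absolute frequency difference;
* **Hudson's pairwise Fst**,
  $\hat F = \frac{(p_A-p_B)^2 - \frac{p_A(1-p_A)}{n_A-1} - \frac{p_B(1-p_B)}{n_B-1}}
  {p_A(1-p_B)+p_B(1-p_A)}$, clipped to $[0,1]$ per site (the genome-wide
  estimate uses the ratio-of-averages form, which is what the simulator
  calibration is checked against);
* optionally a haploid-count Weir–Cockerham estimator.

A SNP is *high-delta* when its value strictly exceeds a threshold (0.9 by
default; 0.8 is conventional for closely related pairs where no SNP clears
0.9). A window of the `RegionGrid` containing at least one high SNP is a
*high region*; windows are anchored at the configured span start, and the
packaged non-pseudoautosomal X layout uses a 148.8-Mb span so that 200-kb
and 400-kb tilings give 744 and 372 windows. Because one published table is
ambiguous about the window width used for X-region tallies, the width is a
parameter with 200 kb as the default everywhere.

Ancestral states come from an outgroup: a marker whose outgroup genotypes
are all fixed for one base takes that base as ancestral; polymorphic or
missing outgroup calls leave the state unknown, and an optional override
table (e.g. from a database lookup) fills gaps. The enrichment summary
reports the genic fraction among high SNPs, per-population counts of high
SNPs whose *derived* allele frequency is at least 0.9 (markers with unknown
ancestral state are excluded from the denominator — "high derived frequency"
is operationalized as a 0.9 cut, configurable), genic enrichment per
delta-decile bin (bins $[0,0.1),\dots,[0.9,1]$), a genic-by-low-MAF-by-high
cross-tabulation (MAF on the copy-weighted pooled frequency), and a 2x2
chi-square without Yates correction by default.

# The TA/EX demographic grid

Writing $F' = F/(1-F)$, the linearized infinite-island relation between
autosomal and X-linked differentiation used throughout is

$$F'_X = \frac{4}{3}\,\frac{2 - N_f/N}{1 + m_f/m}\; F'_A
       = \frac{4/3}{c}\,F'_A, \qquad c = \frac{1 + m_f/m}{2 - N_f/N}.$$

Demography enters only through the combined term $c$; at
$N_f/N = m_f/m = 0.5$ the multiplier is exactly $4/3$, the classic
X/autosome ratio. The printed form of the relation only fixes the combined
term; the $4/3$ normalisation is the unique choice consistent with the
balanced-demography limit.

`demographyGridScan()` transforms the autosomal value list through this map
at every $(N_f/N, m_f/m)$ cell of a 99x99 grid (0.01 to 0.99 in steps of
0.01 — 9,801 cells; a published figure caption says "9,800 possible pairs",
which we treat as a rounding slip) and records three surfaces: the
transformed high-value count, the count of autosomal windows holding at
least one such value, and a Wilcoxon (Mann–Whitney) p-value against the
observed X list. Each autosomal value is transformed individually. Cells
sharing $c$ are computed once and are therefore bit-identical — the diagonal
bands on the surfaces. The rank test uses the tie-corrected normal
approximation with continuity correction (re-implemented for speed and
verified against `stats::wilcox.test` in the test suite; exact enumeration
for tie-free combined $n \le 20$); all-constant input yields p = 1 with a
warning. Because absolute counts are incomparable between panels of 640k
and 16k markers, "matching the X observation" is defined proportionally
(`cellsMatchingX()`).

**Which measure recovers demography.** The grid scan runs on either delta or
per-locus Hudson Fst values. For *parameter recovery* the package's own
validation uses the Fst variant: under the equilibrium Beta model the
dispersion of allele-frequency differences grows like $\sqrt F$, while the
linearized map scales values like $F$ itself, so elementwise-transformed
delta distributions are systematically wider than true X delta distributions
at the generative $c^*$ and a rank test with thousands of loci will reject
there. Per-locus Fst estimates scale linearly in $F$, making the map
distributionally consistent and $c^*$ recoverable. Delta surfaces remain
available and reproduce the qualitative banding; they should be read as a
descriptive comparison, not an estimator.

# AMOVA

`amova()` implements the Excoffier–Quattro–Smouse nested analysis on
pairwise distances: haplotypic mode treats each chromosome copy as a unit
with the count of differing loci as squared distance (so all genotyped X
chromosomes are usable); diploid mode treats individuals as units with the
count of loci at differing allele dosage, phase ignored. For diploid X
analyses, `makePseudofemales()` pairs random same-population male
haplotypes into synthetic diploids (floor(n/2) per population, leftover male
dropped, fully seeded). Loci are filtered to those polymorphic within the
analyzed group, so different groupings legitimately use different locus
counts (`n_loci_used`). Hierarchy is copies/individuals within populations
within continental regions; with one region the analysis is two-level, and
a grouping with one population per region has a structurally zero
among-population stratum. Negative variance components are truncated to
zero before conversion to percentages. Both distances are additive over
loci, so all sums of squares are precomputed per locus and the bootstrap
(default B = 20,000, reducible) simply resamples locus indices; confidence
intervals are percentile 2.5/97.5. Bootstrapping loci rather than
individuals reflects that the uncertainty being summarized is over markers;
the alternative is deliberately not offered as a default.

# Selection scans

**EHH.** For a core marker and a haplotype class (derived carriers,
ancestral carriers, or everyone), EHH at flanking marker distance $d$ is
$\sum_h n_h(n_h-1) / (n_c(n_c-1))$ over the classes of haplotypes identical
from the core through $d$, per direction; it is 1 at the core and
non-increasing outward.

**iHH/iHS.** iHH is the trapezoidal integral of EHH over genetic distance
(cM from the map, else 1 cM/Mb) out to the first marker where EHH falls
below the cutoff (0.1 by default), including that final segment, summed
over directions; if the cutoff is never reached before the last marker on
either side the integral is undefined — cores near chromosome ends get no
score. Raw iHS is $\ln(\mathrm{iHH}_{anc}/\mathrm{iHH}_{der})$. Flagging
follows the absolute-deviation rule: markers are grouped by observed
derived-allele count and flagged when $|iHS - \overline{iHS}_{group}| \ge 2$.
This is deliberately *not* the usual SD-standardization; an optional 2%
frequency-bin mode serves sparse panels, and is what the packaged synthetic
checks use, since exact-count groups are tiny at simulation sample sizes.

**XP-EHH.** Unpartitioned EHH is integrated per population with the same
cutoff and boundary rules (each population stops at its own cutoff crossing
— a simplification of the original two-population stopping rule, chosen to
share the iHH machinery since the source analysis does not document its
rule), then $\ln(\mathrm{iHH}_A/\mathrm{iHH}_B)$ is standardized
chromosome-wide to mean 0, variance 1.

**Window aggregation.** `regionizeScores()` turns per-marker scores into
one score per fixed-width window: the flagged/scored ratio for iHS, the
plain mean for imported score tracks (e.g. composite-likelihood-ratio
values, which enter as a generic chrom/pos/score TSV; empty windows stay
missing), and the mean with empty windows set to zero for XP-EHH (the
zero-fill rule is specific to XP-EHH). `topRegions()` ranks windows (ties
to the smaller start), and `empiricalWindowTest()` compares a run of k
consecutive scores against every other k-run (sliding, overlapping,
excluding the tested run), flagging the run as elevated above the 95th
percentile. `hapHetRatio()` gives the 5-SNP haplotype heterozygosity ratio
track between two populations, using the plug-in estimator $1-\sum p_h^2$
(an $n/(n-1)$ correction is available but off by default since the ratio is
the quantity of interest).

# The synthetic-data generator

`simulateDataset()` produces matched X and autosomal panels under a
sex-structured island model at equilibrium. Per locus, an ancestral
frequency $p \sim \mathrm{Uniform}(0.05, 0.95)$ (avoiding near-fixed loci)
and per-population frequencies from the Balding–Nichols distribution
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, with $F = F_A$ for autosomes and
$F = $ `expectedXDifferentiation`$(F_A, N_f/N, m_f/m)$ for the X; $F \to 0$
degenerates to $q = p$. Equilibrium sampling (rather than forward
simulation) matches the island-model assumption, is fast, and makes
parameter recovery well-posed.

Haplotype structure comes from founder copying: each population has
`founder_count` founder haplotypes; at each site exactly
$\mathrm{round}(Kq)$ founders carry allele 1, so the founder-pool frequency
matches the drawn frequency to within $1/2K$ and genome-wide Hudson Fst
recovers the generative $F$ (checked to ±0.01 at 10,000 loci). Haplotypes
copy founders, switching at exponential distances (`switch_rate`, default
1e-5 /bp, 100-kb mean segments) and flipping alleles at `flip_rate`
(default 0.002 /site). Defaults describe the packaged study conditions: 2
regions x 3 populations, 2,000 autosomal + 500 X loci at 20-kb spacing,
$F_A = 0.10$, balanced demography, 25 females + 25 males per population, 16
founders, outgroup pair fixed ancestral with probability 0.8, gene
intervals (40-kb) covering about 32% of markers. A `region_fst_share`
option splits differentiation hierarchically for region-level AMOVA
experiments; the default 0 is the exchangeable island model.

`plantSweep()` adds a sweep signature: a fraction of one population's
haplotypes (default 0.8) receive the derived allele at a focal marker and
copy one of `carrier_founders` (default 2) template haplotypes over a tract
around the core — per side, `min_tract_bp` (50 kb) plus an exponential
distance at `tract_rate` (5e-6 /bp, 200-kb mean), reverting to their own
background outside. Local tract regeneration, rather than resampling whole
chromosomes from few founders, is what keeps the signature localized the
way recombination onto the background does in a real sweep; whole-chromosome
regeneration would elevate EHH everywhere and make the sweep undetectable
against itself.

What the generator does **not** emulate: realistic recombination-map
heterogeneity, mutation-model detail, ascertainment of array SNPs, linkage
between the frequency draw and the haplotype process beyond the founder
calibration, admixture, or selection dynamics (sweeps are planted, not
evolved). Passing tests on this generator show the statistics behave as
designed under the island model; they do not certify performance on real
HGDP-like data.

# Numerical choices and degenerate inputs

* Strict inequalities for all "high" thresholds; values exactly at a
  threshold are not high.
* Missing genotypes are excluded site-wise from frequency denominators; a
  site with zero non-missing copies is dropped from scans. In EHH walks a
  missing allele breaks haplotype identity (conservative).
* Hudson per-site values are clipped to [0,1]; sites monomorphic in both
  populations are undefined.
* Window ties in `topRegions()` resolve to the smaller start coordinate;
  the empirical percentile counts strictly smaller means.
* The grid scan caches by the combined term rounded to 12 significant
  digits, which also guarantees bit-identical equal-c cells despite
  floating-point axis arithmetic.
* Heterozygous unphased genotypes are errors at load; homozygous unphased
  genotypes are accepted (phase is unambiguous). Heterozygous male X
  genotypes are errors naming sample and site; haploid and
  homozygous-diploid male encodings are normalized to one haplotype.

# Problem sizes used in the packaged checks

The validation suite and the acceptance script run: parameter recovery on
20 replicates of 5,000 autosomal + 2,000 X loci (2 populations, 25 + 25
diploids each); AMOVA direction on 20 replicates of 400 + 400 loci (3
populations); sweep detection on 20 replicates of 2,000 X loci spanning 100
400-kb windows, with the sweep planted at the centre of one window so its
signal is attributed to a single region. These sizes were chosen as the
smallest at which the Monte-Carlo rates are stable.

# Known limitations

* The TA/EX map is a linearized equilibrium relation; bottlenecks and
  non-equilibrium demography shift the surfaces in ways the grid cannot
  separate from sex bias.
* The iHS flag rule follows the absolute-deviation variant; its scores are
  not comparable to SD-standardized iHS from other software.
* Diploid AMOVA ignores phase by construction; the pseudofemale pairing
  adds pairing noise that the seed controls but does not remove.
* The pipeline assumes biallelic, phased input; multi-allelic sites and
  pseudoautosomal regions are out of scope (the PAR is handled by excluding
  it from the span).
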