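---
title: "Auditing admixed cohorts: models, parameters and design choices"
author: "admixaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing admixed cohorts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

admixaudit asks a methodological question about population-genomic cohorts
from underrepresented, admixed populations: when sample sizes per community
are wildly unequal and the genotyping content was ascertained on a European
discovery panel, how much do the standard analyses — PCA, allele-frequency
spectra, FST, polygenic scores — distort, and how can the distortion be
measured and corrected? Because cohorts of this kind are controlled-access,
the package pairs every audit with a seeded generator that reproduces the
relevant statistical structure, so every claim the toolkit makes can be
checked against simulated ground truth.

## The synthetic cohort generator

The generator is the Balding–Nichols model with an explicit admixture layer.

**Ancestral frequencies.** Each variant receives a base frequency $p_0$ from
a site-frequency spectrum, by default Beta(0.2, 0.2) truncated to
$[0.001, 0.999]$. This choice is deliberate: the U-shape concentrates mass
near 0 and 1, giving the excess of rare variants that array ascertainment
acts on, without requiring coalescent machinery. It does not reproduce the
$1/x$ spectrum of real sequencing data — real WGS call sets carry far more
singletons — so absolute capture rates in simulation are higher than those
reported on real data; only the *direction and mechanism* of ascertainment
bias transfer. Per ancestry $k$ with drift parameter $F_k \in (0,1)$, the
population frequency is drawn as

$$p_k \sim \mathrm{Beta}\!\left(p_0 \tfrac{1-F_k}{F_k},\; (1-p_0) \tfrac{1-F_k}{F_k}\right),$$

with mean $p_0$ and variance $F_k\,p_0(1-p_0)$; the default $F_k = 0.1$ is a
continental-scale divergence.

**Admixture.** Each individual in a population with admixture proportions
$q$ draws, independently per locus and per allele copy, an ancestry from $q$
and then an allele Bernoulli($p_{k,\ell}$). The haploid-level draw (rather
than fixing one ancestry per individual per locus pair) is the simplest
model under which population allele frequencies are exactly the mixture
$\sum_k q_k p_k$; its realized per-individual ancestry fractions are stored
as ground truth. Loci are independent: there is no linkage disequilibrium,
no phasing, and no recombination, which is why LD-dependent analyses (tagging,
imputation) are out of scope.

**Default configuration.** 26 populations, sizes 80 down to 10 (8:1
imbalance; 15 populations at or above 30 and 11 below), Native American
admixture declining from 0.95 to 0.60 along the list, European up to ~0.35,
African up to 0.10, and $m = 50{,}000$ variants. These are the study
conditions every downstream audit assumes; tests that need a faster cohort
scale the population sizes and variant count down, never the structure.

**Array ascertainment.** An `array_design` names a discovery ancestry
(default EUR), a discovery haplotype count (default 120) and a MAF cutoff
(default 0.05). The discovery sample is drawn as haploid genomes from the
discovery ancestry's panel frequencies — the cohort itself contains no
unadmixed European individuals, and a pure-ancestry discovery panel is the
cleanest model of an externally designed array. Variants polymorphic in the
discovery sample with discovery MAF at or above the cutoff form the panel.
Both knobs are free parameters of the emulation; they were not calibrated to
reproduce any particular published capture percentage.

**Error injection.** Artifact variants are modeled at the *site* level: a
fraction of variants has its ref/alt substitution class redrawn so the
artifact class has expected Ts/Tv $R_\mathrm{err}$ (default 0.4, the ratio
of a uniformly random substitution being 0.5 and empirical artifact classes
being transversion-heavy). Genotype-level error (miscalls) is limited to
i.i.d. missingness, because the downstream error bound is a site-class
argument, not a genotype-quality one.

## Quality control

Per-variant call rate, MAF, heterozygosity and the Levene–Haldane exact HWE
test, with defaults call rate $\ge 0.95$, MAF $\ge 0.01$, HWE $p \ge
10^{-6}$. The HWE p-value is the conventional two-sided exact conditional
test — the sum of probabilities of heterozygote counts no more probable than
the observed one — without mid-p correction; monomorphic variants return
$p = 1$ since no deviation is expressible. The pmf is evaluated by a ratio
recurrence, and the test suite checks it against an independent
log-factorial full enumeration for every table up to 200 alleles.

Relatedness uses the classic method-of-moments IBD decomposition from IBS
sharing with frequencies estimated from the cohort; $\hat\pi = P(\mathrm{IBD}{=}2)
+ P(\mathrm{IBD}{=}1)/2$, and pruning removes the lower-call-rate member of
each pair above the threshold (ties to the lexicographically smaller ID, so
pruning is deterministic and idempotent). The default threshold 0.185 is the
conventional midpoint between second- and third-degree relatives; no
published threshold was available to calibrate retained-sample counts
against, so the default is a convention, not a fit.

## Ascertainment-bias audit

`capture_rate` matches variants across platforms by (chrom, pos, sorted
alleles) — IDs are ignored because rsID vocabularies differ across
platforms, and allele sorting makes the key orientation-free. Matching by
position+alleles rather than position alone is the stricter of the two
readings and the one implemented. `maf_spectrum_distortion` bins each
platform's polymorphic variants by its own MAF, with default edges
$\{0, 0.005, 0.01, 0.05, 0.10, 0.5\}$; the outer cutpoints 0.005 and 0.10
define the rare and common bins, the interior ones are conventional. The
distortion per bin is (array fraction − WGS fraction) × 100 percentage
points, computed over each platform's own variant list — the only
convention under which per-bin percentage-point differences are meaningful —
so distortions always sum to zero. Monomorphic variants are excluded from
binning and reported separately.

In the bundled pipeline the comparison is made against the *pre-QC* variant
set: the rare variants a MAF filter removes are exactly the ones
ascertainment depletes, and filtering first would empty the rare bins on
both sides.

## Ts/Tv validation and the mixture error bound

Transitions are A↔G and C↔T; everything else single-base is a transversion;
multi-base alleles are "other". Multiallelic records are decomposed per alt
allele for counting but count once toward the multiallelic rate. The
observed genome-wide ratio of a high-quality human call set falls in
2.0–2.2, exposed as a configurable pass band.

The conservative error bound treats the observed call set as a two-component
mixture of true variation (ratio $R_\mathrm{exp}$, default 2.1) and
artifacts (ratio $R_\mathrm{err}$, default 0.4). Two modes are shipped
because the mixture can be written on two scales:

* **ratio-linear** (default): $e = (R_\mathrm{exp} - R_\mathrm{obs}) /
  (R_\mathrm{exp} - R_\mathrm{err})$.
* **proportion-mixture**: mixing on the transition *proportion*
  $p = R/(1+R)$, the scale on which site classes actually combine, solving
  $p_\mathrm{obs} = (1-e)p_\mathrm{exp} + e\,p_\mathrm{err}$.

The proportion-mixture is the statistically principled form; the
ratio-linear form is the default because it is the transparent linear
interpolation practitioners write down first, and recovery experiments
(injected artifact fractions 0.001–0.02 at $10^6$ sites) show both modes
recover injected fractions within 20% relative error. Observed ratios
outside $(R_\mathrm{err}, R_\mathrm{exp})$ clip $e$ to $[0,1]$ rather than
extrapolate. On small post-QC panels (a few thousand sites) the sampling
noise of $R_\mathrm{obs}$ dominates small $e$; the bound is meaningful at
the $10^5$–$10^6$-site scale it is designed for.

## Sample-size-corrected structure

**Weighted PCA.** Sample $i$ in population $g(i)$ of size $n_{g(i)}$ gets
weight $w_i \propto 1/n_{g(i)}$, normalized to sum 1, so every population
contributes equal total weight. The weights enter *both* the allele
frequency estimate $\hat p_j = \sum_i w_i g_{ij} / (2\sum_i w_i)$ and the
covariance $\sum_i w_i x_i x_i^\top$: weighting only the covariance would
leave the centering dominated by large groups and defeat the correction.
Genotypes are centered at $2\hat p$, scaled by $\sqrt{2\hat p(1-\hat p)}$,
and missing values mean-imputed at $2\hat p$ (standard PCA practice, and it
keeps the weighted metric coherent). The decomposition runs on the
$n \times n$ inner-product matrix; component signs are fixed by making each
component's largest-magnitude variant loading positive. Uniform weights
reproduce standard PCA exactly, which the tests verify against an
independent dense eigendecomposition.

**Stratified bootstrap.** Individuals are resampled with replacement within
each population (default $B = 100$); each replicate is re-decomposed and its
coordinates for the resampled individuals Procrustes-aligned (rotation,
reflection, translation *and scaling* — eigenvalue scale varies between
resamples and only shape stability is claimed) to the full-data solution via
`vegan::procrustes`. Reported: mean Procrustes RMSD, per-sample coordinate
standard deviation, and per population the fraction of replicates whose
nearest-centroid neighbor population is unchanged. "Cluster consistency" has
no canonical definition; nearest-centroid agreement was chosen as the
operationalization because it is parameter-free and directly interpretable.
It is only informative when pairwise population distances are distinct —
with mutually equidistant groups the nearest neighbor is a coin flip — which
the test fixtures are built to respect. Populations of size 1 resample as
themselves and are flagged: they contribute no within-group variance.

**Hudson FST.** Per variant, numerator $(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1}
- \frac{p_2(1-p_2)}{n_2-1}$ (allele counts $n$), denominator
$p_1(1-p_2) + p_2(1-p_1)$; the mean is the ratio of summed numerators to
summed denominators, the standard recommendation for combining per-site
estimates, and negative per-variant values are retained. Variants
monomorphic for the same allele in both populations are excluded (0/0) and
counted. Two populations drifted by $F$ from a shared ancestor give mean
FST $\approx F$, which the suite verifies within 15% at $n = 100$,
$m = 10^4$.

**Unweighted GRS.** The score is the plain count of risk alleles across the
matched risk-variant table; missing genotypes contribute the sample's
population expected dosage $2\hat p_\mathrm{pop}$ so that missingness does
not deflate scores differentially across populations. Risk variants absent
from the cohort are reported, never silently dropped. Population score
distributions are compared with a Kruskal–Wallis rank test.

## Pipeline, determinism and problem sizes

`run_pipeline` executes simulate → qc → ascertain → validate → structure
(any subset in that order) under one configuration; every stochastic stage
derives its seed from the global seed plus the stage name, so identical
configurations produce byte-identical reports, which the tests assert by
re-running the bundled demo. Reports are written atomically (temp file, then
rename). The bundled demo uses $m = 4{,}000$ variants and half-scale
population sizes (total $n = 468$, ratio still 8:1) so a full run takes
seconds; the acceptance-style checks run the ascertainment audit at the full
default scale ($m = 50{,}000$, $n = 935$) and the error-recovery experiment
at $10^6$ sites. These sizes are the package's chosen compromise between
statistical resolution and a test suite that runs in minutes.

## What passing tests do and do not show

The generator reproduces: three-way admixture with a dominant Native
component, unequal sizes up to 8:1, a rare-variant-heavy spectrum, a
European-ascertained array subset, i.i.d. missingness, and site-class
artifacts. It does not reproduce: linkage disequilibrium, realistic
singleton load, phased haplotypes, indels/SVs, batch or platform genotype
error structure, or cross-cohort frequency incomparability (real array and
WGS cohorts with no overlapping samples differ by more than ascertainment).
Passing tests therefore demonstrate that the *methods* behave as specified
under their assumptions — not that any particular published figure from
real, controlled-access data would be reproduced.
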