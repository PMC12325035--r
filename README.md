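# admixaudit

Auditing tools for population-genomic cohorts from admixed, underrepresented
populations — the setting where a study has recruited dozens of small
communities with wildly unequal sample sizes, genotyped part of the cohort
on a European-designed SNP array and part by whole-genome sequencing, and
needs to know how much its population-structure and allele-frequency results
can be trusted.

The package implements, and stress-tests against a seeded simulator:

* **A synthetic admixed-cohort generator.** Balding–Nichols ancestral
  frequencies (population frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F) around an
  ancestral frequency p with drift F), a per-allele-copy admixture draw over
  three ancestries (Native American / European / African), unequal
  population sizes up to 8:1, array ascertainment against a single-ancestry
  discovery panel, and site-class artifact injection — with ground truth
  recorded, and VCF v4.2 / transposed-text / TSV round-trip I/O.
* **QC**: per-variant call rate, MAF, heterozygosity, the Levene–Haldane
  exact Hardy–Weinberg test, method-of-moments pi-hat with IBD pruning,
  sample-size audits (30- and 10-sample thresholds, max:min ratio) and
  participant-characteristics tables.
* **Ascertainment bias**: capture rate of WGS variants on an array
  (matched by chrom/pos/sorted alleles), per-chromosome capture, and
  MAF-spectrum distortion in percentage points per frequency bin.
* **Variant validation**: Ts/Tv ratio with a 2.0–2.2 pass band, per-sample
  variant burden, multiallelic rate, and a conservative two-component Ts/Tv
  mixture bound on the artifact fraction,
  e = (R_exp − R_obs) / (R_exp − R_err).
* **Structure**: PCA with samples weighted inversely to their population's
  size (weights enter both the frequency estimate and the covariance),
  stratified bootstrap stability with Procrustes alignment, Hudson FST
  (ratio-of-averages), and unweighted polygenic risk scores with
  population-expected-dosage imputation.

See the vignette (`vignettes/cohort-audit-methods.Rmd`) for the models,
parameter defaults and design rationale.

## Worked example

```r
library(admixaudit)

panel <- draw_ancestral_frequencies(m = 20000, seed = 1)
co <- simulate_admixed_cohort(panel, default_population_specs(scale = 0.5),
                              seed = 1)
co
#> <cohort> 468 samples x 20000 variants
#>   populations: 26
#>   missingness: 0.0000
#>   generator truth attached

sample_size_audit(co$samples)
#> <sample-size audit> 26 populations
#>   below 30 samples: 21 (81%)
#>   below 10 samples: 7 (27%)
#>   max:min size ratio 8.0:1

arr <- ascertain_array_panel(co, array_design("EUR", 120, 0.05), seed = 1)
maf_spectrum_distortion(co, arr)
#> <ascertainment spectrum> capture rate 37.8%
#>   rare bin (MAF < 0.005): -11.6 pp
#>   common bin (MAF > 0.1): +22.8 pp
#>           bin wgs_fraction array_fraction distortion_pp
#>     (0,0.005]       0.1220        0.00595       -11.609
#>  (0.005,0.01]       0.0634        0.01666        -4.671
#>   (0.01,0.05]       0.1908        0.12750        -6.329
#>    (0.05,0.1]       0.1168        0.11493        -0.183
#>     (0.1,0.5]       0.5070        0.73496        22.793

tstv_model(R_obs = 2.09)
#> <Ts/Tv mixture error model> mode=ratio-linear
#>   R_obs=2.09  R_exp=2.1  R_err=0.4
#>   artifact fraction <= 0.59% (high-confidence 99%)

weighted_pca(co, k = 2)
#> <weighted PCA> 468 samples, 2 components (inverse-group-size weights)
#>   variance explained: PC1 0.8%, PC2 0.8%
```

Reading the output: the half-scale default cohort keeps the 8:1 size
imbalance; ascertaining its variants on a 120-haplotype European discovery
panel at MAF ≥ 0.05 captures 37.8% of them, depleting the rare bin by 11.6
percentage points and enriching the common bin by 22.8 (signed distortions
always sum to zero); an observed Ts/Tv of 2.09 against an expected 2.1 for
true variation and 0.4 for artifacts bounds the artifact fraction at 0.59%.

An end-to-end seeded demo (simulate → QC → ascertainment audit → validation
→ structure, with byte-reproducible reports) runs via the bundled
configuration:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "admixaudit"))
run_pipeline(cfg)
```

or from the shell through the thin wrapper
`inst/scripts/admixaudit.R run --config <yaml> [--seed N] [--out DIR]`.

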