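# defcnv

Gene-focused copy number variation (CNV) analysis for multicopy gene
families — built around the bovine β-defensins, whose near-identical
paralogues defeat locus-by-locus genotyping — from short-read
whole-genome sequencing depth and droplet digital PCR (ddPCR), with a
seeded synthetic-cohort generator providing ground truth for every
stage.

It is aimed at researchers quantifying CNV of a known gene panel across
a cohort (population genetics of gene families, fertility/immunity
candidate genes) who need reference-gene-normalized copy numbers,
deletion/duplication calls, evidence for shared copy-number-variable
segments, wet-lab ddPCR validation, and copy-number–expression (gene
dosage) correlation — as one auditable pipeline.

## The model

Paralogous regions that short reads cross-map among are pooled into an
**assay group** with expected diploid copy number *E* = 2 ×
(assembly copies); in the packaged catalogue all groups expect CN 2
except the three-copy *DEFB103* group, which expects CN 6. For sample
*s*, group *g* and two-copy reference gene *R* (*TP53*):

    CN̂(s,g) = E_g · [c(s,g)/c(s,R)] / mean_s [c(s,g)/c(s,R)]

The reference ratio removes per-sample depth, the cohort mean removes
per-gene constants, so the cohort mean estimate equals *E_g* exactly.
Calls use one band rule, estimate < *E*(1 − 0.25) → deletion and
> *E*(1 + 0.25) → duplication, reproducing the conventional 1.5/2.5
bounds at *E* = 2 and 4.5/7.5 at *E* = 6. Genes on one
copy-number-variable segment are detected as connected components of
the pair graph with copy-number correlation r ≥ 0.9 across
individuals. ddPCR wells are quantified by Poisson partition
statistics, λ = −ln(1 − positive fraction), and CN = 2 λ_target/λ_ref.
Dosage effects are screened by correlating per-gene CN with expression
(TPM) across matched samples. Full derivations, assumptions and
numerical choices are in `vignettes/defcnv-methods.Rmd`.

## Worked example

A 100-animal cohort simulated at 30× under the default study structure
(5% deletion/duplication alleles, multi-allelic *DEFB103*, a shared
cluster-C segment), then analysed end to end:

```r
library(defcnv)
catalogue <- load_catalogue(system.file("extdata",
  "bdefensin_catalogue.tsv", package = "defcnv"))
cohort <- simulate_cohort(cohort_config(n_samples = 100, seed = 17))

cn    <- estimate_copy_number(cohort$counts, catalogue)
calls <- call_cnv(cn)
table(calls$call)
#>    deletion duplication      normal
#>         545         543        4212

summ <- summarize_cohort(calls, breed = cohort$breed)
summ$gene_ranges[summ$gene_ranges$assay_group %in%
                   c("DEFB103", "DEFB126", "DEFB402"), ]
#>    assay_group min_estimate max_estimate n_deletion n_duplication
#> 4      DEFB103    1.6680069    13.461478         25            25
#> 30     DEFB126    0.9647039     3.137371          9             6
#> 43     DEFB402    0.9585861     3.106570         11             6
```

Most genes range over roughly 1–3 copies (heterozygote deletions and
duplications), while the multi-allelic *DEFB103* group spans 1.7–13.5
against its expected 6. Covariation analysis recovers the planted
segment — and flags that two of its members are overlapping
annotations, so part of that signal is shared reads rather than
biology:

```r
corr   <- cn_correlation(cn)
blocks <- flag_overlap_artifacts(
  find_blocks(find_covarying_pairs(corr, 0.9), corr), catalogue)
blocks[, c("members", "min_r", "overlap_artifact")]
#>                               members     min_r overlap_artifact
#> 1 DEFB113,DEFB110-1,DEFB110-2,DEFB112 0.9891424             TRUE
```

ddPCR wells from the same individuals validate the sequencing
estimates, and the dosage screen ranks the genes whose expression
tracks copy number (the simulator plants positive effects on *DEFB10*
and *DEFB1-1*, negative on *DEFB127* and *DEFB103*, each explaining
~10% of expression variance):

```r
dd   <- classify_ddpcr(ddpcr_copy_number(cohort$wells), catalogue)
conc <- ddpcr_concordance(cn, dd)
#> ddPCR vs WGS: r = 0.987, bias = -0.001, call agreement = 0.997

dosage <- dosage_correlation(cn, cohort$expression)
head(dosage[, c("gene", "r", "r_squared", "slope_sign", "p_value")], 4)
#>         gene      r r_squared slope_sign  p_value
#> 41    DEFB10  0.331    0.1094          1 0.000778
#> 53   DEFB103 -0.312    0.0974         -1 0.001568
#> 19  DEFB122A  0.276    0.0764          1 0.005382
#> 4  DEFB132-1 -0.231    0.0534         -1 0.020759
```

The r² values sit near the planted 0.10 for the true dosage genes;
*DEFB122A* and *DEFB132-1* are planted nulls that reach nominal
significance — exactly the false-positive behaviour a nominal-p screen
at n = 100 should show, and why the table carries a BH-adjusted column
too. `run_pipeline(list(simulate = list(n_samples = 100, seed = 17)),
"out/")` performs the same analysis as one call, writing each stage's
TSV plus a `manifest.json` recording versions, parameters, timings and
output digests.

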