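# scnet — structural covariance networks of subcortical volumes

`scnet` is an R package for analysing cohorts in which subjects with
subjective cognitive decline (SCD) are subgrouped by spatial-navigation
performance and compared — against normal controls (NC) and mild cognitive
impairment (MCI) patients — on subcortical volumetry, group-level
structural covariance networks, and longitudinal conversion to MCI. It is
aimed at neuroimaging researchers who have subject-level ROI volume tables
(e.g. FreeSurfer subcortical/hippocampal-subfield output and basal
forebrain subfield volumes) plus neuropsychological and navigation scores,
and who want the full inference chain behind such studies in tested,
scriptable form.

## What it computes

**Subgrouping.** SCD subjects are split at the median of their mean
navigation distance error (8 egocentric + 8 allocentric trials; lower is
better) into good (`G-SCD`) and bad (`B-SCD`) halves; memory, language or
executive composites can be used instead.

**Volumetric statistics.** One-way ANOVA and Pearson chi-square for
demographics; one-way ANCOVA for ROI volumes controlling for sex, age,
education and total intracranial volume, with the group F from model
comparison

    F = ((SSE_reduced − SSE_full) / (k−1)) / MSE_full,

LSD post hoc contrasts of adjusted means, Benjamini–Hochberg FDR across
ROIs, and covariate-adjusted partial correlations
`r = cor(resid(x ~ Z), resid(y ~ Z))`.

**Covariance networks.** Per group, the 5 basal-forebrain and 12
right-hippocampal subfields form a 17-node network with edges
`R_ij = cor(vol_i, vol_j)` across subjects; negatives are zeroed and the
network binarized at sparsities 18%–50% (step 1%), keeping the
`k = floor(s·N(N−1)/2)` strongest edges. Global metrics Cp, Lp, Eglobal,
Elocal and their degree-preserving-null normalizations

    Gamma = Cp / ⟨Cp_random⟩,  Lambda = Lp / ⟨Lp_random⟩,  Sigma = Gamma / Lambda

(plus nodal efficiency, betweenness, degree) are integrated over the grid
into AUC summaries (aCp, aLambda, …) and compared between groups by a
permutation test that re-runs the entire chain per relabelling, with
two-tailed p `(1 + #{|Δperm| ≥ |Δobs|})/(1 + n_perm)` and FDR across nodes
for nodal metrics.

**Follow-up.** Fisher's exact test (two-tailed, sum-of-small-probabilities
rule) on conversion counts between the SCD subgroups.

Because such MRI cohorts are not publicly sharable, the package includes a
synthetic cohort generator (`cohort_spec()` / `generate_cohort()`) whose
defaults reproduce the reference study's group-level summaries, so the
whole pipeline runs and is tested without any private data.

## Worked example

```r
library(scnet)

cohort <- generate_cohort(cohort_spec(seed = 1))
table(cohort$group)
#>    NC G-SCD B-SCD   MCI
#>    77    40    40    23

# covariate-adjusted group effect on basal forebrain volume
anc <- ancova_group_effect(cohort$`Basal forebrain`, cohort$group,
                           cohort[, c("sex", "age", "education", "tiv")])
anc
#> One-way ANCOVA (group effect)
#>   F = 3.4934, df = 3, 172, p = 0.01692
round(anc$adjusted_means, 2)
#>     NC  G-SCD  B-SCD    MCI
#> 538.79 542.62 527.23 508.71

# network AUC permutation test, G-SCD vs B-SCD
cfg <- analysis_config(n_perm = 500, n_random = 20, seed = 1)
permutation_test_auc(cohort, c("G-SCD", "B-SCD"), config = cfg)
#>    metric auc_A auc_B     diff     p n_perm
#>  1     Cp 0.150 0.127  0.02296 0.305    500
#>  2     Lp 0.580 0.604 -0.02389 0.453    500
#>  ...
#>  6 Lambda 0.328 0.330 -0.00209 0.788    500

# follow-up conversion
fu <- compare_followup(cohort, c("G-SCD", "B-SCD"))
fu[fu$variable == "Outcome (converters/nonconverters)", c("G-SCD", "B-SCD", "p")]
#>   G-SCD B-SCD      p
#>    0/16  7/17 0.0295
```

The ANCOVA here detects the generator's built-in basal-forebrain deficit
of the B-SCD/MCI groups (adjusted means decrease from G-SCD to MCI); the
network AUCs are near-null because the default generator gives every group
the same covariance structure, and the synthetic follow-up Fisher p
reflects conversion probabilities of 0 vs 4/19.

A full run — demographics table, three volumetric tables, partial
correlations, per-group networks with top-25% edge lists, permutation
inference for all group pairs, and the follow-up table, written as CSVs
plus a JSON run log — is one call:

```r
run_pipeline(analysis_config(seed = 1), out_dir = "results")
```

or, from a shell, `Rscript inst/scripts/scnet_pipeline.R --out-dir results
--seed 1` (exit codes: 0 ok, 2 validation error, 3 stage failure).

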