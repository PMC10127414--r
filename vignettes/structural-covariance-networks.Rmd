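---
title: "Subcortical structural covariance networks and navigation-based subgrouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subcortical structural covariance networks and navigation-based subgrouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Subjective cognitive decline (SCD) — self-reported memory worsening without
measurable deficits — is a heterogeneous condition: only a fraction of SCD
individuals later progress to mild cognitive impairment (MCI). One candidate
marker for separating higher-risk from lower-risk SCD is spatial-navigation
performance, measured as the mean distance error over repeated egocentric
and allocentric navigation trials (8 of each; lower error is better).

`scnet` implements the complete statistical workflow for that design:

1. **Subgrouping.** SCD subjects are split symmetrically at the median of
   their mean navigation distance error into a good-navigation half
   (`G-SCD`) and a bad-navigation half (`B-SCD`); the split can instead use
   a memory, language or executive composite for sensitivity re-analyses.
2. **Volumetrics.** Volumes of 15 subcortical nuclei, 5 basal-forebrain
   subfields (Ch4p, Ch4a-i, Ch3, NSP, Ch1/2) and 12 right-hippocampal
   subfields are compared across the four groups (`NC`, `G-SCD`, `B-SCD`,
   `MCI`) by one-way ANCOVA controlling for sex, age, education years and
   total intracranial volume (TIV), with LSD post hoc pairwise contrasts and
   Benjamini–Hochberg FDR across the regions of each table.
3. **Covariance networks.** For each group, the 17 basal-forebrain and
   right-hippocampal subfields become nodes of a structural covariance
   network whose edges are inter-subject Pearson correlations of regional
   volumes. Negative correlations are zeroed, and the weighted matrix is
   binarized over a sparsity grid (18%–50% in 1% steps). Global metrics
   (Cp, Lp, Eglobal, Elocal and the small-world ratios Gamma, Lambda,
   Sigma) and nodal metrics (nodal efficiency, betweenness, degree) are
   integrated over the grid into AUC summaries and compared between groups
   with a label-permutation test; nodal p-values are FDR-adjusted across
   the 17 nodes.
4. **Follow-up.** Conversion to MCI among followed subjects is compared
   between the two SCD subgroups with Fisher's exact test, alongside t
   tests on age, education and follow-up interval.

Because MRI-derived cohorts of this kind are not publicly distributable,
the package ships a first-class synthetic cohort generator that reproduces
the group-level statistical structure the analyses assume, so every stage
is exercised end to end by code alone.

## The synthetic cohort generator

`cohort_spec()` collects every generator parameter; `generate_cohort()`
draws the table. Defaults encode the reference cohort's group-level
summaries: group sizes 77/40/40/23; per-group ROI volume means and SDs for
all 32 regions (mm^3); demographic distributions (age, education, sex and
scanner proportions, standardized TIV); standardized navigation error
means/SDs per group (−0.28/0.65, −0.51/0.27, 0.80/0.69, 0.42/1.03); latent
cognitive-domain levels matching the reported composite z-scores; and
follow-up availability (20 of 40 good navigators, 19 of 40 bad navigators)
with conversion probabilities 0 and 4/19.

Choices the reference data do not pin down, fixed once here:

* **Inter-ROI correlation.** No inter-regional correlation matrix is
  reported, so the default is exchangeable: 0.4 between the 17 network
  nodes, 0.2 elsewhere, unit diagonal — plausible positive structural
  covariance that keeps the matrix positive semidefinite. A per-group
  scalar (`covariance_strength`) rescales the off-diagonal via
  `scale_offdiagonal()`.

  One consequence deserves emphasis: because binarization keeps the top-k
  *ranked* sample correlations, uniformly rescaling an **exchangeable**
  correlation matrix changes no true ordering — the thresholded edge
  pattern remains a noise ranking in both groups, and sparsity-thresholded
  topology carries essentially no signal about the scaling (simulations
  confirm near-zero power). Group differences in covariance strength
  become visible to network topology only when the base correlation is
  *structured*; `ring_decay_correlation()` provides such a base (node
  correlations decaying with ring distance), under which scaling by
  1.5 vs 0.5 (mean node correlations ≈ 0.6 vs 0.2) turns the stronger
  group's thresholded network lattice-like and yields a clearly larger
  Lambda — the configuration the power studies use.
* **Raw test scores.** Each cognitive test score is generated as
  `base + slope * latent_domain + noise` on a plausible raw scale, with
  completion-time tests (TMT-A/B) given negative slopes so that higher raw
  scores mean worse performance. Only the latent domain levels are
  calibrated; the raw scales are conventional.
* **Per-trial navigation errors.** A subject-level latent error is drawn
  from the group distribution and 16 trial values add N(0, 0.3) noise, so
  the per-subject mean distance error — the statistic the split uses — is
  well defined.
* **Positivity.** Volumes must be positive; offending subjects are redrawn
  (at most 100 attempts). Defaults place every mean at least ~5 SDs above
  zero, so truncation bias is negligible.
* **Simplification.** The "Basal forebrain" total is generated as its own
  correlated coordinate rather than as the exact sum of its five
  subfields; analyses treat it as a separate ROI, as the summary tables do.

What the generator does **not** emulate: segmentation error, scanner batch
effects, non-normal volume distributions, spatial autocorrelation beyond
the exchangeable block structure, longitudinal trajectories, and any
subject-level coupling between cognition and regional volumes (domain
latents and volumes are drawn independently). Passing calibration and
power tests on these cohorts therefore demonstrates correctness of the
*procedures* under the stated statistical structure, not biological
validity on real data.

## Statistical conventions

* **Composite z-scores** standardize each test over the full analyzed
  sample (mean 0, SD 1, n−1 denominator), flip higher-is-worse tests, and
  average within domain. The navigation composite is the standardized mean
  distance error and is *not* flipped (higher = worse). The reference
  population for standardization is configurable in principle; the whole
  sample is the default because it reproduces the expected sign pattern
  (controls positive, MCI negative).
* **Median split.** Ties at the split boundary are resolved by stable
  input order and reported via a warning; an odd SCD count requires an
  explicit rule (`odd = "good"`/`"bad"`).
* **Chi-square** is Pearson's statistic without continuity correction;
  **Fisher's exact test** uses the sum-of-small-probabilities two-tailed
  rule (all tables with the observed margins whose probability is at most
  that of the observed table, within a relative tolerance of 1e-7), with
  the tail-doubling rule available as an option.
* **ANCOVA** tests the group factor by model comparison:
  `F = ((SSE_reduced − SSE_full)/(k−1)) / MSE_full`. LSD post hoc
  contrasts of covariate-adjusted means are deliberately unadjusted across
  pairs; FDR is applied across the ROIs of a table instead.
* **Partial correlation** correlates covariate residuals and uses
  `t = r sqrt((n−2−k)/(1−r²))`.

## Network construction and metrics

Edges are Pearson correlations by default (Spearman available). Covariate
residualization before correlation is **off** by default — the covariate
adjustment of the volumetric models is not part of the network definition —
but can be switched on for sensitivity analyses; inside permutation tests
the residualization is computed on the pooled two-group sample so permuted
relabellings stay consistent.

Binarization retains the `k = floor(s·N(N−1)/2)` strongest positive edges
at sparsity `s`; `floor` guarantees the nominal sparsity is never
exceeded. Ties at the cutoff are broken by the fixed lexicographic
node-pair order (stable sort), which also makes edge sets nested across
the grid. Zero-weight edges are never retained: the achieved edge count is
recorded and a warning raised when it falls short of `k`.

Metric conventions on binary graphs: nodes of degree < 2 contribute 0 to
Cp and Elocal (mean over all nodes); Lp averages finite shortest-path
lengths only, with the number of unreachable pairs reported — a convention
that matters for permuted or synthetic graphs that disconnect even though
the sparsity lower bound is intended to keep groups connected; Eglobal and
nodal efficiency use `1/∞ = 0`; betweenness is the Brandes accumulation
normalized by `(N−1)(N−2)/2`.

**Random-network normalization.** Gamma and Lambda divide Cp and Lp by
their ensemble means over degree-preserving random networks
(`Sigma = Gamma/Lambda`; Sigma > 1 indicates small-world organization).
Randomization is by Maslov–Sneppen double-edge swaps with a budget of
10 successful swaps per edge and an attempt cap of 100× the budget (a
complete graph, which admits no legal swap, is returned unchanged with a
warning). The ensemble itself is generated as a single swap chain — full
burn-in before the first member, one-tenth of the burn-in between
members — so each member is marginally a fully randomized network while
large permutation runs stay linear in the burn-in rather than in
`n_random` times it. Members of a chain are mutually correlated, which
leaves the ensemble mean unbiased and only modestly increases its Monte
Carlo variance; the calibration suite verifies that a rewired random graph
scores Gamma ≈ Lambda ≈ 1 and that permutation type-I error is nominal
under this scheme. Ensemble means use the mean (not the median), and all
ensemble seeds derive deterministically from the configured master seed.

**AUC and permutation inference.** Metric curves are integrated over the
sparsity grid by the trapezoidal rule (default) or by a values-times-step
sum, exposed as a compatibility switch because network toolboxes differ.
The permutation test pools both groups, reassigns labels preserving group
sizes, and re-runs the whole chain — correlation, zeroing, binarization,
metrics, normalization, AUC — per permutation; with
`reuse_random_ensembles = TRUE` the observed groups' normalization
denominators are reused instead, which keeps the test exact under
exchangeability at lower cost. Two-tailed p-values use the add-one rule
`(1 + #{|Δperm| ≥ |Δobs|})/(1 + n_perm)`, so p is never below
`1/(n_perm+1)`; the two groups are ordered canonically inside the engine,
making the p-value invariant to label order.

## Problem sizes in the test suite

The package's calibration studies run at deliberately chosen desk scales:
permutation type-I error uses 200 null cohorts (40 subjects per group, 17
nodes) with 500 permutations and 10 random networks per sparsity; power
against a covariance difference (distance-decay base scaled to mean node
correlations 0.6 vs 0.2) uses 40 replicate cohorts at the same settings;
ANCOVA recovery uses 200 cohorts
for the one-pooled-SD basal-forebrain deficit and 1000 for null
calibration; metric oracles are checked on 500 random graphs of up to 7
nodes and Fisher's test against full enumeration for all 2×2 tables with
margins ≤ 12. Defaults for real analyses remain 1000 permutations and 100
random networks.

## Known limitations

* Graphs are limited to 64 nodes (bitmask representation) — ample for
  subfield-level node sets, unsuitable for voxel- or parcellation-scale
  networks.
* The permutation engine treats the two-group comparison; omnibus
  multi-group network tests are out of scope.
* Weighted-network metrics, community detection and individual-subject
  covariance networks are not implemented.
* The generator's independence between cognitive latents and volumes means
  brain-behaviour partial correlations are null by construction; the
  correlation stage is therefore validated for calibration, not for
  effect recovery.
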