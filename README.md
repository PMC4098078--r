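# restfc

Seed-based resting-state functional connectivity (rFC) analysis for
block-design fMRI studies, with a median permutation test for group
differences, effect-size gating, behavior–connectivity correlation, and a
synthetic two-group BOLD cohort generator for end-to-end validation.

The package re-implements, as a tested and reusable pipeline, the analysis
used to compare expert and non-expert creative writers at rest: baseline
volumes interspersed in a task block design are selected as the resting
series, confound variance is removed, seed time courses are extracted from
5-mm spheres at ten MNI coordinates of a creative-writing network, and
seed-to-seed Fisher-Z correlations are compared between groups and
correlated with verbal-creativity scores. Because the original participant
data are not publicly deposited, the package ships a synthetic cohort
generator that emulates the study design (n = 20 experts vs 23 non-experts,
TR = 2 s, two runs, 90 retained rest volumes per participant) with planted
group differences and planted behavior couplings, so every stage of the
pipeline is exercisable and its calibration measurable.

## The analysis

For each subject and each pair of seeds *(i, j)*:

1. **Rest extraction.** From each run, the first volumes of every 10-volume
   inter-block rest period are dropped and 8 are retained, plus 5 volumes at
   the end of the run: 45 per run, 90 per subject.
2. **Confound model.** Each channel's variance explained by 30 nuisance
   regressors — 6 motion parameters, their temporal derivatives, 3
   tissue-class mean signals, and the squares of all 15 — is removed by OLS
   on the full continuous run; residuals are band-pass filtered (zero-phase
   order-2 Butterworth, 0.01–0.08 Hz) before rest volumes are extracted.
3. **Seed extraction.** Each seed's gray-matter voxels within the 5-mm
   sphere are reduced to the first eigenvariate (first left singular vector,
   unit variance, sign aligned with the seed mean).
4. **Connectivity.** Pearson correlation *r*(i, j) over the 90 retained
   volumes, Fisher-transformed: *z* = ½ ln((1+r)/(1−r)) = atanh(r). Age and
   sex are partialled out of edge values and behavioral scores.
5. **Group inference.** Per edge, the observed statistic is
   median(z_expert) − median(z_nonexpert). Its null distribution is built
   from 10,000 group-label permutations (one shared permutation set across
   edges). The directional posterior probability must exceed 0.95, the
   back-transformed group median must reach at least a small effect
   (|r| ≥ 0.10) in either group, and the difference must be large
   (Cohen's |d| ≥ 0.80) for an edge to be flagged. Main effects are
   one-sample t-tests with Benjamini–Hochberg FDR across the 45 edges.
6. **Behavior.** Spearman rank correlation of each edge with the verbal
   creativity index (VCI), the consensual creativity rating (CR), and the
   practice index PI = (semester + years of writing) × weekly hours;
   flagged when p < 0.05 (uncorrected) and |rho| ≥ 0.24.

## Worked example

Simulate the default cohort (full block-design runs with motion/tissue
confounds, the planted expert pattern — increased right IPS–right caudate
coupling, decreased interhemispheric area-44 coupling, both targeting
|d| ≈ 1 — and a CR coupling of ρ = −0.62 on left 44–left temporal pole in
experts), then run the whole pipeline:

```r
library(restfc)

run <- run_pipeline(
  simulation_config(mode = "full", rng_seed = 3),
  inference_config(n_permutations = 10000, rng_seed = 7))
print(run)
#> <rfc_edge_test> 45 edges, n = 20 expert / 23 nonexpert, 10000 permutation(s)
#>   flagged group differences: R_IPS--R_CAUD
#>   flagged behavior correlations: 13

dplyr::filter(tidy(run$edge_test), flagged)
#>            edge median_expert median_nonexpert posterior_dir         d
#> 1 R_IPS--R_CAUD     0.2882844       0.06461966     0.9966003 0.9489756
```

Here the planted right IPS–right caudate increase is recovered (expert
median Fisher-Z 0.29 vs 0.06, directional posterior 0.997, d = 0.95); in
this particular cohort the planted area-44 decrease fell just short of the
d ≥ 0.8 gate — single-cohort recovery power at d ≈ 1 is about 50–70% per
edge, which is what the replicate studies below quantify. `tidy()`,
`glance()`, `autoplot()`, and `plot_connectivity_matrix()` /
`plot_behavior_correlations()` give tabular and graphical views of any
result.

Replicate-cohort calibration uses the same machinery:

```r
null_rates <- replicate_study(500, null_simulation_config(),
                              inference_config(n_permutations = 1000))
mean(null_rates$edges$flag_rate)   # false-flag rate of the full gate, ~0.01
```

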