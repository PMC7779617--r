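# epitensor

Feature-tensor classification of directed EEG brain networks, aimed at
screening for epilepsy from *short* (20-second) interictal multichannel
EEG, where waveform-based detection is unreliable. The package is for
researchers in EEG network analysis who want the full pipeline — directed
connectivity, deliberate-attack features, tensor reduction,
cross-validated classification — as composable, tested R functions, plus
a synthetic-data generator that stands in for restricted clinical
recordings.

## The method

For each subject and each canonical rhythm band (β 13–30 Hz, α 8–13 Hz,
θ 4–8 Hz, δ 1–4 Hz):

1. **Transfer entropy** between every ordered channel pair builds a
   weighted digraph per band:

   *T*<sub>Y→X</sub> = Σ p(x₍t+u₎, Xᵈₜ, Yᵐₜ) log₂ [ p(x₍t+u₎ | Xᵈₜ, Yᵐₜ) /
   p(x₍t+u₎ | Xᵈₜ) ],

   estimated by a plug-in histogram with lowest-order embedding
   (d = m = τ = u = 1, 8 bins).
2. **Multi-threshold binarization** converts each weighted digraph into h
   unweighted digraphs (clinical scale: h = 600 thresholds over
   (0, 0.006]).
3. **Edge-removal attack**: nodes are ranked by in-degree (receiving) or
   out-degree (sending); step k deletes all in-edges (resp. out-edges) of
   the k-th ranked node, giving n nested residual networks. The average
   clustering coefficient C and network efficiency N of every residual
   form attack curves — a directed generalisation of node-removal
   deliberate attacks.
4. **Feature tensor**: the curves fill a five-way array
   (threshold × removal step × sub-approach × feature × rhythm), shape
   h × n × 2 × 2 × 4.
5. **Tucker/HOOI** reduces each tensor to a core (default 8 × 6 × 2 × 2
   × 4 → a 768-dimensional vector at clinical scale).
6. **SVM** (linear or fine/medium/coarse Gaussian kernels) evaluated by
   twenty repeats of stratified 10-fold cross-validation; sensitivity =
   TP/(TP+FN), specificity = TN/(TN+FP), accuracy = (TP+TN)/total.

Group-level descriptive networks (edge drawn when the subjects' weight
sample is significantly above a threshold, right-tailed t-test at
P < 0.01) and the undirected node-removal baseline are also provided.

See the vignette (`vignettes/feature-tensor-pipeline.Rmd`) for
conventions, estimator details and design rationale.

## Worked example

Two synthetic cohorts whose directed coupling topologies differ (ring vs
hub), pushed through the entire pipeline at demo scale (8 channels, 30
thresholds, 6 × 4 × 2 × 2 × 4 core):

```r
library(epitensor)

spec <- cohort_spec(subjects_per_group = 20, channels = 8, duration = 20,
                    coupling_A = ring_coupling(8, 0.4),
                    coupling_B = hub_coupling(8, 0.4), seed = 11)
cohort <- synth_cohort(spec)
cohort
#> <cohort> 40 subjects, 8 channels x 5120 samples @ 256 Hz

cfg <- pipeline_config(profile = "demo", seed = 11)
res <- end_to_end(cohort, cfg)
res$report
#> <eval_report> kernel=medium_gaussian, 10-fold x 20 repeats (20+20 subjects)
#>   sensitivity 100.00%  specificity 100.00%  accuracy 100.00%
```

The two topologies differ in graph invariants, so the attack curves
separate the groups completely: all 20 patients-per-fold analogues (group
A) and controls (group B) are correctly identified in every repeat. With
identical coupling in both groups the same pipeline returns chance-level
accuracy (≈ 50 %). The mean Tucker fit over subjects here is ψ ≈ 0.998,
i.e. the 384-entry demo core retains essentially all tensor variance.

Individual stages are exposed as plain functions (`te_matrix()`,
`binarize()`, `edge_removal_sequence()`, `build_feature_tensor()`,
`tucker_hooi()`, `cross_validate()`, …), and a command-line wrapper over
the same functions ships in `inst/cli/epitensor.R`:

```sh
Rscript inst/cli/epitensor.R pipeline --profile demo --run-dir run1 --seed 11
```

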