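---
title: "Directed brain networks, edge-removal attacks and feature tensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed brain networks, edge-removal attacks and feature tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Interictal scalp EEG of epilepsy patients often looks normal over short
windows, which makes waveform-based screening unreliable unless hours of
signal are available. A network view helps: epileptiform activity perturbs
the *directed* information flow between cortical regions, and those
perturbations are visible in 20-second segments. `epitensor` implements a
detection pipeline built on that idea:

1. **Rhythm decomposition.** Each multichannel segment is split into the
   canonical beta (13–30 Hz), alpha (8–13 Hz), theta (4–8 Hz) and delta
   (1–4 Hz) bands.
2. **Directed connectivity.** For every ordered channel pair $(i, j)$ and
   every band, the transfer entropy
   $T_{i \to j} = \sum p(x_{t+u}, X^d_t, Y^m_t)\,
   \log_2 \frac{p(x_{t+u} \mid X^d_t, Y^m_t)}{p(x_{t+u} \mid X^d_t)}$
   quantifies the information channel $i$'s past adds about channel $j$'s
   future beyond $j$'s own past. This yields a weighted digraph per band.
3. **Threshold sweep.** Each weighted digraph is binarized at $h$ equally
   spaced thresholds, because no single cut preserves all structure.
4. **Edge-removal attack.** Each binary digraph is attacked twice: nodes
   are ranked once by in-degree (receiving capability) or out-degree
   (sending capability), and step $k$ deletes all in-edges (resp.
   out-edges) of the $k$-th ranked node, producing $n$ nested residual
   networks that end edgeless. The average clustering coefficient $C$ and
   network efficiency $N$ of every residual form attack curves that are
   far more discriminative than the undirected node-removal baseline.
5. **Feature tensor.** The curves are arranged per subject as a five-way
   tensor of shape $h \times n \times 2 \times 2 \times 4$
   (threshold × removal step × sub-approach × feature × rhythm).
6. **Tucker core + SVM.** Higher-order orthogonal iteration (HOOI)
   extracts a small core tensor, its entries are flattened into a vector,
   and a kernel SVM is evaluated with repeated stratified 10-fold
   cross-validation, reporting sensitivity, specificity and accuracy.

At clinical scale the tensor is $600 \times 16 \times 2 \times 2 \times 4$
(600 thresholds over $(0, 0.006]$, 16 electrodes) and the default core is
$8 \times 6 \times 2 \times 2 \times 4$, i.e. a 768-dimensional feature
vector per subject.

# Graph conventions

* **Directed clustering.** A node's neighbourhood is the union of its
  predecessors and successors, $k_i$ its size; the coefficient is the
  number of directed edges among the neighbours divided by
  $k_i (k_i - 1)$, and nodes with $k_i < 2$ contribute 0. Each directed
  edge among the neighbours is counted once (so a reciprocal pair counts
  twice), which reduces exactly to the familiar undirected formula, with
  its factor 2, on symmetric graphs.
* **Efficiency.** Mean of $1 / \ell_{ij}$ over ordered pairs, with
  unreachable pairs contributing 0 — the standard convention, so
  $N \in [0, 1]$ with $N = 1$ only for a complete digraph.
* **Attack ranking.** The edge-removal order is fixed by the original
  network (the attack is defined by sorting once), while the undirected
  node-removal baseline re-ranks at every step; both behaviours are
  switchable (`rank = "static"|"dynamic"`). Degree ties break by ascending
  node index, making every sequence deterministic and label-stable.

# Estimator choices

The transfer-entropy estimator is a plug-in histogram: each series is
discretised into `n_bins = 8` equal-width bins over its observed range,
and the functional is evaluated as the four-entropy combination
$H(X^d, Y^m) - H(x_+, X^d, Y^m) + H(x_+, X^d) - H(X^d)$, in bits. The
defaults $d = m = \tau = u = 1$ are the lowest-order embedding; on a 20-s
segment at 256 Hz (5120 samples) they keep the largest joint histogram
(512 cells) well populated. Finite samples give the estimator a positive
bias (roughly 0.05–0.08 bits at these settings) and occasionally a tiny
negative value; negatives are clipped to zero and counted. A constant
series collapses to a single bin and yields 0 by construction. For
validation, `te_from_joint()` evaluates the same functional on an *exact*
joint distribution, by direct summation or through the entropy
combination; the two routes agree to numerical precision on arbitrary
joints, and both return exactly 0 on factorized (independent) joints. The
`noisy_copy_pair()` generator provides series whose true transfer entropy
is the closed form $1 - H_b(\varepsilon)$, used to check estimator
consistency. When a recording yields several 20-s segments the per-segment
weight matrices are averaged by default (`segment_aggregate = "concat"`
concatenates instead).

# Rhythm extraction backends

Two backends produce the band-limited signals:

* `"butter"` (default): order-4 Butterworth bandpass applied
  forwards-backwards (zero phase). Measured on white noise, 94–98 % of
  each band's output power lies inside its nominal edges.
* `"wavelet"`: a db4 wavelet-packet decomposition to depth 6, rebuilding
  each band from the terminal nodes whose centre frequency falls inside
  it. At 256 Hz the terminal nodes are 2 Hz wide, so the 13, 8, 4 and 1 Hz
  band edges are only approximated to the nearest node boundary, and the
  db4 filters roll off slowly: in-band output power on white noise is
  0.63–0.81 depending on the band. The backend is retained because
  wavelet-packet banding is common practice in the EEG literature, but the
  bandpass backend is the default precisely because of those leakage
  figures.

Node-to-band assignment uses the node *centre* frequency, which makes the
bands disjoint; assigning by interval overlap would place the 12–14 Hz
node in both alpha and beta. The 50 Hz mains notch is a zero-phase
band-stop (the narrow-band removal the preprocessing requires; spectral
subtraction would also fit and was not chosen). Independent-component
artifact removal is out of scope: `preprocess_subject()` exposes an
`artifact_fun` hook where users can insert their own cleaner, and the
returned log records that the step was skipped otherwise. This is a known
limitation — muscle and ocular artifacts in real recordings pass through
untouched and inflate high-frequency connectivity.

# Group networks and thresholds

The threshold grid is $t_k = k \cdot \text{step}$ for
$k = 1 \dots \lfloor (\text{stop} - \text{start}) / \text{step} \rceil$;
the clinical-scale default (step $10^{-5}$ up to $0.006$) gives exactly
600 thresholds. Binarization is strict ($w > t$), so even $t = 0$ excludes
zero-weight pairs, and edge sets are nested along increasing thresholds.
Per-subject classification tensors always use direct binarization; the
right-tailed one-sample t-test network (edge drawn when the subjects'
weight sample is significantly above the threshold at $P < 0.01$) is a
*descriptive* group-level object. A zero-variance sample has an undefined
t statistic; the edge is then decided by the sign of the mean minus the
threshold. The t-test population is the subjects (one weight per subject
and pair); feeding per-segment weights instead is possible by passing the
per-segment matrices as "subjects".

# Tucker reduction

HOOI starts from the truncated higher-order SVD and alternately replaces
each factor with the leading left singular vectors of the partially
projected tensor, which makes the fit
$\psi = 1 - \lVert Q - \hat Q \rVert^2 / \lVert Q \rVert^2$ non-decreasing
across sweeps; iteration stops when $\psi$ improves by less than $10^{-6}$
or after 50 sweeps (typically 1–3 suffice). Because the factors are
orthonormal, $\psi$ is also $\lVert \text{core} \rVert^2 / \lVert Q
\rVert^2$, which is what the implementation tracks. An alternative
"explained fraction" that mixes squared and unsquared norms,
$1 - (\Gamma(Q)^2 - \Gamma(\Lambda)^2)/\Gamma(Q)$, appears in parts of the
tensor literature; it is dimensionally inconsistent (it is not scale
invariant and can leave $[0,1]$), so the standard fit is the default and
the other form is available as `fraction_explained(..., method =
"ratio")` for auditability. They coincide at $\psi = 1$. The candidate
core search keeps every mode strictly between 1 and 10: modes 3 and 4 stay
at 2, the rhythm mode ranges over 2–4, and the threshold/step modes over
$2 \dots \min(\text{dim}, 9)$, i.e. $3 \cdot \min(h-1, 8) \cdot
\min(n-1, 8)$ candidates. Cores are flattened with the threshold mode
varying slowest and the rhythm mode fastest; an all-zero tensor is defined
as fully explained. The removal-step axis stores the $n$ residual networks
(steps $1 \dots n$); the un-attacked network's features are available as
step 0 of `feature_curves()` but are not a tensor slab.

# Classification

The four kernels follow the fine/medium/coarse Gaussian convention with
kernel scale $\sigma = \sqrt{p}/4$, $\sqrt{p}$, $4\sqrt{p}$ for $p$
features (radial kernel $\exp(-\lVert u - v \rVert^2 / \sigma^2)$), plus a
linear kernel; the box constraint defaults to $C = 1$. Features are
z-scored with statistics fitted on the training folds only — tensor
features mix clustering coefficients and efficiencies whose scales differ,
and the Gaussian kernels are not scale invariant. Folds are stratified, so
the class balance survives in every fold, and the whole evaluation is
deterministic given the seed. Metrics are computed from pooled confusion
counts per repeat and averaged over repeats; the identities
$TP + FN = P$, $TN + FP = N$ and
$\text{accuracy} = (\text{sens} \cdot P + \text{spec} \cdot N)/(P + N)$
hold for every report.

# What the synthetic cohorts emulate — and what they do not

The clinical recordings behind the method are not redistributable, so the
package generates its own study conditions: two groups of 50 subjects, 16
channels, 20 s at 256 Hz. Each subject's channels follow a stable AR(2)
process ($a_1 = 0.5$, $a_2 = -0.2$) with lag-1 cross-channel coupling and
unit Gaussian innovations; the groups differ only through their coupling
topology. This is the simplest generative model with tunable directed
information flow — what matters for testing the pipeline is the
*statistical structure* (directed coupling that differs by group), not
EEG realism. The default topologies are a directed ring (group A) and a
hub that drives all other channels (group B). An earlier, more symmetric
choice — two rings of opposite orientation — is a cautionary example: the
two graphs are isomorphic, every graph-invariant feature coincides, and
the pipeline correctly finds (almost) nothing. Groups must differ in graph
invariants, not merely labelling or orientation, for a topological method
to separate them.

The generator makes no attempt at realistic EEG spectra, volume
conduction, artifacts or non-stationarity. A pipeline that separates these
cohorts is demonstrably able to recover directed topological differences
through the full stack; that is a necessary, not a sufficient, condition
for clinical performance, and the restricted clinical accuracies are not
reproduced here.

Seeding is counter-based: subject $k$ derives its stream from the global
seed and $k$ alone, so any subject is reproducible in isolation and
cohorts are byte-identical across runs.

# Scales used in the shipped checks

The demo profile runs 8 channels, 20 + 20 subjects and $h = 30$
thresholds, with a $6 \times 4 \times 2 \times 2 \times 4$ core — chosen
so a full pipeline evaluation completes in well under a minute on one
core while exercising every stage at meaningful sizes. The demo threshold
grid spans $(0, 0.45]$ bits because synthetic-cohort transfer entropies
range from the estimator bias floor (≈ 0.06 bits) to ≈ 0.4 bits for
coupled pairs; the clinical-scale grid over $(0, 0.006]$ reflects the much
smaller weights of real scalp recordings and remains the `"full"` profile
default. Graph-metric correctness is checked against brute-force oracles
exhaustively over all digraphs on up to 4 nodes and on a large seeded
sample of 5-node digraphs; transfer-entropy identities over random
three-variable binary joints; estimator consistency on $10^5$-sample
noisy-copy pairs.

# Known limitations

* No artifact removal beyond filtering (hook provided).
* Histogram TE needs ample samples per histogram cell; the defaults suit
  the 20-s/256 Hz regime, not much shorter segments or much larger
  embeddings.
* The t-test group network is descriptive; it is not fed to the
  classifier.
* HOOI converges to a local optimum of the fit; with the HOSVD start this
  is standard practice, but global optimality is not guaranteed.
* EDF ingestion is not built in; recordings enter as channels × samples
  matrices (`signal_set`) or via the delimited cohort container.
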