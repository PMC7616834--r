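---
title: "Methods: connectome metrics and peristalsis trace analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome metrics and peristalsis trace analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how each analysis in `vagusnet` is defined, the
assumptions behind it, the choices made where several conventions were
defensible, and what the synthetic-data generator does and does not
emulate.

## Data model

A **skeleton** is a rooted tree of 3D nodes (one per neuron) with
coordinates in nanometres; no unit conversion happens anywhere in the
package, since EM reconstructions are natively in nm. Each skeleton may
carry an `origin_node`, the anatomically designated measurement origin
(e.g. the vagus-nerve-junction entry point, or the CNS-entry node as the
anticipated locus of spike initiation). The origin is an annotation that
must be supplied — it cannot be inferred from geometry, and different
analyses may legitimately use different origins, so it is per-neuron
configurable.

A **connector** is one presynaptic release site. It is polyadic: one
presynaptic (neuron, node) faces zero or more postsynaptic
(neuron, node) partners. A connector with zero partners is a *peripheral
active zone* and must carry the tag of the tissue it abuts (HCG, PVG,
ring gland, midgut, ...). In tables, a connector occupies one row per
postsynaptic partner.

**Counting convention.** A polyadic connector with *k* partners counts as
*k* synaptic pairs everywhere (count matrices, budgets, placement
records). Whether published budgets count connectors or pairs is often
left implicit; the pair convention is the common one in fly EM
connectomics and is used consistently here — results are not comparable
with connector-counting pipelines without re-deriving the counts.

## Input fractions

`input_fractions()` divides each column of the count matrix by the
column total: the target's complete synaptic input budget *as present in
the connector table*, including inputs from neurons outside any
particular analysis set. This full-budget denominator is deliberate: the
alternative (renormalizing within the analyzed subset) silently inflates
fractions when the subset is small. Consequently a fraction column sums
to 1 exactly when every presynaptic partner of that neuron is in the row
index, and to less than 1 otherwise. Zero-input columns are undefined
and stored as `NA` — never as zero, because "no measured inputs" and
"zero share" are different statements. Undefined entries are excluded
from downstream sums and logged.

## Pathway weights

Direct score: `F[s, t]`. Indirect scores: products of hop fractions
along simple paths `s -> i1 [-> i2] -> t`, with every hop normalized to
the *postsynaptic* neuron's input budget. Design choices:

* **Layer discipline.** Hops follow sensory -> interneuron(s) -> target
  order; an interneuron -> interneuron hop occurs only as the L1 -> L2
  hop of a two-layer path. Whether a published two-layer scheme permits
  within-layer hops is usually unstated; strict ordering avoids cycle
  divergence and is the assumption made here.
* **Simple paths only** — no neuron revisited. With class-disjoint
  layers the only possible revisit is `i1 == i2`, which is excluded.
* Interneuron membership comes from the annotation table
  (`cell_class == "interneuron"`), never from connectivity.
* Distinct paths through the same interneuron at different depths are
  separate records and are summed.
* Modality rollup: per (target, modality), `total = direct + indirect`,
  and `normalized_percent = 100 * total / sum(total)` within the target.
  Argmax ties across modalities are broken lexicographically and
  flagged.

The vectorized implementation (sparse hop tables joined by merge) is
cross-checked in the tests against `enumerate_pathway_sums()`, a
deliberately naive recursive depth-first enumeration kept as an
independent code path; the suite requires agreement below 1e-12 on
50 random layered circuits of up to 40 neurons.

## Bilateral symmetry

`AI = (LL - RR) / (RR + LL) * 100` (ipsilateral) and the analogous
(LR, RL) form (contralateral), per cluster and direction. LL etc. always
read presynaptic-hemisphere x postsynaptic-hemisphere. Both-zero
denominators give `NA`, logged. Unpaired neurons (e.g. midline cells
with no hemisphere homologue) are excluded from budgets and the
exclusion count reported.

The ipsi-vs-contra correspondence across clusters is tested with
Spearman's rank correlation on mid-ranks, with the large-sample
t-approximation for p. Whether such correlations should be computed on
raw counts or on percentages is a genuine choice; the default is
left-share percentages (`100*LL/(LL+RR)` vs `100*LR/(LR+RL)`), with
`measure = "count"` correlating total ipsi- vs contralateral budget
magnitudes instead. Fewer than 3 complete cluster pairs is reported as
insufficient data rather than a number.

## Synapse placement

For the analyzed neuron, each synaptic pair contributes one record at
the connector's node *on that neuron* — presynaptic node for outputs
(including peripheral active zones), postsynaptic node for inputs — with
its geodesic distance from the origin computed on the raw node-to-node
polyline (no smoothing or resampling; whether published figures used
smoothed arbors is typically unstated, and raw polylines are the
conservative choice). When several neurons share an anatomical origin,
each is measured on its own tree from its own entry node; distances are
never mixed across trees.

Group differences use the classical one-way fixed-effects F computed
from explicit between/within sums of squares. The explicit form is used
(rather than an `lm`/`aov` wrapper) so the degenerate case of zero
within-group variance with distinct means can be reported as the
`F = Inf`, `p = 0` sentinel with a warning; `stats::aov` serves as the
oracle in the tests for the regular case.

## Trace analytics

`detect_events()` marks local maxima that exceed the channel median by
`threshold_k` MADs, have topographic prominence of at least
`min_prominence` of the signal range, and are separated by at least
`min_interval` seconds (accepted in order of decreasing height). All
criteria are scale-free, so detection is invariant under affine
rescaling of the fluorescence. Defaults: `threshold_k = 3`,
`min_interval = 1` s, `min_prominence = 0.1`. A moving-average
pre-filter (`smooth_s`, default 0.25 s) is applied first: without it,
single-sample noise excursions in low-duty-cycle stretches of the trace
are topographically prominent and defeat the prominence criterion,
whereas after averaging their prominence collapses while genuine
calcium transients (hundreds of ms wide) are preserved. The peak time is
reported at the (smoothed) peak sample.

`pair_events()` implements the trigger/completion picture: muscle
activity in the neurogenic zone (ROI1) is a trigger, and a subsequent
myogenic-zone (ROI2) event is the completed peristaltic wave. Each ROI2
event is greedily assigned to the **latest** unconsumed trigger within
`[t - window, t]` (default window 2 s); ROI2 events with no available
prior trigger are orphans and reported, since empirically myogenic waves
do not arise without a neurogenic trigger. Published descriptions of the
completion rate disagree internally about the direction of propagation
(myogenic-to-neurogenic vs neurogenic-to-myogenic); the
neurogenic-trigger-first form is implemented, as it is the one tied to
the observation that myogenic activity never precedes a trigger.

`completion_rate()` is `100 * completed / triggers`; with zero triggers
it is undefined (`NA`, warned). `cycle_frequency()` is
`60 * count / duration`; because conventions differ on whether cycle
frequency counts triggers or completed waves, `analyze_trace()` emits
both. Per-cell channel ratios are averaged unweighted within animal;
single-channel reporters use a unit denominator, and non-positive
denominators exclude the cell with a warning.

## The synthetic-data generator

`generate_circuit()` emulates the structural features the analyses rely
on: bilaterally mirrored clusters in feed-forward layers, polyadic
connectors, random-walk tree skeletons with a designated entry origin,
peripheral active zones with a tissue-tag distribution, and a
configurable excess left-ipsilateral drive (`asymmetry_eps` scales
expected LL pair counts by `1 + eps` and RR by `1 - eps`, so the
expected ipsilateral AI is `100 * eps` percent). Per ordered neuron
pair, a connection is drawn with the edge's probability and its pair
count from a Poisson with the edge's mean; pairs are then chunked into
connectors with `1 + Poisson(polyadicity - 1)` partners. The default
cast mirrors the enteric circuit at reduced scale (four sensory
clusters — one chemosensory, three mechanosensory — interneuron layers
L1/L2, a motor cluster, and a modulatory cluster bearing the peripheral
active zones), 46 neurons in all. The ground-truth bundle stores the
exact planted tallies and exhaustively enumerated pathway sums, so
recovery tests never re-derive truth through the code under test.

`generate_trace()` plants triggers as a Poisson process with a hard
2 s refractory gap — a peristaltic wave occupies the esophagus for over
a second, so overlapping triggers are unphysical, and the refractory
period also keeps planted events separable at the detector's 1 s
refractory default. Each trigger completes with probability
`completion_prob` (default 0.6) into an ROI2 bump after a 0.5 s latency;
bumps are unit-amplitude instant-rise exponential kernels
(`kernel_tau_s = 0.8` s, a fast calcium-indicator-like decay) and
Gaussian noise is added at `noise_sd = 0.05` of the bump amplitude.
Default rate and duration (10 triggers/min — a stimulated-preparation
wave rate — for 1200 s) give about 200 triggers per trace.

**What the generator does not emulate:** realistic arbor morphology
(random walks have no neurite-type structure, tortuosity statistics or
tiling), synapse-position biases along the arbor (placement tests plant
their own), distance-dependent connectivity, gap junctions, indicator
photobleaching, movement artifacts, and amplitude heterogeneity across
events. Passing recovery tests therefore demonstrates correctness of the
bookkeeping and statistics on circuits with the stated structure — not
robustness to every artifact of real recordings.

## Numerical choices and problem sizes

* Child iteration and layout order: ascending node id everywhere;
  dendrogram lanes assign leaves consecutive integers in depth-first
  order and give internal nodes the lane of their first child, so
  sibling subtrees occupy disjoint lane ranges deterministically.
* Geodesics are computed by a single stack-based traversal of the
  undirected weighted tree; tests require exact agreement with
  `igraph::distances` on 100 random trees of up to 500 nodes, and the
  acceptance script checks the same against an edge-relaxation oracle.
* All text writers render numbers in plain decimal with up to 15
  significant digits, making SWC/TSV round-trips lossless and rerun
  digests reproducible.
* One integer seed drives each generator call; the RNG state of the
  caller is saved and restored.
* Suite problem sizes: 50 random circuits (<= 40 neurons) for the
  pathway oracle, 100 trees (<= 500 nodes) for the geodesic oracle,
  20 seeds for asymmetry recovery (~512 expected ipsilateral pairs per
  side at eps = 0) and for placement ordering, 10 seeds of 1200 s traces
  for completion-rate recovery — sizes at which every stochastic check
  has comfortable margins while the whole suite runs in well under a
  minute per module.

## Known limitations

* Signed (excitatory/inhibitory) propagation, synapse-size weighting and
  paths deeper than two interneuron layers are out of scope.
* The pair-counting convention and the full-budget denominator (above)
  must match between datasets before comparing numbers.
* The one-way F assumes independent observations; synapses on one
  neuron are spatially autocorrelated, so its p-values should be read as
  descriptive ordering statistics rather than strict inference — the
  group summaries (n, mean, median per partner group, ordered by mean)
  are the primary output.
* Per-neuron homologue matching and permutation nulls for the symmetry
  analysis are not implemented; the asymmetry index is a cluster-level
  summary.
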